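#!/usr/bin/env Rscript
# Stage 1: generate the synthetic microcosm datasets.
#
# Two experiments are simulated, mirroring how the incubations were run:
#   (a) a short potential-oxidation-rate assay: 24 h of half-hourly CH4
#       monitoring at 2-500 ppmv, no replenishment;
#   (b) the 30-day stable-isotope-probing (SIP) design: triplicate 125-ml
#       bottles with 20 g sediment, 13CH4 (99 atom%) vs unlabelled CH4 at
#       2-500 ppmv, replenished every 3 days, full headspace swap on day 15,
#       plus sterile and ambient-air controls (42 bottles).
# Both carry multiplicative GC noise (CV 2%) and 0.3 permil IRMS noise.

library(karstCH4)

seed <- 20260922L
out <- "results/data"

sip_cfg <- incubation_config(seed = seed)
rate_cfg <- rate_assay_config(sampling_interval = 0.5, seed = seed + 1L)

message("simulating 30-day SIP design (", nrow(generate_design(sip_cfg)),
        " bottles) ...")
sip <- simulate_experiment(sip_cfg, true_state())
write_dataset(sip, file.path(out, "sip"))

message("simulating 24-h rate assay (", nrow(generate_design(rate_cfg)),
        " bottles) ...")
rates <- simulate_experiment(rate_cfg, true_state())
write_dataset(rates, file.path(out, "rate_assay"))

message("SIP headspace observations: ", nrow(sip$headspace))
message("rate-assay observations:    ", nrow(rates$headspace))
message("written to ", out)
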