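#!/usr/bin/env Rscript
# Stage 3: 13C mass balance of the SIP incubations.
#
# For every labelled bottle, reconstructs the supplied 13CH4 from the
# injection history, inventories excess 13C in sediment organic carbon
# (from the delta-13C-TOC shift against the paired unlabelled control), in
# vented plus final-headspace CO2, and in residual CH4, and reports the
# carbon-assimilation efficiency, biomass/CO2 partitioning and total
# recovery per bottle.

library(karstCH4)

sip <- read_dataset("results/data/sip")
budget <- isotope_budget(sip)
write_table_csv(budget, "results/budget.csv", sip$config$seed)

by_ppm <- aggregate(cbind(efficiency_pct, partition_co2_pct, recovery_pct) ~
                      target_ppm, data = budget, FUN = mean)
message("mean 13C budget by CH4 target (ppmv):")
print(round(by_ppm, 1), row.names = FALSE)
message(sprintf(
  "assimilation efficiency across treatments: %.1f%% to %.1f%% (generative truth: %.0f%%)",
  min(by_ppm$efficiency_pct), max(by_ppm$efficiency_pct),
  100 * sip$truth$f_assim))
message(sprintf("overall mean recovery of supplied 13C: %.1f%%",
                mean(budget$recovery_pct)))
message(paste(
  "note: at <= 10 ppm the delta-13C-TOC shift is a few tenths of a permil,",
  "the same order as IRMS precision, so per-bottle efficiencies at the",
  "lowest doses are noise-limited; the >= 50 ppm treatments recover the",
  "generative fraction closely."))
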