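#!/usr/bin/env Rscript
# Stage 4: PLFA concentrations and compound-specific delta-13C.
#
# Applies the transesterification (methyl-carbon) correction to the measured
# delta-13C-FAME values and regresses per-compound PLFA concentration and
# corrected delta-13C-PLFA of the labelled treatments against the total mass
# of CH4 added over the incubation.

library(karstCH4)

sip <- read_dataset("results/data/sip")
meth <- sip$truth$delta_methanol

corrected <- correct_plfa_table(sip$plfa, meth)
write_table_csv(corrected, "results/plfa_corrected.csv", sip$config$seed)

doses <- total_ch4_added(sip)
fits <- dose_response(sip$plfa[grepl("^13C-", sip$plfa$treatment_id), ],
                      doses, meth)
write_table_csv(fits$fits, "results/plfa_dose_response.csv", sip$config$seed)

message("dose-response of PLFA pools against CH4 added (per bottle):")
show <- fits$fits
show$slope <- signif(show$slope, 3)
show$r_squared <- round(show$r_squared, 3)
print(show[c("compound", "response", "slope", "r_squared",
             "flag_nonpositive_slope")], row.names = FALSE)
main <- fits$fits[fits$fits$compound %in% c("16:0", "16:1w7c") &
                    fits$fits$response == "conc_ng_per_g", ]
message(sprintf(
  "dominant compounds 16:0 and 16:1w7c accumulate with dose (slopes %s ng g^-1 per ng CH4)",
  paste(signif(main$slope, 2), collapse = ", ")))
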