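# Factorial expansion of the microcosm design into per-bottle descriptors.

#' Expand an incubation design into bottle descriptors
#'
#' Expands the factorial design of an [incubation_config()] — CH4 targets x
#' (13C label / unlabelled) x replicates, plus optional autoclaved-sterile
#' and ambient-air controls — into one descriptor per bottle. The sterile
#' control (oxidation and respiration disabled) is incubated at the lowest
#' CH4 target with unlabelled methane; the ambient control tracks
#' near-atmospheric CH4 with its headspace fully exchanged at every
#' replenishment.
#'
#' @param config An `incubation_config`.
#' @param constants An `isotope_constants` object (sets the natural-abundance
#'   atom fraction of unlabelled CH4).
#' @return A data.frame with one row per bottle: `treatment_id`, `replicate`,
#'   `kind` (labeled/unlabeled/sterile/ambient), `target_ppm`,
#'   `label_atom_fraction`, `oxidation`, `respiration`,
#'   `flush_on_replenish`.
#' @examples
#' nrow(generate_design(incubation_config()))  # 42 bottles in the full design
#' @export
generate_design <- function(config, constants = isotope_constants()) {
  validate_incubation_config(config)
  nat <- constants$natural_at / 100
  rows <- list()
  add <- function(id, kind, target, label_f, oxidation, respiration, flush) {
    for (r in seq_len(config$replicates)) {
      rows[[length(rows) + 1]] <<- data.frame(
        treatment_id = id, replicate = r, kind = kind,
        target_ppm = target, label_atom_fraction = label_f,
        oxidation = oxidation, respiration = respiration,
        flush_on_replenish = flush, stringsAsFactors = FALSE)
    }
  }
  for (ppm in sort(config$target_ch4)) {
    add(sprintf("13C-%g", ppm), "labeled", ppm, config$label_atom_fraction,
        TRUE, TRUE, FALSE)
    add(sprintf("12C-%g", ppm), "unlabeled", ppm, nat, TRUE, TRUE, FALSE)
  }
  if (config$include_sterile_control) {
    add("sterile", "sterile", min(config$target_ch4), nat, FALSE, FALSE, FALSE)
  }
  if (config$include_ambient_control) {
    add("ambient", "ambient", config$ambient_ch4, nat, TRUE, TRUE, TRUE)
  }
  do.call(rbind, rows)
}
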