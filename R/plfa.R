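# FAME methylation correction and PLFA dose-response regressions.

#' Correct a FAME delta-13C for the derivatization methyl carbon
#'
#' During transesterification each fatty acid gains one methyl carbon from
#' the methanol, diluting its isotopic signal. The mass-balance correction
#' recovers the free fatty acid's delta-13C:
#' `delta_PLFA = ((n + 1) * delta_FAME - delta_methanol) / n`,
#' where `n` is the number of carbon atoms in the free fatty acid (the FAME
#' has `n + 1`).
#'
#' @param delta_fame Measured delta-13C of the methyl ester, permil.
#' @param n_carbons Carbons in the free fatty acid (>= 1).
#' @param delta_methanol delta-13C of the derivatization methanol, permil.
#' @return Corrected delta-13C of the free fatty acid, permil.
#' @examples
#' correct_fame_delta(-30, 16, -47)  # -28.9375
#' @export
correct_fame_delta <- function(delta_fame, n_carbons, delta_methanol) {
  stopifnot(all(is.finite(delta_fame)), all(is.finite(delta_methanol)))
  if (any(n_carbons < 1)) stop("n_carbons must be >= 1")
  ((n_carbons + 1) * delta_fame - delta_methanol) / n_carbons
}

#' Predict the FAME delta-13C from a free fatty acid's delta-13C
#'
#' Algebraic inverse of [correct_fame_delta()]; used by the simulator and by
#' round-trip checks: `delta_FAME = (n * delta_PLFA + delta_methanol) /
#' (n + 1)`.
#'
#' @param delta_plfa delta-13C of the free fatty acid, permil.
#' @inheritParams correct_fame_delta
#' @return delta-13C of the methyl ester, permil.
#' @export
fame_from_plfa_delta <- function(delta_plfa, n_carbons, delta_methanol) {
  if (any(n_carbons < 1)) stop("n_carbons must be >= 1")
  (n_carbons * delta_plfa + delta_methanol) / (n_carbons + 1)
}

#' Apply the methylation correction to a PLFA table
#'
#' @param plfa Data.frame with columns `n_carbons` and `delta_fame_permil`.
#' @param delta_methanol delta-13C of the derivatization methanol, permil
#'   (no default: it must be measured for each methanol batch).
#' @return The table with an added `delta_plfa_permil` column.
#' @export
correct_plfa_table <- function(plfa, delta_methanol) {
  stopifnot(all(c("n_carbons", "delta_fame_permil") %in% names(plfa)))
  plfa$delta_plfa_permil <- correct_fame_delta(plfa$delta_fame_permil,
                                               plfa$n_carbons, delta_methanol)
  plfa
}

#' PLFA dose-response against methane added
#'
#' Per-compound ordinary least squares of treatment-mean PLFA concentration
#' and corrected delta-13C against the total mass of CH4 added to each
#' treatment. Compounds whose concentration slope is not positive are
#' flagged.
#'
#' @param plfa PLFA table (columns `treatment_id`, `replicate`, `compound`,
#'   `n_carbons`, `conc_ng_per_g`, `delta_fame_permil`).
#' @param total_ch4_added Named numeric vector: total CH4 added (ng per
#'   bottle) by `treatment_id`.
#' @param delta_methanol delta-13C of the derivatization methanol, permil.
#' @return A list with `fits` (one row per compound x response: `slope`,
#'   `intercept`, `r_squared`, `flag_nonpositive_slope`) and `residuals`.
#' @export
dose_response <- function(plfa, total_ch4_added, delta_methanol) {
  stopifnot(!is.null(names(total_ch4_added)))
  plfa <- plfa[plfa$treatment_id %in% names(total_ch4_added), , drop = FALSE]
  plfa <- correct_plfa_table(plfa, delta_methanol)
  plfa$dose <- total_ch4_added[plfa$treatment_id]
  if (length(unique(plfa$dose)) < 3) stop("need at least 3 dose levels")
  means <- stats::aggregate(
    cbind(conc_ng_per_g, delta_plfa_permil) ~ compound + dose,
    data = plfa, FUN = mean)
  fits <- list(); resids <- list()
  for (cp in unique(means$compound)) {
    m <- means[means$compound == cp, ]
    for (resp in c("conc_ng_per_g", "delta_plfa_permil")) {
      fit <- stats::lm(stats::reformulate("dose", resp), data = m)
      sl <- unname(stats::coef(fit)[2])
      fits[[length(fits) + 1]] <- data.frame(
        compound = cp, response = resp, slope = sl,
        intercept = unname(stats::coef(fit)[1]),
        r_squared = suppressWarnings(summary(fit)$r.squared),
        flag_nonpositive_slope = resp == "conc_ng_per_g" && sl <= 0,
        stringsAsFactors = FALSE)
      resids[[length(resids) + 1]] <- data.frame(
        compound = cp, response = resp, dose = m$dose,
        residual = stats::resid(fit), stringsAsFactors = FALSE)
    }
  }
  list(fits = do.call(rbind, fits), residuals = do.call(rbind, resids))
}
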