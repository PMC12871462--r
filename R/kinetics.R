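# Michaelis-Menten kinetics of methane oxidation and per-cell specific
# affinity.

#' Fit Michaelis-Menten kinetics to (concentration, rate) data
#'
#' Unweighted nonlinear least squares of `v = Vmax * S / (Km + S)` by
#' Levenberg-Marquardt, multi-started from 8 log-spaced Km initial values
#' spanning the observed concentration range. The half-saturation constant is
#' fitted on the measured headspace axis (ppmv) and converted to the aqueous
#' scale (nM) afterwards via [headspace_to_aqueous()]. Standard errors come
#' from the Jacobian at the optimum. Failure to converge from every start is
#' reported via `converged = FALSE`, never as an error.
#'
#' @param rates A data.frame with columns `concentration` (ppmv) and `rate`
#'   (ng CH4 g^-1 h^-1), or a two-column matrix/list of (concentration,
#'   rate).
#' @param temperature,pressure,bunsen Conditions for the ppm -> nM
#'   conversion of Km.
#' @return A one-row data.frame (`KineticsFit`): `vmax`, `km_ppm`, `km_aq`,
#'   `se_vmax`, `se_km_ppm`, `r_squared`, `n_points`, `converged`.
#' @examples
#' s <- c(2, 10, 50, 100, 250, 500)
#' fit_michaelis_menten(data.frame(concentration = s,
#'                                 rate = 100 * s / (50 + s)))
#' @export
fit_michaelis_menten <- function(rates, temperature = 20, pressure = 1,
                                 bunsen = 0.034) {
  if (!is.data.frame(rates)) rates <- as.data.frame(rates)
  if (!all(c("concentration", "rate") %in% names(rates))) {
    names(rates)[1:2] <- c("concentration", "rate")
  }
  s <- rates$concentration
  v <- rates$rate
  ok <- is.finite(s) & is.finite(v)
  s <- s[ok]; v <- v[ok]
  empty <- data.frame(vmax = NA_real_, km_ppm = NA_real_, km_aq = NA_real_,
                      se_vmax = NA_real_, se_km_ppm = NA_real_,
                      r_squared = NA_real_, n_points = length(s),
                      converged = FALSE)
  if (length(unique(s)) < 4) stop("need rates at >= 4 distinct concentrations")
  if (all(v == 0) || max(v) <= 0) return(empty)

  km_starts <- exp(seq(log(max(min(s[s > 0]), 1e-3) / 4),
                       log(max(s) * 4), length.out = 8))
  best <- NULL
  for (km0 in km_starts) {
    vmax0 <- max(v) * (km0 + max(s)) / max(s)
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * s / (km + s),
                        start = list(vmax = vmax0, km = km0),
                        lower = c(vmax = 0, km = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(empty)

  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  tss <- sum((v - mean(v))^2)
  data.frame(
    vmax = unname(cf["vmax"]),
    km_ppm = unname(cf["km"]),
    km_aq = headspace_to_aqueous(unname(cf["km"]), temperature, pressure,
                                 bunsen),
    se_vmax = unname(se["vmax"]),
    se_km_ppm = unname(se["km"]),
    r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
    n_points = length(s),
    converged = TRUE)
}

#' Michaelis-Menten sum of squared residuals
#'
#' Objective function of [fit_michaelis_menten()]; exposed so tests can
#' compare the fitted optimum against brute-force grid searches.
#'
#' @param vmax,km Parameter values.
#' @param s,v Concentration and rate vectors.
#' @return Sum of squared residuals.
#' @export
mm_objective <- function(vmax, km, s, v) {
  sum((v - vmax * s / (km + s))^2)
}

#' Per-cell specific affinity for methane
#'
#' Specific affinity `a0_s = Vmax(app) / Km(app)` normalized per cell: the
#' volume of water cleared of CH4 per cell per hour. `vmax` per gram dry
#' sediment is converted to mol per cell per hour using the CH4 molar mass
#' (16.04) and a cell density of `gene_copies_per_g / genes_per_cell`
#' (one pmoA copy per genome by default), then divided by the aqueous Km in
#' mol/L.
#'
#' @param vmax Maximal oxidation rate, ng CH4 g^-1 dry h^-1.
#' @param km_aq Aqueous half-saturation constant, nM.
#' @param gene_copies_per_g pmoA gene copies per g dry sediment.
#' @param genes_per_cell pmoA copies per cell (default 1).
#' @return Specific affinity in liters per cell per hour.
#' @export
specific_affinity <- function(vmax, km_aq, gene_copies_per_g,
                              genes_per_cell = 1) {
  stopifnot(vmax >= 0, km_aq > 0, gene_copies_per_g > 0, genes_per_cell > 0)
  cells_per_g <- gene_copies_per_g / genes_per_cell
  if (cells_per_g <= 0) stop("cell density must be positive")
  vmax_mol_cell <- vmax * 1e-9 / .const$molar_mass_ch4 / cells_per_g
  vmax_mol_cell / (km_aq * 1e-9)
}

#' Treatment-level kinetics from a microcosm dataset
#'
#' Convenience chain: estimate per-bottle rates, average replicates per
#' treatment (labelled and unlabelled live bottles), and fit the
#' Michaelis-Menten curve against the target concentrations.
#'
#' @param dataset A `microcosm_dataset` (or list with `headspace`, `design`,
#'   `config`).
#' @param ... Passed to [estimate_oxidation_rate()].
#' @return A list with `rates` (per-bottle), `by_treatment` (mean rate per
#'   target concentration) and `fit` (a `KineticsFit` row).
#' @export
kinetics_from_dataset <- function(dataset, ...) {
  design <- dataset$design
  rates <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    sub <- dataset$headspace[dataset$headspace$treatment_id == d$treatment_id &
                               dataset$headspace$replicate == d$replicate, ,
                             drop = FALSE]
    estimate_oxidation_rate(sub, dataset$config, c0 = d$target_ppm, ...)
  }))
  live <- merge(rates, design, by = c("treatment_id", "replicate"))
  live <- live[live$oxidation & !live$flush_on_replenish, , drop = FALSE]
  agg <- stats::aggregate(rate_ng_g_h ~ target_ppm, data = live, FUN = mean)
  fit <- fit_michaelis_menten(
    data.frame(concentration = agg$target_ppm, rate = agg$rate_ng_g_h),
    temperature = dataset$config$temperature,
    pressure = dataset$config$pressure)
  list(rates = rates, by_treatment = agg, fit = fit)
}
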