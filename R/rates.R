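# Potential methane oxidation rates from headspace draw-down series.

#' Estimate a potential methane oxidation rate from one bottle's series
#'
#' Estimates the oxidation rate at the start of an observation window from
#' the headspace CH4 draw-down, converted to ng CH4 per g dry sediment per
#' hour using the headspace moles (ideal gas, molar mass 16.04) and the dry
#' mass.
#'
#' Methods:
#' \describe{
#'   \item{`log_quadratic` (default)}{fits a quadratic to ln(ppm) vs time and
#'     reports the initial slope times the initial concentration. Exact on
#'     first-order (exponential) decay and nearly unbiased when the draw-down
#'     starts in the saturated Michaelis-Menten regime, where a straight
#'     ln-linear fit overestimates the initial rate.}
#'   \item{`first_order`}{fits ln(ppm) vs time; rate at window start is
#'     k * C0.}
#'   \item{`linear`}{reports minus the slope of ppm vs time.}
#' }
#' Standard errors are propagated from the regression slope. If the
#' first-order/log-quadratic window contains nonpositive concentrations the
#' estimator falls back to `linear` with a warning.
#'
#' @param series Headspace series data.frame for a single bottle (columns
#'   `time_h`, `ch4_ppmv`, `event`).
#' @param config An [incubation_config()] providing the bottle geometry.
#' @param method One of `"log_quadratic"`, `"first_order"`, `"linear"`.
#' @param window Length-2 numeric `(t_start, t_end)` in hours, or `NULL` for
#'   the default window: from the series start to just before the first
#'   replenish/swap event (or the series end).
#' @param c0 Known initial concentration at the window start (ppmv), e.g.
#'   the injection target the bottle was filled to. When supplied, the
#'   log-based fits are anchored through it (no free intercept), which
#'   stabilizes short noisy windows; when `NULL` the intercept is estimated.
#' @param drawdown_limit For the default window only: truncate the window
#'   once CH4 falls below this fraction of its initial value, so the
#'   estimate stays close to the *initial* rate even under saturated
#'   (zero-order) draw-down; at least 3 points are always retained.
#' @return A one-row data.frame (`RateEstimate`): `treatment_id`,
#'   `replicate`, `initial_ppm`, `rate_ng_g_h`, `se`, `method`,
#'   `window_start_h`, `window_end_h`, `n_points`.
#' @export
estimate_oxidation_rate <- function(series, config,
                                    method = c("log_quadratic", "first_order",
                                               "linear"),
                                    window = NULL, c0 = NULL,
                                    drawdown_limit = 0.85) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series), nrow(series) >= 3)
  ord <- order(series$time_h)
  series <- series[ord, , drop = FALSE]

  if (is.null(window)) {
    ev <- which(series$event != "none")
    t_end <- if (length(ev)) series$time_h[ev[1]] else max(series$time_h)
    window <- c(series$time_h[1], t_end)
    auto <- TRUE
  } else auto <- FALSE
  in_win <- series$time_h >= window[1] & series$time_h <= window[2]
  if (any(series$event[in_win] != "none" &
          series$time_h[in_win] > window[1] &
          series$time_h[in_win] < window[2])) {
    stop("window must not contain a replenish/swap event")
  }
  w <- series[in_win, , drop = FALSE]
  if (auto && nrow(w) > 3) {
    keep <- w$ch4_ppmv >= drawdown_limit * (if (is.null(c0)) w$ch4_ppmv[1]
                                            else c0)
    # keep a contiguous leading run, at least 3 points
    last <- max(sum(cumsum(!keep) == 0), 3L)
    w <- w[seq_len(min(last, nrow(w))), , drop = FALSE]
  }
  if (nrow(w) < 3) stop("need at least 3 observations in the window")

  t <- w$time_h - w$time_h[1]
  y <- w$ch4_ppmv
  fallback <- method != "linear" && any(y <= 0)
  if (fallback) {
    warning("nonpositive concentrations in window; falling back to linear")
    method <- "linear"
  }
  ng_per_ppm <- ppm_to_mass(1, config$headspace_volume, config$temperature,
                            config$pressure)
  conv <- ng_per_ppm / config$sediment_dry_mass  # ppm/h -> ng/g/h

  if (method == "linear") {
    fit <- stats::lm(y ~ t)
    slope <- unname(stats::coef(fit)[2])
    se_slope <- suppressWarnings(stats::summary.lm(fit))$coefficients[2, 2]
    rate_ppm_h <- -slope
    se_ppm_h <- se_slope
    c0 <- unname(stats::coef(fit)[1])
  } else if (method == "first_order") {
    if (is.null(c0)) {
      fit <- stats::lm(log(y) ~ t)
      k <- -unname(stats::coef(fit)[2])
      se_k <- suppressWarnings(stats::summary.lm(fit))$coefficients[2, 2]
      c_start <- exp(unname(stats::coef(fit)[1]))
    } else {
      fit <- stats::lm(log(y / c0) ~ 0 + t)
      k <- -unname(stats::coef(fit)[1])
      se_k <- suppressWarnings(stats::summary.lm(fit))$coefficients[1, 2]
      c_start <- c0
    }
    rate_ppm_h <- k * c_start
    se_ppm_h <- se_k * c_start
  } else { # log_quadratic
    if (is.null(c0)) {
      fit <- stats::lm(log(y) ~ t + I(t^2))
      k <- -unname(stats::coef(fit)[2])
      se_k <- if (nrow(w) > 3) suppressWarnings(stats::summary.lm(fit))$coefficients[2, 2] else NA_real_
      c_start <- exp(unname(stats::coef(fit)[1]))
    } else {
      fit <- stats::lm(log(y / c0) ~ 0 + t + I(t^2))
      k <- -unname(stats::coef(fit)[1])
      se_k <- if (nrow(w) > 2) suppressWarnings(stats::summary.lm(fit))$coefficients[1, 2] else NA_real_
      c_start <- c0
    }
    rate_ppm_h <- k * c_start
    se_ppm_h <- se_k * c_start
  }
  data.frame(
    treatment_id = if ("treatment_id" %in% names(w)) w$treatment_id[1] else NA,
    replicate = if ("replicate" %in% names(w)) w$replicate[1] else NA,
    initial_ppm = y[1],
    rate_ng_g_h = rate_ppm_h * conv,
    se = se_ppm_h * conv,
    method = method,
    window_start_h = min(w$time_h), window_end_h = max(w$time_h),
    n_points = nrow(w),
    stringsAsFactors = FALSE)
}

#' Estimate rates for every bottle of a dataset
#'
#' Applies [estimate_oxidation_rate()] to each bottle of a
#' `microcosm_dataset` (or a raw headspace table).
#'
#' @param headspace Headspace table or `microcosm_dataset`.
#' @param config An [incubation_config()] (taken from the dataset if given).
#' @param ... Passed to [estimate_oxidation_rate()].
#' @return A data.frame of rate estimates, one row per bottle.
#' @export
estimate_rates <- function(headspace, config = NULL, ...) {
  if (inherits(headspace, "microcosm_dataset")) {
    config <- headspace$config
    headspace <- headspace$headspace
  }
  stopifnot(!is.null(config))
  keys <- unique(headspace[c("treatment_id", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- headspace[headspace$treatment_id == keys$treatment_id[i] &
                       headspace$replicate == keys$replicate[i], , drop = FALSE]
    estimate_oxidation_rate(sub, config, ...)
  })
  do.call(rbind, out)
}
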