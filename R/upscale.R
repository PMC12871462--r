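# Regional methane-sink upscaling with Monte-Carlo uncertainty, emission
# offsets, and habitat-stratified rate summaries.

#' Define an upscaling scenario
#'
#' Parameters of a regional methane-sink estimate: habitat area, reactive
#' (methane-oxidizing) dry sediment mass per unit area, potential oxidation
#' rate, and the fraction of time/area that is active. `reactive_mass` and
#' `rate` may be point values or distribution specs
#' `list(dist = "lognormal"|"normal"|"uniform", ...)` with the usual stats
#' parameters (`meanlog`/`sdlog`, `mean`/`sd`, `min`/`max`). Default numbers
#' are illustrative placeholders, not survey-derived values.
#'
#' @param name Scenario label.
#' @param area Habitat area, km^2.
#' @param reactive_mass_per_area Reactive dry sediment, kg m^-2 (point value
#'   or distribution spec).
#' @param rate Oxidation rate, ng CH4 g^-1 h^-1 (point value or spec).
#' @param active_fraction Fraction of the year/area that is active (0-1).
#' @param hours_per_year Hours per year (8760).
#' @param draws Monte-Carlo draws (1 = point estimate only).
#' @param seed Seed for the Monte-Carlo draws.
#' @return A list of class `upscaling_scenario`.
#' @export
upscaling_scenario <- function(name = "illustrative",
                               area = 5e5,
                               reactive_mass_per_area = 100,
                               rate = 1.28,
                               active_fraction = 1,
                               hours_per_year = 8760,
                               draws = 1L,
                               seed = 1L) {
  sc <- structure(as.list(environment()), class = "upscaling_scenario")
  stopifnot(sc$area >= 0, sc$active_fraction >= 0, sc$active_fraction <= 1,
            sc$draws >= 1, sc$hours_per_year > 0)
  sc
}

.central_value <- function(x) {
  if (!is.list(x)) return(x)
  switch(x$dist,
         lognormal = exp(x$meanlog + x$sdlog^2 / 2),
         normal = x$mean,
         uniform = (x$min + x$max) / 2,
         stop(sprintf("unknown distribution '%s'", x$dist)))
}

.draw_values <- function(x, n) {
  if (!is.list(x)) {
    if (n > 1) stop("configuration error: draws > 1 requires a distribution ",
                    "spec (list(dist = ..., ...)) for stochastic parameters")
    return(rep(x, n))
  }
  switch(x$dist,
         lognormal = stats::rlnorm(n, x$meanlog, x$sdlog),
         normal = stats::rnorm(n, x$mean, x$sd),
         uniform = stats::runif(n, x$min, x$max),
         stop(sprintf("unknown distribution '%s'", x$dist)))
}

#' Regional methane-sink estimate
#'
#' Point estimate and Monte-Carlo interval of the annual regional methane
#' sink: `area (km^2 -> m^2) x reactive mass (kg m^-2 -> g) x rate
#' (ng g^-1 h^-1) x active_fraction x hours per year`, converted from ng to
#' Tg (1e-21). The point estimate uses central values (means of the
#' distribution specs); the interval is the seeded 2.5/97.5 percentile range
#' over `draws` Monte-Carlo samples.
#'
#' @param scenario An [upscaling_scenario()].
#' @return A list with `point` (Tg CH4 yr^-1), `interval` (2.5/97.5
#'   percentiles; equals the point when `draws == 1`), `draws` (the sampled
#'   sinks) and `scenario`.
#' @export
regional_sink <- function(scenario) {
  stopifnot(inherits(scenario, "upscaling_scenario"))
  sink_tg <- function(mass, rate) {
    scenario$area * 1e6 * mass * 1e3 * rate * scenario$active_fraction *
      scenario$hours_per_year * 1e-21
  }
  point <- sink_tg(.central_value(scenario$reactive_mass_per_area),
                   .central_value(scenario$rate))
  if (scenario$draws > 1) {
    set.seed(scenario$seed)
    if (!is.list(scenario$reactive_mass_per_area) &&
        !is.list(scenario$rate)) {
      stop("configuration error: draws > 1 but no parameter has a ",
           "distribution spec")
    }
    n <- scenario$draws
    mass <- if (is.list(scenario$reactive_mass_per_area)) {
      .draw_values(scenario$reactive_mass_per_area, n)
    } else rep(scenario$reactive_mass_per_area, n)
    rate <- if (is.list(scenario$rate)) .draw_values(scenario$rate, n) else
      rep(scenario$rate, n)
    draws <- sink_tg(mass, rate)
    interval <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  } else {
    draws <- point
    interval <- c(point, point)
  }
  list(point = point, interval = interval, draws = draws, scenario = scenario)
}

#' Fraction of an emission offset by a sink
#'
#' `100 * sink / emission`, both in Tg CH4 per year. Rounding to one decimal
#' is left to reporting.
#'
#' @param sink Sink, Tg CH4 yr^-1.
#' @param emission Emission, Tg CH4 yr^-1 (> 0).
#' @return Offset percentage.
#' @examples
#' round(offset_fraction(0.56, 9.79), 1)   # 5.7
#' round(offset_fraction(0.56, 23.39), 1)  # 2.4
#' @export
offset_fraction <- function(sink, emission) {
  stopifnot(all(sink >= 0))
  if (any(emission <= 0)) stop("emission must be > 0")
  100 * sink / emission
}

# Compact letter display from a logical "significantly different" matrix
# (insert-absorb): habitats sharing a letter are not significantly
# different.
.letters_from_diff <- function(diff_mat) {
  groups <- rownames(diff_mat)
  sets <- list(groups)  # start with one letter covering everything
  for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
    if (!diff_mat[i, j]) next
    gi <- groups[i]; gj <- groups[j]
    for (k in seq_along(sets)) {
      if (all(c(gi, gj) %in% sets[[k]])) {
        s <- sets[[k]]
        sets[[k]] <- setdiff(s, gi)
        sets[[length(sets) + 1]] <- setdiff(s, gj)
      }
    }
    # absorb redundant sets
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) for (b in seq_along(sets)) {
      if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]])) keep[a] <- FALSE
    }
    sets <- sets[keep]
  }
  out <- vapply(groups, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Habitat-stratified oxidation-rate summary
#'
#' Summarizes potential methane oxidation rates per habitat within bins of
#' initial CH4 concentration (half-open intervals `(low, high]`, matching
#' "<= 5 ppm" and "> 5 but <= 60 ppm" binning). Within each bin, habitats
#' are compared by Kruskal-Wallis followed by all-pairs Wilcoxon rank-sum
#' tests with Benjamini-Hochberg adjustment at 0.05, reported as compact
#' group letters (habitats sharing a letter are not significantly
#' different).
#'
#' @param records Data.frame with columns `habitat`, `initial_ch4_ppm`,
#'   `rate_ng_g_h` (and optionally `source`).
#' @param bins List of `c(low, high)` bin edges (half-open `(low, high]`).
#' @param alpha Significance level for the letters.
#' @param min_n Minimum records per habitat-bin cell to summarize.
#' @return A data.frame: `bin`, `habitat`, `mean`, `sd`, `n`, `letter`.
#' @export
habitat_summary <- function(records,
                            bins = list(c(0, 5), c(5, 60)),
                            alpha = 0.05, min_n = 2) {
  known <- c("forest", "grassland", "farmland", "cave", "other")
  stopifnot(all(c("habitat", "initial_ch4_ppm", "rate_ng_g_h") %in%
                  names(records)))
  bad <- setdiff(unique(records$habitat), known)
  if (length(bad)) {
    stop(sprintf("unknown habitat label(s): %s", paste(bad, collapse = ", ")))
  }
  out <- list()
  for (b in bins) {
    lab <- sprintf("(%g, %g]", b[1], b[2])
    sub <- records[records$initial_ch4_ppm > b[1] &
                     records$initial_ch4_ppm <= b[2], , drop = FALSE]
    counts <- table(sub$habitat)
    habs <- names(counts)[counts >= min_n]
    if (!length(habs)) next
    sub <- sub[sub$habitat %in% habs, , drop = FALSE]
    stats_df <- do.call(rbind, lapply(habs, function(h) {
      x <- sub$rate_ng_g_h[sub$habitat == h]
      data.frame(bin = lab, habitat = h, mean = mean(x),
                 sd = stats::sd(x), n = length(x), stringsAsFactors = FALSE)
    }))
    if (length(habs) >= 2) {
      pw <- stats::pairwise.wilcox.test(sub$rate_ng_g_h,
                                        factor(sub$habitat, levels = habs),
                                        p.adjust.method = "BH", exact = FALSE)
      diff_mat <- matrix(FALSE, length(habs), length(habs),
                         dimnames = list(habs, habs))
      pv <- pw$p.value
      for (i in rownames(pv)) for (j in colnames(pv)) {
        if (!is.na(pv[i, j]) && pv[i, j] < alpha) {
          diff_mat[i, j] <- diff_mat[j, i] <- TRUE
        }
      }
      stats_df$letter <- .letters_from_diff(diff_mat)[stats_df$habitat]
    } else stats_df$letter <- "a"
    out[[length(out) + 1]] <- stats_df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
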