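# Experiment configuration objects and their validation.

#' Incubation configuration
#'
#' Describes one microcosm treatment set: bottle geometry, methane targets,
#' labelling, event schedule and measurement model. Defaults reproduce the
#' 30-day stable-isotope-probing design: 20 g air-dried sediment in a 125-ml
#' serum bottle (0.105 L headspace), CH4 targets 2-500 ppmv, 99 atom% 13CH4
#' versus unlabelled control, replenishment every 3 days, a full headspace
#' swap on day 15, triplicates, sterile and ambient-air controls, 20 degC.
#'
#' @param sediment_dry_mass Dry sediment mass per bottle, grams.
#' @param moisture_fraction Gravimetric moisture fraction (0-1).
#' @param headspace_volume Headspace volume, liters.
#' @param temperature Incubation temperature, degrees Celsius.
#' @param pressure Headspace pressure, atm (held constant).
#' @param target_ch4 Numeric vector of target CH4 mixing ratios, ppmv.
#' @param label_atom_fraction 13C atom fraction of the labelled CH4 (0-1).
#' @param replenish_interval Hours between CH4 replenishments.
#' @param headspace_swap_time Hour at which the headspace is fully replaced
#'   with synthetic air (NA to disable).
#' @param duration Total incubation length, hours.
#' @param sampling_interval Hours between headspace observations.
#' @param replicates Bottles per treatment.
#' @param include_sterile_control Include an autoclaved (killed) control.
#' @param include_ambient_control Include an ambient-air control whose
#'   headspace is fully exchanged at each replenishment.
#' @param ambient_ch4 CH4 target of the ambient control, ppmv.
#' @param measurement_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise on concentration-type observations
#'   (default 0.02, typical GC-FID repeatability; 0 for noiseless runs).
#' @param delta_sd Additive 1-sigma instrument noise on delta-13C readings,
#'   permil.
#' @param step Integration step for the simulator, hours (<= 0.5).
#' @param seed Master random seed.
#' @return A validated list of class `incubation_config`.
#' @export
incubation_config <- function(sediment_dry_mass = 20,
                              moisture_fraction = 0.20,
                              headspace_volume = 0.105,
                              temperature = 20,
                              pressure = 1,
                              target_ch4 = c(2, 10, 50, 100, 250, 500),
                              label_atom_fraction = 0.99,
                              replenish_interval = 72,
                              headspace_swap_time = 360,
                              duration = 720,
                              sampling_interval = 12,
                              replicates = 3,
                              include_sterile_control = TRUE,
                              include_ambient_control = TRUE,
                              ambient_ch4 = 2,
                              measurement_cv = 0.02,
                              delta_sd = 0.3,
                              step = 0.25,
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "incubation_config")
  validate_incubation_config(cfg)
  cfg
}

#' Short-run configuration for rate measurements
#'
#' Convenience wrapper around [incubation_config()] for the separate
#' potential-oxidation-rate assay: a 24-hour monitoring run with hourly
#' sampling and no replenishment or swap, from which initial draw-down rates
#' are estimated.
#'
#' @param ... Overrides passed to [incubation_config()].
#' @return An `incubation_config`.
#' @export
rate_assay_config <- function(...) {
  args <- list(duration = 24, sampling_interval = 1,
               replenish_interval = 24, headspace_swap_time = NA_real_,
               include_sterile_control = FALSE,
               include_ambient_control = FALSE, ...)
  do.call(incubation_config, args[!duplicated(names(args), fromLast = TRUE)])
}

#' Validate an incubation configuration
#'
#' Checks positivity, bounds and schedule consistency; errors name the
#' offending field.
#'
#' @param config An `incubation_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_incubation_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid config field '%s': %s", field, msg),
                          call. = FALSE)
  }
  with(config, {
    chk(sediment_dry_mass > 0, "sediment_dry_mass", "must be > 0")
    chk(moisture_fraction >= 0 && moisture_fraction < 1, "moisture_fraction",
        "must be in [0, 1)")
    chk(headspace_volume > 0, "headspace_volume", "must be > 0")
    chk(temperature > -273.15, "temperature", "must be above absolute zero")
    chk(pressure > 0, "pressure", "must be > 0")
    chk(length(target_ch4) >= 1 && all(target_ch4 > 0), "target_ch4",
        "must be positive")
    chk(label_atom_fraction >= 0 && label_atom_fraction <= 1,
        "label_atom_fraction", "must be in [0, 1]")
    chk(replenish_interval > 0, "replenish_interval", "must be > 0")
    chk(duration > 0, "duration", "must be > 0")
    chk(is.na(headspace_swap_time) ||
          (headspace_swap_time > 0 && duration >= headspace_swap_time),
        "headspace_swap_time", "must lie within the incubation duration")
    chk(sampling_interval > 0 && sampling_interval <= duration,
        "sampling_interval", "must be in (0, duration]")
    chk(abs(replenish_interval / sampling_interval -
              round(replenish_interval / sampling_interval)) < 1e-9,
        "replenish_interval", "must be a multiple of sampling_interval")
    chk(replicates >= 1, "replicates", "must be >= 1")
    chk(measurement_cv >= 0, "measurement_cv", "must be >= 0")
    chk(delta_sd >= 0, "delta_sd", "must be >= 0")
    chk(step > 0 && step <= 0.5, "step", "must be in (0, 0.5] hours")
    chk(ambient_ch4 > 0, "ambient_ch4", "must be > 0")
  })
  invisible(config)
}

#' Generative ("true") state of a simulated microcosm
#'
#' Ground-truth parameters the simulator runs on and the analysis chain tries
#' to recover. Defaults are calibrated to the operating point of
#' methanotrophic cave sediment: an apparent Km of 138.8 ppmv headspace CH4
#' (196 nM aqueous at 20 degC) and a Vmax such that the oxidation rate at
#' 500 ppmv is 90.7 ng CH4 per g dry sediment per hour; 60% of oxidized
#' carbon is assimilated into biomass.
#'
#' @param vmax_true Maximal oxidation rate, ng CH4 g^-1 dry h^-1.
#' @param km_aq_true Aqueous half-saturation constant, nM.
#' @param f_assim Fraction of oxidized carbon assimilated into biomass (0-1).
#' @param epsilon_ox Kinetic isotope fractionation of oxidation, permil
#'   (0 = no isotopic selectivity; labelled and unlabelled bottles behave
#'   identically).
#' @param toc0 Initial total organic carbon, percent of dry mass.
#' @param delta_toc0 Initial delta-13C of the TOC, permil VPDB.
#' @param respiration_rate Background (non-methanotrophic) respiration,
#'   ng C g^-1 h^-1, feeding unlabelled CO2 into the headspace.
#' @param delta_resp delta-13C of respired background CO2, permil.
#' @param plfa_yield Fraction of assimilated carbon entering the PLFA pool.
#' @param plfa_allocation Named numeric vector summing to 1: allocation of
#'   PLFA-bound carbon among compounds (defaults 16:0, 16:1w7c, other).
#' @param plfa_background_conc Named numeric vector, pre-existing PLFA
#'   concentrations, ng per g dry sediment (defaults reflect the low
#'   standing biomass of oligotrophic subsurface sediments).
#' @param delta_plfa0 delta-13C of the pre-existing PLFA pool, permil.
#' @param delta_methanol delta-13C of the derivatization methanol, permil.
#' @return A validated list of class `true_state`.
#' @export
true_state <- function(vmax_true = 115.9,
                       km_aq_true = 196.0,
                       f_assim = 0.60,
                       epsilon_ox = 0,
                       toc0 = 1.5,
                       delta_toc0 = -25,
                       respiration_rate = 8,
                       delta_resp = -25,
                       plfa_yield = 0.03,
                       plfa_allocation = c("16:0" = 0.40,
                                           "16:1w7c" = 0.35,
                                           "other" = 0.25),
                       plfa_background_conc = c("16:0" = 600,
                                                "16:1w7c" = 450,
                                                "other" = 550),
                       delta_plfa0 = -28,
                       delta_methanol = -40) {
  ts <- structure(as.list(environment()), class = "true_state")
  validate_true_state(ts)
  ts
}

#' Validate a true-state object
#' @param truth A `true_state`.
#' @return The object, invisibly, if valid.
#' @export
validate_true_state <- function(truth) {
  with(truth, {
    stopifnot(vmax_true >= 0, km_aq_true > 0,
              f_assim >= 0, f_assim <= 1,
              epsilon_ox > -1000,
              toc0 > 0, delta_toc0 >= -1000,
              respiration_rate >= 0, delta_resp >= -1000,
              plfa_yield >= 0, plfa_yield <= 1,
              abs(sum(plfa_allocation) - 1) < 1e-9,
              all(plfa_allocation >= 0),
              all(plfa_background_conc >= 0),
              identical(sort(names(plfa_allocation)),
                        sort(names(plfa_background_conc))),
              delta_plfa0 >= -1000)
  })
  invisible(truth)
}

# Carbons in the free fatty acid, by compound label ("16:0" -> 16).
.plfa_n_carbons <- function(compound) {
  n <- suppressWarnings(as.integer(sub(":.*$", "", compound)))
  n[is.na(n)] <- 16L  # pooled "other" compounds treated as C16
  n
}
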