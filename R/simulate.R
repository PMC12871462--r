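# Forward simulation of one 13CH4/12CH4 microcosm bottle and of a whole
# treatment set. State is tracked in moles of carbon, separately for 12C and
# 13C, across four pools: headspace CH4, headspace CO2, sediment TOC and the
# (new) PLFA sub-pool. Measurement noise is applied to observations only, so
# the generative truth stays recoverable.

.lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  # mean-one lognormal multiplier
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate one microcosm bottle
#'
#' Forward-simulates the headspace gas time series and the sediment endpoint
#' of a single bottle described by one row of [generate_design()]. CH4 is
#' consumed by Michaelis-Menten kinetics acting on the aqueous concentration
#' at instantaneous headspace-water equilibrium (Bunsen coefficient); the
#' oxidized carbon carries the CH4 pool's 13C atom fraction (optionally
#' shifted by a kinetic fractionation), with a fraction `f_assim` routed to
#' the TOC pool (and `plfa_yield` of that into PLFA compounds) and the rest
#' to headspace CO2, where it mixes with unlabelled background respiration.
#' Replenishment events restore the CH4 target; the headspace swap vents all
#' gas (logged as vented 13C) before re-injection. Integration is an explicit
#' fixed-step update (step <= 0.5 h) between events.
#'
#' Rows whose `event` is `replenish` or `swap` record the observation taken
#' immediately *before* the event was applied; the post-event state is first
#' visible at the next sampling time (except at t = 0, which records the
#' freshly filled headspace).
#'
#' @param descriptor One-row data.frame from [generate_design()].
#' @param truth A [true_state()].
#' @param config An [incubation_config()].
#' @param constants An [isotope_constants()].
#' @param bottle_seed Integer seed for this bottle's measurement-noise
#'   stream.
#' @return A list with `series` (headspace observations), `endpoint`
#'   (sediment endpoint incl. PLFA records) and `ledger` (the simulator's
#'   exact internal carbon/13C bookkeeping, used by conservation tests).
#' @export
simulate_microcosm <- function(descriptor, truth, config,
                               constants = isotope_constants(),
                               bottle_seed = config$seed) {
  validate_incubation_config(config)
  validate_true_state(truth)
  stopifnot(nrow(descriptor) == 1, config$step > 0)
  set.seed(bottle_seed)

  vm <- molar_volume(config$temperature, config$pressure)
  hs_mol <- config$headspace_volume / vm        # total gas moles in headspace
  mol_per_ppm <- hs_mol * 1e-6
  nat <- constants$natural_at / 100
  f_lab <- descriptor$label_atom_fraction
  dry <- config$sediment_dry_mass

  # pools (mol C)
  ch4 <- c(l = 0, h = 0)   # l = 12C, h = 13C
  co2 <- c(l = 0, h = 0)
  toc_mol <- dry * truth$toc0 / 100 / .const$molar_mass_c
  f_toc0 <- .delta_to_frac(truth$delta_toc0, constants$r_standard)
  toc <- c(l = toc_mol * (1 - f_toc0), h = toc_mol * f_toc0)
  comps <- names(truth$plfa_allocation)
  plfa_new <- matrix(0, nrow = length(comps), ncol = 2,
                     dimnames = list(comps, c("l", "h")))
  f_resp <- .delta_to_frac(truth$delta_resp, constants$r_standard)

  ledger <- list(supplied_mol = 0, supplied_13c_mol = 0, injections = 0,
                 oxidized_mol = 0, oxidized_13c_mol = 0,
                 assim_13c_mol = 0, co2_prod_13c_mol = 0,
                 vented_co2_13c_mol = 0, vented_ch4_13c_mol = 0,
                 resp_mol = 0)
  injection_log <- list()

  inject <- function(time) {
    cur_ppm <- sum(ch4) / mol_per_ppm
    add_ppm <- max(descriptor$target_ppm - cur_ppm, 0)
    add_mol <- add_ppm * mol_per_ppm
    ch4 <<- ch4 + add_mol * c(1 - f_lab, f_lab)
    ledger$supplied_mol <<- ledger$supplied_mol + add_mol
    ledger$supplied_13c_mol <<- ledger$supplied_13c_mol + add_mol * f_lab
    ledger$injections <<- ledger$injections + 1
    injection_log[[length(injection_log) + 1]] <<-
      data.frame(time_h = time, added_mol = add_mol, label_frac = f_lab)
  }
  vent <- function() {
    ledger$vented_co2_13c_mol <<- ledger$vented_co2_13c_mol + co2[["h"]]
    ledger$vented_ch4_13c_mol <<- ledger$vented_ch4_13c_mol + ch4[["h"]]
    ch4 <<- c(l = 0, h = 0)
    co2 <<- c(l = 0, h = 0)
  }

  step <- config$step
  times <- seq(0, config$duration, by = step)
  sample_every <- round(config$sampling_interval / step)
  repl_every <- round(config$replenish_interval / step)
  swap_idx <- if (is.na(config$headspace_swap_time)) -1L else
    round(config$headspace_swap_time / step)

  inject(0)
  obs <- list()
  observe <- function(time, event) {
    tot <- sum(ch4)
    ppm_true <- tot / mol_per_ppm
    ppm_obs <- ppm_true * .lognorm_noise(1, config$measurement_cv)
    if (tot > 0) {
      f <- ch4[["h"]] / tot
      r <- f / (1 - f) * .lognorm_noise(1, config$measurement_cv)
      f_obs <- r / (1 + r)
    } else f_obs <- NA_real_
    co2_tot <- sum(co2)
    co2_obs <- co2_tot / mol_per_ppm * .lognorm_noise(1, config$measurement_cv)
    d_co2 <- if (co2_tot > 0) {
      .frac_to_delta(co2[["h"]] / co2_tot, constants$r_standard) +
        stats::rnorm(1, 0, config$delta_sd)
    } else NA_real_
    obs[[length(obs) + 1]] <<- data.frame(
      treatment_id = descriptor$treatment_id,
      replicate = descriptor$replicate,
      time_h = time, ch4_ppmv = ppm_obs, ch4_13f = f_obs,
      co2_ppmv = co2_obs, delta_co2_permil = d_co2, event = event,
      vented_13c_ug = (ledger$vented_co2_13c_mol + ledger$vented_ch4_13c_mol) *
        .const$molar_mass_13c * 1e6,
      stringsAsFactors = FALSE)
  }
  observe(0, "none")

  for (i in seq_along(times)[-1]) {
    t_now <- times[i]
    # integrate one step
    if (descriptor$oxidation && sum(ch4) > 0) {
      # consumption over one step by classical RK4 on the total CH4 pool
      aq_per_mol <- headspace_to_aqueous(1 / mol_per_ppm, config$temperature,
                                         config$pressure)
      dmdt <- function(m) {            # mol CH4 consumed per hour
        s_aq <- max(m, 0) * aq_per_mol
        truth$vmax_true * s_aq / (truth$km_aq_true + s_aq) * dry * 1e-9 /
          .const$molar_mass_ch4
      }
      m0 <- sum(ch4)
      k1 <- dmdt(m0)
      k2 <- dmdt(m0 - step / 2 * k1)
      k3 <- dmdt(m0 - step / 2 * k2)
      k4 <- dmdt(m0 - step * k3)
      d_mol <- step * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      if (d_mol >= sum(ch4)) {
        stop("unstable integration: CH4 pool exhausted within one step; ",
             "reduce config$step")
      }
      f <- ch4[["h"]] / sum(ch4)
      r_ox <- (f / (1 - f)) * (1 + truth$epsilon_ox / 1000)
      f_ox <- r_ox / (1 + r_ox)
      d <- d_mol * c(l = 1 - f_ox, h = f_ox)
      ch4 <- ch4 - d
      a <- truth$f_assim * d
      toc <- toc + a
      plfa_new <- plfa_new + truth$plfa_yield *
        outer(truth$plfa_allocation[comps], a)
      co2 <- co2 + (1 - truth$f_assim) * d
      ledger$oxidized_mol <- ledger$oxidized_mol + d_mol
      ledger$oxidized_13c_mol <- ledger$oxidized_13c_mol + d[["h"]]
      ledger$assim_13c_mol <- ledger$assim_13c_mol + a[["h"]]
      ledger$co2_prod_13c_mol <- ledger$co2_prod_13c_mol +
        (1 - truth$f_assim) * d[["h"]]
    }
    if (descriptor$respiration && truth$respiration_rate > 0) {
      r_mol <- truth$respiration_rate * dry * step * 1e-9 / .const$molar_mass_c
      co2 <- co2 + r_mol * c(1 - f_resp, f_resp)
      ledger$resp_mol <- ledger$resp_mol + r_mol
    }
    # events (observation first: gas is sampled before each addition)
    is_swap <- i - 1L == swap_idx
    is_repl <- (i - 1L) %% repl_every == 0 && t_now < config$duration
    is_sample <- (i - 1L) %% sample_every == 0
    if (is_swap || (is_repl && descriptor$flush_on_replenish)) {
      observe(t_now, "swap")
      vent()
      inject(t_now)
    } else if (is_repl) {
      observe(t_now, "replenish")
      inject(t_now)
    } else if (is_sample) {
      observe(t_now, "none")
    }
  }

  series <- do.call(rbind, obs)
  rownames(series) <- NULL

  # endpoint
  toc_tot <- sum(toc)
  toc_pct_true <- toc_tot * .const$molar_mass_c * 100 / dry
  f_toc <- toc[["h"]] / toc_tot
  d_toc <- .frac_to_delta(f_toc, constants$r_standard)
  plfa_c_frac <- 0.75  # carbon mass fraction of a fatty acid, ~C16
  bg_conc <- truth$plfa_background_conc[comps]
  f_bg <- .delta_to_frac(truth$delta_plfa0, constants$r_standard)
  plfa_rows <- lapply(comps, function(cp) {
    bg_c_mol <- bg_conc[[cp]] * plfa_c_frac * dry / (.const$molar_mass_c * 1e9)
    new_l <- plfa_new[cp, "l"]; new_h <- plfa_new[cp, "h"]
    tot_mol <- bg_c_mol + new_l + new_h
    f_cp <- (bg_c_mol * f_bg + new_h) / tot_mol
    d_plfa <- .frac_to_delta(f_cp, constants$r_standard)
    n <- .plfa_n_carbons(cp)
    d_fame <- fame_from_plfa_delta(d_plfa, n, truth$delta_methanol)
    conc_true <- tot_mol * .const$molar_mass_c * 1e9 / (plfa_c_frac * dry)
    data.frame(treatment_id = descriptor$treatment_id,
               replicate = descriptor$replicate,
               compound = cp, n_carbons = n,
               conc_ng_per_g = conc_true * .lognorm_noise(1, config$measurement_cv),
               delta_fame_permil = d_fame + stats::rnorm(1, 0, config$delta_sd),
               stringsAsFactors = FALSE)
  })
  endpoint <- list(
    summary = data.frame(
      treatment_id = descriptor$treatment_id,
      replicate = descriptor$replicate,
      toc_pct = toc_pct_true * .lognorm_noise(1, config$measurement_cv),
      delta_toc_permil = d_toc + stats::rnorm(1, 0, config$delta_sd),
      delta_methanol_permil = truth$delta_methanol,
      stringsAsFactors = FALSE),
    plfa = do.call(rbind, plfa_rows))
  rownames(endpoint$plfa) <- NULL

  ledger$residual_ch4_13c_mol <- ch4[["h"]]
  ledger$residual_co2_13c_mol <- co2[["h"]]
  ledger$toc_excess_13c_mol <- toc[["h"]] - toc_mol * f_toc0
  ledger$injection_log <- do.call(rbind, injection_log)
  list(series = series, endpoint = endpoint, ledger = ledger)
}

#' Derive a per-bottle seed from the master seed
#'
#' Deterministic substream derivation: each bottle's measurement-noise stream
#' is seeded from the master seed and the bottle index.
#'
#' @param master Master seed (integer).
#' @param index Bottle index (1-based).
#' @return An integer seed below 2^31.
#' @export
bottle_seed <- function(master, index) {
  as.integer((as.numeric(master) * 97 + index * 10007) %% 2147483629)
}

#' Simulate a full microcosm experiment
#'
#' Runs [simulate_microcosm()] for every bottle of the expanded design and
#' assembles tidy tables.
#'
#' @param config An [incubation_config()].
#' @param truth A [true_state()].
#' @param constants An [isotope_constants()].
#' @return A list of class `microcosm_dataset` with elements `design`,
#'   `headspace`, `endpoints`, `plfa` (data.frames), `ledgers` (per-bottle
#'   internal bookkeeping), `config`, `truth`.
#' @export
simulate_experiment <- function(config = incubation_config(),
                                truth = true_state(),
                                constants = isotope_constants()) {
  design <- generate_design(config, constants)
  runs <- lapply(seq_len(nrow(design)), function(i) {
    simulate_microcosm(design[i, , drop = FALSE], truth, config, constants,
                       bottle_seed = bottle_seed(config$seed, i))
  })
  out <- list(
    design = design,
    headspace = do.call(rbind, lapply(runs, `[[`, "series")),
    endpoints = do.call(rbind, lapply(runs, function(r) r$endpoint$summary)),
    plfa = do.call(rbind, lapply(runs, function(r) r$endpoint$plfa)),
    ledgers = lapply(runs, `[[`, "ledger"),
    config = config, truth = truth)
  rownames(out$headspace) <- rownames(out$endpoints) <- rownames(out$plfa) <- NULL
  class(out) <- "microcosm_dataset"
  out
}

#' @export
print.microcosm_dataset <- function(x, ...) {
  cat(sprintf("<microcosm_dataset> %d bottles, %d headspace observations\n",
              nrow(x$design), nrow(x$headspace)))
  cat(sprintf("  targets: %s ppmv; duration %g h; seed %s\n",
              paste(sort(unique(x$design$target_ppm)), collapse = ", "),
              x$config$duration, x$config$seed))
  invisible(x)
}
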