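test_that("first-order estimator is exact on exponential decay", {
  # C(t) = 500 * exp(-0.05 t) ppm in a 125-ml bottle headspace, 20 g, 20 C
  k <- 0.05
  t <- seq(0, 24, by = 1)
  series <- data.frame(treatment_id = "x", replicate = 1L, time_h = t,
                       ch4_ppmv = 500 * exp(-k * t), event = "none")
  cfg <- incubation_config(target_ch4 = 500)
  est <- estimate_oxidation_rate(series, cfg, method = "first_order",
                                 window = c(0, 24))
  expected <- k * 500 *
    ppm_to_mass(1, cfg$headspace_volume, cfg$temperature, cfg$pressure) /
    cfg$sediment_dry_mass
  expect_equal(est$rate_ng_g_h, expected, tolerance = 1e-6)
  # the log-quadratic default is exact here too (zero curvature)
  est2 <- estimate_oxidation_rate(series, cfg, window = c(0, 24))
  expect_equal(est2$rate_ng_g_h, expected, tolerance = 1e-6)
})

test_that("a flat sterile series yields a zero rate", {
  series <- data.frame(treatment_id = "sterile", replicate = 1L,
                       time_h = 0:10, ch4_ppmv = rep(2, 11), event = "none")
  cfg <- incubation_config(target_ch4 = 2)
  est <- estimate_oxidation_rate(series, cfg, method = "linear",
                                 window = c(0, 10))
  expect_equal(est$rate_ng_g_h, 0, tolerance = 1e-9)
})

test_that("estimator guards: events in window, short series, fallback", {
  cfg <- incubation_config(target_ch4 = 100)
  series <- data.frame(treatment_id = "x", replicate = 1L, time_h = 0:6,
                       ch4_ppmv = 100 * exp(-0.2 * (0:6)),
                       event = c("none", "none", "none", "replenish",
                                 "none", "none", "none"))
  expect_error(estimate_oxidation_rate(series, cfg, window = c(0, 6)),
               "event")
  expect_error(estimate_oxidation_rate(series[1:2, ], cfg),
               "at least 3|>= 3")
  neg <- data.frame(treatment_id = "x", replicate = 1L, time_h = 0:4,
                    ch4_ppmv = c(10, 5, 1, 0, 0), event = "none")
  expect_warning(est <- estimate_oxidation_rate(neg, cfg, window = c(0, 4)),
                 "linear")
  expect_equal(est$method, "linear")
})

test_that("Michaelis-Menten fit recovers exact parameters from clean data", {
  fit <- fit_michaelis_menten(mm_rates(100, 50))
  expect_true(fit$converged)
  expect_equal(fit$vmax, 100, tolerance = 1e-6)
  expect_equal(fit$km_ppm, 50, tolerance = 1e-6)
  expect_equal(fit$km_aq, headspace_to_aqueous(fit$km_ppm), tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("fit handles degenerate input without raising", {
  flat <- data.frame(concentration = c(2, 10, 50, 100), rate = 0)
  fit <- fit_michaelis_menten(flat)
  expect_false(fit$converged)
  expect_error(fit_michaelis_menten(mm_rates(100, 50, s = c(1, 2, 3))),
               "4 distinct")
})

test_that("fitted optimum beats a 200x200 grid search on noisy instances", {
  set.seed(11)
  for (rep in 1:5) {
    truth_v <- stats::runif(1, 50, 150)
    truth_k <- stats::runif(1, 20, 300)
    d <- mm_rates(truth_v, truth_k)
    d$rate <- d$rate * exp(stats::rnorm(6, 0, 0.05))
    fit <- fit_michaelis_menten(d)
    vg <- seq(0.5 * truth_v, 2 * truth_v, length.out = 200)
    kg <- exp(seq(log(1), log(2000), length.out = 200))
    grid_min <- min(outer(vg, kg, Vectorize(function(vv, kk)
      mm_objective(vv, kk, d$concentration, d$rate))))
    expect_lte(mm_objective(fit$vmax, fit$km_ppm, d$concentration, d$rate),
               grid_min + 1e-8)
  }
})

test_that("median Km error stays under 15% across 200 noisy datasets", {
  set.seed(101)
  errs <- replicate(200, {
    d <- mm_rates(115.9, 138.8)
    d$rate <- d$rate * exp(stats::rnorm(6, 0, 0.05))
    fit <- fit_michaelis_menten(d)
    abs(fit$km_ppm - 138.8) / 138.8
  })
  expect_lt(stats::median(errs), 0.15)
})

test_that("fit is scale-equivariant in the rate axis", {
  d <- mm_rates(80, 120)
  d$rate <- d$rate * exp(stats::rnorm(6, 0, 0.03))
  f1 <- fit_michaelis_menten(d)
  d2 <- d; d2$rate <- d2$rate * 7
  f2 <- fit_michaelis_menten(d2)
  expect_equal(f2$vmax, 7 * f1$vmax, tolerance = 1e-6)
  expect_equal(f2$km_ppm, f1$km_ppm, tolerance = 1e-6)
})

test_that("specific affinity follows its defining ratio and proportionality", {
  # 1.96e-16 mol/cell/h at 196 nM -> 1.0e-9 L/cell/h
  cells <- 1e7
  vmax <- 1.96e-16 * cells * 16.04 * 1e9  # ng CH4 per g per h
  expect_equal(specific_affinity(vmax, 196, cells), 1.0e-9,
               tolerance = 1e-6)
  expect_equal(specific_affinity(0, 196, 1e7), 0)
  expect_equal(specific_affinity(50, 196, 1e7, genes_per_cell = 2),
               2 * specific_affinity(50, 196, 1e7, genes_per_cell = 1))
  # invariance: per-gram and per-cell formulations agree
  a_direct <- (vmax * 1e-9 / 16.04 / cells) / (196e-9)
  expect_equal(specific_affinity(vmax, 196, cells), a_direct)
  expect_error(specific_affinity(10, 196, 0), "gene_copies_per_g")
})

test_that("noiseless simulator kinetics recover the generative truth within 1%", {
  truth <- true_state()
  ds <- simulate_experiment(quiet_rate_config(), truth)
  kin <- kinetics_from_dataset(ds)
  expect_true(kin$fit$converged)
  expect_equal(kin$fit$vmax, truth$vmax_true, tolerance = 0.01)
  expect_equal(kin$fit$km_aq, truth$km_aq_true, tolerance = 0.01)
  # the 500-ppm treatment runs at the calibrated operating point
  r500 <- kin$by_treatment$rate_ng_g_h[kin$by_treatment$target_ppm == 500]
  expect_equal(r500, 90.7, tolerance = 0.05)
})
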