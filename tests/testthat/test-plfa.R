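test_that("methylation correction matches hand evaluations and limits", {
  # identity when the methanol matches the FAME
  expect_equal(correct_fame_delta(-40, 16, -40), -40)
  expect_equal(correct_fame_delta(-30, 16, -47), -28.9375)
  # monotone convergence to delta_FAME as the chain grows
  ns <- c(2, 4, 8, 16, 32, 64, 256)
  vals <- correct_fame_delta(-30, ns, -47)
  expect_true(all(diff(abs(vals - (-30))) < 0))
  expect_equal(correct_fame_delta(-30, 1e6, -47), -30, tolerance = 1e-4)
  expect_error(correct_fame_delta(-30, 0, -47), "n_carbons")
})

test_that("correction round-trips through its inverse and is linear", {
  set.seed(3)
  d_fame <- stats::runif(20, -60, 500)
  n <- sample(c(14:20), 20, replace = TRUE)
  meth <- -47
  back <- fame_from_plfa_delta(correct_fame_delta(d_fame, n, meth), n, meth)
  expect_equal(back, d_fame, tolerance = 1e-10)
  # linear in delta_FAME with slope (n+1)/n
  slope <- (correct_fame_delta(-20, 16, meth) -
              correct_fame_delta(-30, 16, meth)) / 10
  expect_equal(slope, 17 / 16)
})

test_that("dose-response recovers an exact linear relationship", {
  doses <- c(a = 1000, b = 2000, c = 4000, d = 8000)
  plfa <- do.call(rbind, lapply(names(doses), function(id) {
    data.frame(treatment_id = id, replicate = 1L, compound = "16:0",
               n_carbons = 16L,
               conc_ng_per_g = 500 + 0.2 * doses[[id]],
               delta_fame_permil = -30 + 0.001 * doses[[id]])
  }))
  fit <- dose_response(plfa, doses, delta_methanol = -47)
  conc <- fit$fits[fit$fits$response == "conc_ng_per_g", ]
  expect_equal(conc$slope, 0.2, tolerance = 1e-9)
  expect_equal(conc$r_squared, 1, tolerance = 1e-9)
  expect_false(conc$flag_nonpositive_slope)
  expect_error(dose_response(plfa[plfa$treatment_id %in% c("a", "b"), ],
                             doses[1:2], -47), "3 dose levels")
})

test_that("simulated PLFA pools grow and get heavier with methane dose", {
  ds <- simulate_experiment(quiet_sip_config(targets = c(2, 50, 500)),
                            true_state())
  doses <- total_ch4_added(ds)
  fit <- dose_response(ds$plfa[grepl("^13C-", ds$plfa$treatment_id), ],
                       doses, true_state()$delta_methanol)
  main <- fit$fits[fit$fits$compound %in% c("16:0", "16:1w7c"), ]
  expect_true(all(main$slope[main$response == "conc_ng_per_g"] > 0))
  expect_true(all(main$slope[main$response == "delta_plfa_permil"] > 0))
})

test_that("permuting doses destroys the fit in >= 95% of permutations", {
  # full 30-day dose schedule: the concentration signal accumulated over all
  # ten injections is what the regression sees in practice
  ds <- simulate_experiment(
    incubation_config(target_ch4 = c(2, 10, 50, 100, 250, 500),
                      replicates = 1,
                      include_sterile_control = FALSE,
                      include_ambient_control = FALSE,
                      measurement_cv = 0.02, delta_sd = 0.3, seed = 5L),
    true_state())
  doses <- total_ch4_added(ds)
  plfa <- ds$plfa[grepl("^13C-", ds$plfa$treatment_id), ]
  plfa <- plfa[plfa$compound == "16:0", ]
  r2_true <- dose_response(plfa, doses, -40)$fits
  r2_true <- r2_true$r_squared[r2_true$response == "conc_ng_per_g"]
  set.seed(17)
  worse <- replicate(200, {
    perm <- doses
    names(perm) <- sample(names(doses))
    r2p <- dose_response(plfa, perm, -40)$fits
    r2p$r_squared[r2p$response == "conc_ng_per_g"] < r2_true
  })
  expect_gte(mean(worse), 0.95)
})
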