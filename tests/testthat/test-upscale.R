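test_that("regional sink arithmetic matches hand evaluation and is linear", {
  base <- upscaling_scenario(area = 5e5, reactive_mass_per_area = 100,
                             rate = 1.28, active_fraction = 1)
  expect_equal(regional_sink(base)$point, 0.56, tolerance = 0.01 / 0.56)
  expect_equal(regional_sink(upscaling_scenario(area = 0))$point, 0)
  doubled <- upscaling_scenario(area = 5e5, reactive_mass_per_area = 100,
                                rate = 2.56, active_fraction = 1)
  expect_equal(regional_sink(doubled)$point, 2 * regional_sink(base)$point)
  half_active <- upscaling_scenario(area = 5e5,
                                    reactive_mass_per_area = 100,
                                    rate = 1.28, active_fraction = 0.5)
  expect_equal(regional_sink(half_active)$point,
               regional_sink(base)$point / 2)
})

test_that("Monte-Carlo interval brackets the point estimate and is seeded", {
  sc <- upscaling_scenario(
    area = 5e5,
    reactive_mass_per_area = list(dist = "normal", mean = 100, sd = 10),
    rate = list(dist = "uniform", min = 1.0, max = 1.56),
    draws = 2000L, seed = 9L)
  out <- regional_sink(sc)
  expect_true(out$interval[1] <= out$point && out$point <= out$interval[2])
  out2 <- regional_sink(sc)
  expect_identical(out$draws, out2$draws)
  # draws > 1 without any distribution spec is a configuration error
  bad <- upscaling_scenario(draws = 100L)
  expect_error(regional_sink(bad), "configuration error")
})

test_that("offset fractions reproduce the published arithmetic", {
  expect_equal(round(offset_fraction(0.56, 9.79), 1), 5.7)
  expect_equal(round(offset_fraction(0.56, 23.39), 1), 2.4)
  expect_equal(offset_fraction(0, 5), 0)
  expect_error(offset_fraction(0.5, 0), "emission")
})

test_that("habitat summary statistics match brute-force recomputation", {
  rec <- data.frame(habitat = "cave", initial_ch4_ppm = 2,
                    rate_ng_g_h = c(1, 2, 3))
  out <- habitat_summary(rec, bins = list(c(0, 5)))
  expect_equal(out$mean, 2)
  expect_equal(out$sd, 1)
  expect_equal(out$n, 3)
  expect_error(habitat_summary(data.frame(habitat = "swamp",
                                          initial_ch4_ppm = 1,
                                          rate_ng_g_h = 1)),
               "unknown habitat")
  # half-open binning: a 5-ppm record belongs to the (0, 5] bin
  edge <- data.frame(habitat = "cave", initial_ch4_ppm = c(5, 5, 5.01, 6),
                     rate_ng_g_h = 1:4)
  out2 <- habitat_summary(edge, bins = list(c(0, 5), c(5, 60)))
  expect_equal(out2$n, c(2, 2))
})

test_that("well-separated habitats earn distinct letters", {
  set.seed(31)
  rec <- rbind(
    data.frame(habitat = "cave", initial_ch4_ppm = 2,
               rate_ng_g_h = stats::rnorm(30, 10, 1)),
    data.frame(habitat = "forest", initial_ch4_ppm = 2,
               rate_ng_g_h = stats::rnorm(30, 13, 1)))  # shift = 3 sd
  out <- habitat_summary(rec, bins = list(c(0, 5)))
  expect_false(out$letter[out$habitat == "cave"] ==
                 out$letter[out$habitat == "forest"])
})

test_that("identical distributions usually share a letter", {
  set.seed(41)
  same_letter <- replicate(100, {
    rec <- rbind(
      data.frame(habitat = "cave", initial_ch4_ppm = 2,
                 rate_ng_g_h = stats::rnorm(15, 10, 2)),
      data.frame(habitat = "grassland", initial_ch4_ppm = 2,
                 rate_ng_g_h = stats::rnorm(15, 10, 2)))
    out <- habitat_summary(rec, bins = list(c(0, 5)))
    any(strsplit(out$letter[1], "")[[1]] %in% strsplit(out$letter[2], "")[[1]])
  })
  expect_gte(mean(same_letter), 0.9)
})
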