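test_that("linear_rate is the daily OLS slope", {
  expect_equal(linear_rate(c(0, 24), c(10, 10.5)), 0.5)
  expect_equal(linear_rate(c(0, 12, 24), c(3, 3, 3)), 0)
  # OLS oracle on a noisy linear series
  set.seed(1)
  tt <- seq(0, 24, by = 2)
  cc <- 5 + 0.02 * tt + rnorm(length(tt), 0, 0.01)
  expect_equal(linear_rate(tt, cc),
               unname(coef(lm(cc ~ tt))[2]) * 24, tolerance = 1e-12)
  expect_error(linear_rate(0, 1), "2 time points")
  expect_error(linear_rate(c(0, 0), c(1, 2)), "increasing")
})

test_that("DIC-core benthic GPP combines dark respiration and light drawdown", {
  dark <- incubation_record("dic_core", 1, c(0, 24), c(10, 10.5), FALSE,
                            volume_L = 1, footprint_m2 = 0.005)
  light <- incubation_record("dic_core", 1, c(0, 24), c(10, 9.8), TRUE,
                             volume_L = 1, footprint_m2 = 0.005)
  expect_equal(benthic_gpp_dic(light, dark), 140)  # R 100, net -40
  expect_equal(benthic_gpp_dic(dark, dark), 0)
  wrong_depth <- incubation_record("dic_core", 2, c(0, 24), c(10, 10.5),
                                   FALSE, volume_L = 1, footprint_m2 = 0.005)
  expect_error(benthic_gpp_dic(light, wrong_depth), "same depth")
})

test_that("dome benthic GPP reconstructs GPP as NEP + R with O2-to-C conversion", {
  # dark decline 0.3 mg/L over the 6 h dark window; 24 h net gain 0.6 mg/L
  rec <- incubation_record("dome", 1.5, c(0, 18, 21, 24),
                           c(9, 9.9, 9.75, 9.6), TRUE,
                           volume_L = 20, footprint_m2 = 0.1,
                           dark_start = 18, dark_end = 24)
  expect_equal(benthic_gpp_dome(rec, pq = 1), 135)
  expect_equal(benthic_gpp_dome(rec, pq = 1.2), 135 / 1.2)
  flat <- incubation_record("dome", 1.5, c(0, 18, 24), c(9, 9, 9), TRUE,
                            volume_L = 20, footprint_m2 = 0.1,
                            dark_start = 18, dark_end = 24)
  expect_equal(benthic_gpp_dome(flat), 0)
  # O2 rising in the dark clamps R with a warning
  rising <- incubation_record("dome", 1.5, c(0, 18, 21, 24),
                              c(9, 9.9, 9.95, 10.0), TRUE,
                              volume_L = 20, footprint_m2 = 0.1,
                              dark_start = 18, dark_end = 24)
  expect_warning(g <- benthic_gpp_dome(rising), "clamped")
  expect_equal(g, 1.0 / 1 * 200 * (12 / 32))   # NEP only
  expect_error(benthic_gpp_dome(flat, pq = 0), "pq")
})

test_that("pelagic daily GPP is dark-corrected and PAR-scaled", {
  expect_equal(pelagic_gpp_daily(8, 0.5, 6, 24), 30)
  expect_equal(pelagic_gpp_daily(5, 5, 6, 24), 0)
  expect_warning(g <- pelagic_gpp_daily(1, 2, 6, 24), "floored")
  expect_equal(g, 0)
  expect_error(pelagic_gpp_daily(-1, 0, 6, 24), "non-negative")
})

test_that("benthic upscaling integrates rates over sediment area", {
  cone <- cone_hypso()
  uni <- depth_rates("benthic", c(1, 5, 9), c(100, 100, 100))
  expect_equal(upscale_benthic(uni, cone), 100, tolerance = 1e-9)
  # linear rate profile vs brute-force fine-grid oracle
  lin <- depth_rates("benthic", c(0, 10), c(200, 0))
  zz <- seq(0, 10, length.out = 10001)
  rate <- approx(c(0, 10), c(200, 0), xout = zz)$y
  a <- area_at(cone, zz)
  mid_rate <- (rate[-1] + rate[-length(rate)]) / 2
  oracle <- sum(mid_rate * (a[-length(a)] - a[-1])) / cone$a0
  expect_equal(upscale_benthic(lin, cone, n_strata = 10000L), oracle,
               tolerance = 1e-6)
  # refinement invariance (Richardson check)
  expect_equal(upscale_benthic(lin, cone, n_strata = 100L),
               upscale_benthic(lin, cone, n_strata = 10000L),
               tolerance = 1e-3)
  expect_error(upscale_benthic(depth_rates("benthic", 2, 50), cone),
               ">= 2 depths")
})

test_that("pelagic upscaling weights rates by volume", {
  box <- box_hypso(a0 = 100, zmax = 2)
  uni <- depth_rates("pelagic", c(0, 2), c(10, 10))
  expect_equal(upscale_pelagic(uni, box), 10 * box$z_avg, tolerance = 1e-12)
  # uniform rate identity holds on any basin: rate * z_avg
  set.seed(11)
  for (i in 1:10) {
    hy <- random_hypso()
    u <- depth_rates("pelagic", c(0, hy$z_max), c(7, 7))
    expect_equal(upscale_pelagic(u, hy), 7 * hy$z_avg, tolerance = 1e-9)
  }
  # exponentially decaying production vs fine-grid oracle
  cone <- cone_hypso()
  zr <- c(0, 0.5, 1, 2, 4, 8)
  dec <- depth_rates("pelagic", zr, 50 * exp(-0.8 * zr))
  zz <- sort(unique(c(seq(0, 10, length.out = 20001), zr)))
  rate <- approx(zr, 50 * exp(-0.8 * zr), xout = zz, rule = 2)$y
  g <- rate * area_at(cone, zz)
  oracle <- sum(diff(zz) * (g[-1] + g[-length(g)]) / 2) / cone$a0
  expect_equal(upscale_pelagic(dec, cone, n_strata = 10000L), oracle,
               tolerance = 1e-6)
})

test_that("lake productivity combines habitats and flags edge cases", {
  lp <- lake_productivity(300, 100)
  expect_equal(lp$total_avg, 400)
  expect_equal(lp$structuring, 75)
  expect_equal(lake_productivity(0, 50)$structuring, 0)
  miss <- lake_productivity(50, NA)
  expect_true("missing_pelagic" %in% miss$flags)
  expect_true(is.na(miss$total_avg))
  zero <- lake_productivity(0, 0)
  expect_true("structuring_undefined" %in% zero$flags)
  expect_error(lake_productivity(-1, 5), "non-negative")
})

test_that("estimators invert their noise-free forward models exactly", {
  true_b <- depth_rates("benthic", c(0.5, 1.5, 3), c(140, 90, 35))
  recs <- generate_incubations(true_b, "dic_core", noise_sd = 0)
  for (i in seq_along(true_b$depth_m)) {
    est <- benthic_gpp_dic(recs[[2 * i - 1]], recs[[2 * i]])
    expect_equal(est, true_b$rate[i], tolerance = 1e-9)
  }
  domes <- generate_incubations(true_b, "dome", noise_sd = 0)
  for (i in seq_along(true_b$depth_m)) {
    expect_equal(benthic_gpp_dome(domes[[i]]), true_b$rate[i],
                 tolerance = 1e-9)
  }
  true_p <- depth_rates("pelagic", c(0, 1, 3), c(30, 18, 4))
  c14 <- generate_incubations(true_p, "c14_bottle", noise_sd = 0)
  est <- mapply(pelagic_gpp_daily, c14$light_uptake, c14$dark_uptake,
                c14$par_inc, c14$par_daily)
  expect_equal(unname(est), true_p$rate, tolerance = 1e-9)
  expect_error(generate_incubations(true_b, "osmotic"), "arg")
})

test_that("14C Monte-Carlo estimator mean is within 2 % at 5 % noise", {
  true_p <- depth_rates("pelagic", c(0, 1, 2), c(40, 20, 8))
  set.seed(314)
  means <- replicate(100, {
    c14 <- generate_incubations(true_p, "c14_bottle", noise_sd = 0.05)
    mean(mapply(pelagic_gpp_daily, c14$light_uptake, c14$dark_uptake,
                c14$par_inc, c14$par_daily))
  })
  expect_lt(abs(mean(means) - mean(true_p$rate)) / mean(true_p$rate), 0.02)
})
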