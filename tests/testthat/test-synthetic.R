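test_that("PAR profile forward model is exact without noise", {
  p <- generate_par_profile(1.0, 1000, c(0, 1, 2), noise_sd = 0)
  expect_equal(p$par, c(1000, 367.88, 135.34), tolerance = 1e-4)
  expect_error(generate_par_profile(0, 1000, 0:2), "true_kd")
  expect_error(generate_par_profile(1, -5, 0:2), "surface_par")
})

test_that("identical seeds give byte-identical bundles", {
  b1 <- generate_landscape(3, biome_mix = c(arctic = 1, subarctic = 0,
                                            boreal = 0), seed = 7)
  b2 <- generate_landscape(3, biome_mix = c(arctic = 1, subarctic = 0,
                                            boreal = 0), seed = 7)
  expect_identical(b1$lakes, b2$lakes)
  expect_identical(b1$incubations, b2$incubations)
  expect_identical(b1$par_profiles, b2$par_profiles)
  expect_identical(b1$grids, b2$grids)
  b3 <- generate_landscape(3, biome_mix = c(arctic = 1, subarctic = 0,
                                            boreal = 0), seed = 8)
  expect_false(identical(b1$lakes$doc, b3$lakes$doc))
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_landscape(2), "at least 3")
  expect_error(generate_landscape(5, biome_mix = c(arctic = 0.5,
                                                   subarctic = 0.2,
                                                   boreal = 0.2)), "sum to 1")
  expect_error(generate_landscape(5, biome_mix = c(a = 0.5, b = 0.5)),
               "named")
})

test_that("default 26-lake bundle spans the documented chemistry ranges", {
  b <- generate_landscape(26, seed = 1, grids = FALSE)
  l <- b$lakes
  # DOC roughly 1.5-16.3 mg/L, Kd roughly 0.3-4.1 1/m (range emulation)
  expect_gt(min(l$doc), 0.8)
  expect_lt(max(l$doc), 22)
  expect_gt(max(l$doc), 10)
  expect_lt(min(l$doc), 3)
  expect_gt(min(l$kd), 0.1)
  expect_lt(max(l$kd), 5)
  expect_true(all(l$co2 > 0.03 & l$co2 < 2.6))
  expect_true(all(l$ph >= 5.3 & l$ph <= 7.8))
  expect_true(all(l$z_max >= 2 & l$z_max <= 15.8))
  expect_true(all(l$structuring >= 0 & l$structuring <= 100, na.rm = TRUE))
  # biome composition of the default mix
  expect_equal(unname(table(l$biome)[c("arctic", "subarctic", "boreal")]),
               c(11L, 6L, 9L), ignore_attr = TRUE)
  # two lakes without pelagic data, one flagged outlier
  expect_equal(sum(!l$pelagic_measured), 2L)
  expect_equal(sum(l$outlier), 1L)
  expect_identical(l$biome[l$outlier], "boreal")
})

test_that("generated chemistry is self-consistent with carbonate speciation", {
  b <- generate_landscape(10, seed = 4, grids = FALSE)
  l <- b$lakes
  for (i in seq_len(nrow(l))) {
    st <- speciate(l$dic[i], l$ph[i], l$t_water[i])
    expect_equal(st$co2, l$co2[i], tolerance = 1e-9)
  }
  # hypsography tables rebuild into consistent basin objects
  for (lk in l$lake_id) {
    hy <- b$hypso[[lk]]
    expect_equal(hy$z_avg, l$z_avg[l$lake_id == lk], tolerance = 1e-9)
    expect_equal(littoral_fraction(hy, l$kd[l$lake_id == lk]),
                 l$a_littoral[l$lake_id == lk], tolerance = 1e-9)
  }
})

test_that("switches remove the outlier and missing-pelagic lakes", {
  b <- generate_landscape(12, seed = 5, grids = FALSE,
                          include_outlier = FALSE, missing_pelagic = 0)
  expect_equal(sum(b$lakes$outlier), 0L)
  expect_true(all(b$lakes$pelagic_measured))
})

test_that("bundles round-trip through write_bundle/read_bundle", {
  b <- generate_landscape(4, seed = 6, grids = TRUE)
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$lakes$doc, b$lakes$doc, tolerance = 1e-12)
  expect_equal(b2$seed, 6L)
  expect_equal(nrow(b2$incubations), nrow(b$incubations))
  expect_equal(b2$grids[[1]]$dem$data, b$grids[[1]]$dem$data,
               tolerance = 1e-6)
  expect_equal(names(b2$hypso), b$lakes$lake_id)
  unlink(dir, recursive = TRUE)
})

test_that("bundle rasters delineate to the intended catchment area", {
  b <- generate_landscape(3, seed = 9,
                          biome_mix = c(arctic = 0, subarctic = 0,
                                        boreal = 1), grids = TRUE)
  g <- b$grids[[1]]
  del <- delineate_catchment(g$dem, g$lake_mask)
  # whole synthetic basin drains to the central lake
  expect_equal(del$a_catchment_ha, b$lakes$a_catchment_ha[1],
               tolerance = 0.01)
  fr <- cover_fractions(g$cover, del$mask, default_reclass(),
                        incidental_threshold = 0)
  expect_lte(sum(fr), 1 + 1e-9)
})
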