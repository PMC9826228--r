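test_that("depression filling raises pits to their spill elevation", {
  dem <- plane_dem()
  expect_equal(fill_depressions(dem)$data, dem$data)  # already drains
  z <- dem$data
  z[4, 3] <- 0  # single interior pit
  pit <- terrain_grid(z, dem$cellsize)
  filled <- fill_depressions(pit)$data
  spill <- min(z[3:5, 2:4][-5])  # lowest neighbour
  expect_equal(filled[4, 3], spill)
  idx <- (3 - 1) * 8 + 4         # linear index of the pit
  expect_equal(filled[-idx], z[-idx])
  expect_error(fill_depressions(terrain_grid(matrix(NA_real_, 3, 3), 1)),
               "no-data")
})

test_that("random DEMs have zero pits after filling (pit-scan oracle)", {
  set.seed(5)
  for (i in 1:5) {
    z <- matrix(runif(100, 0, 10), 10, 10)
    filled <- fill_depressions(terrain_grid(z, 2))$data
    # exhaustive scan: every interior cell has a neighbour not above it
    for (r in 2:9) for (cc in 2:9) {
      nb <- filled[(r - 1):(r + 1), (cc - 1):(cc + 1)][-5]
      expect_true(min(nb) <= filled[r, cc])
    }
    expect_true(all(filled >= z))
  }
})

test_that("D8 accumulation matches closed form on a plane and an oracle", {
  dem <- plane_dem(nr = 8, nc = 6)
  acc <- flow_accumulation_d8(dem)$data
  # steepest descent is due south: accumulation equals the row index
  expect_equal(acc, outer(1:8, rep(1, 6)))
  # mass conservation: southern boundary carries every cell exactly once
  expect_equal(sum(acc[8, ]), 8 * 6)
  # brute-force oracle on a jittered (flat-free, depression-free) surface
  set.seed(9)
  z <- outer(seq(40, 5, length.out = 8), rep(1, 7)) +
    matrix(runif(56, 0, 0.3), 8, 7)
  z <- fill_depressions(terrain_grid(z, 5))$data
  acc2 <- flow_accumulation_d8(terrain_grid(z, 5))$data
  expect_equal(acc2, oracle_accumulation(z, 5))
  expect_error(flow_accumulation_d8(terrain_grid(matrix(c(
    5, 5, 5, 5, 1, 5, 5, 5, 5), 3, 3), 1)), "unfilled")
})

test_that("catchment delineation finds contributing cells", {
  bowl <- bowl_dem()
  mask <- central_mask()
  del <- delineate_catchment(bowl, mask)
  expect_true(all(del$mask$data == 1))       # whole bowl drains to the lake
  expect_equal(del$a_catchment_ha, 81 * 25 / 1e4)
  # ridge: terrain slopes away from the lake, only the lake itself remains
  ridge <- terrain_grid(200 - bowl$data, bowl$cellsize)
  del2 <- delineate_catchment(ridge, mask)
  expect_equal(del2$mask$data == 1, mask$data == 1)
  # flood-fill oracle on the bowl: catchment mask is flow-closed
  expect_true(all(del$mask$data >= mask$data))
  expect_error(delineate_catchment(bowl, terrain_grid(matrix(0, 9, 9), 5)),
               "empty")
})

test_that("TWI matches the analytic solution on an inclined plane", {
  expect_equal(log((100) / 0.1), 6.908, tolerance = 1e-3)  # formula anchor
  dem <- plane_dem(nr = 8, nc = 6, slope = 0.1, cellsize = 10)
  acc <- flow_accumulation_d8(dem)
  tw <- twi(dem, acc)
  # row r: a = r * cellsize, tan beta = 0.1; the bottom row has no in-grid
  # downhill neighbour and falls back to the slope floor
  for (r in 1:7) {
    expect_equal(tw$grid$data[r, 3], log(r * 10 / 0.1), tolerance = 1e-9)
  }
  expect_equal(tw$grid$data[8, 3], log(8 * 10 / 1e-4), tolerance = 1e-9)
  # flats stay finite through the slope floor
  flat <- terrain_grid(matrix(5, 4, 4), 1)
  accf <- flow_accumulation_d8(flat)
  expect_true(all(is.finite(twi(flat, accf)$grid$data)))
  # mean TWI invariant to a constant elevation shift
  dem2 <- terrain_grid(dem$data + 100, dem$cellsize)
  expect_equal(twi(dem2, acc)$mean, tw$mean, tolerance = 1e-12)
})

test_that("cover fractions reclassify, mask and drop incidental classes", {
  codes <- matrix(c(rep(5, 60), rep(2, 30), rep(1, 10)), 10, 10)
  mask <- terrain_grid(matrix(1, 10, 10), 10)
  fr <- cover_fractions(terrain_grid(codes, 10), mask, default_reclass(),
                        incidental_threshold = 5)
  expect_equal(fr[["coniferous forest"]], 0.6)
  expect_equal(fr[["wetland"]], 0.3)
  expect_equal(fr[["water"]], 0.1)
  # a 4 % incidental class is excluded at the 5 % threshold
  codes[1, 1:4] <- 6
  fr2 <- cover_fractions(terrain_grid(codes, 10), mask, default_reclass())
  expect_false("temporarily deforested" %in% names(fr2))
  expect_lte(sum(fr2), 1)
  codes[1, 1] <- 99
  expect_error(cover_fractions(terrain_grid(codes, 10), mask,
                               default_reclass()), "unmapped")
})

test_that("hydrology metrics and lapse adjustment are exact arithmetic", {
  h <- hydrology_metrics(1e6, 1e7, 1e5, 500)
  expect_equal(h$discharge_m3_yr, 5e6)
  expect_equal(h$hrt_yr, 0.2)
  expect_equal(h$dr, 100)
  expect_equal(hydrology_metrics(1e6, 1e7, 1e5, 1000)$hrt_yr, 0.1)
  expect_equal(hydrology_metrics(1e6, 1e5, 1e5, 500)$dr, 1)
  expect_error(hydrology_metrics(1e6, 1e7, 1e5, 0), "runoff")
  expect_equal(lapse_adjust(14, 300, 600), 12.29)
  expect_equal(lapse_adjust(14, 300, 300), 14)
  expect_gt(lapse_adjust(14, 600, 300), 14)
})

test_that("ESRI ASCII grids round-trip through write/read", {
  g <- terrain_grid(matrix(c(1.5, 2, NA, 4, 5, 6), 2, 3), 2.5, xll = 10,
                    yll = 20)
  f <- tempfile(fileext = ".asc")
  write_grid_asc(g, f)
  g2 <- read_grid_asc(f)
  expect_equal(g2$data, g$data)
  expect_equal(g2$cellsize, 2.5)
  expect_equal(g2$xll, 10)
  expect_error(read_grid_asc(tempfile()), "no such file")
  unlink(f)
})
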