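#' Generate a noisy Beer-Lambert PAR depth profile
#'
#' Forward model for light-profile measurements: exponential decay from the
#' surface value with multiplicative log-normal noise.  With `noise_sd = 0`
#' the profile is exactly `surface_par * exp(-true_kd * z)`.
#'
#' @param true_kd True attenuation coefficient (m^-1), positive.
#' @param surface_par Surface PAR (umol m^-2 s^-1), positive.
#' @param depths Measurement depths (m), non-negative.
#' @param noise_sd Relative (log-scale) noise standard deviation.
#' @param seed Optional seed for reproducibility.
#' @return Data frame with `depth_m` and `par`.
#' @export
generate_par_profile <- function(true_kd, surface_par, depths,
                                 noise_sd = 0, seed = NULL) {
  if (true_kd <= 0) stop("true_kd must be positive")
  if (surface_par <= 0) stop("surface_par must be positive")
  if (any(depths < 0)) stop("depths must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  par <- surface_par * exp(-true_kd * depths)
  if (noise_sd > 0) {
    par <- par * exp(stats::rnorm(length(depths), 0, noise_sd))
  }
  data.frame(depth_m = depths, par = par)
}

# default enclosure geometries (volume L, sediment footprint m2)
.ls_geometry <- list(dic_core = list(volume_L = 0.8, footprint_m2 = 0.004),
                     dome = list(volume_L = 20, footprint_m2 = 0.1))

#' Forward-model incubation series from true GPP depth rates
#'
#' Produces the raw enclosure data that the corresponding estimator in the
#' metabolism module inverts: paired light/dark DIC core series
#' (`dic_core`), 24-h dome O2 series with an explicit dark window
#' (`dome`), or 14C light/dark bottle uptakes with PAR sums
#' (`c14_bottle`).  At `noise_sd = 0` every estimator returns the true
#' rates exactly (round-trip identity).
#'
#' @param true_rates A [depth_rates()] profile: areal mg C m^-2 d^-1 for
#'   benthic methods, volumetric mg C m^-3 d^-1 for `c14_bottle`.
#' @param method `"dic_core"`, `"dome"` or `"c14_bottle"`.
#' @param geometry List with `volume_L` and `footprint_m2` (benthic
#'   methods); defaults are a 0.8 L sediment core of 0.004 m^2 and a 20 L
#'   dome over 0.1 m^2.
#' @param noise_sd Relative measurement noise per reading.
#' @param seed Optional seed.
#' @param respiration_ratio True respiration as a fraction of GPP plus the
#'   `respiration_base` offset (mg m^-2 d^-1); shapes the dark series only.
#' @param respiration_base See `respiration_ratio`.
#' @param pq Photosynthetic quotient used by the dome forward model.
#' @param light_hours Length of the lit period in the dome deployment (h).
#' @param par_inc,par_daily Incubation-window and daily PAR sums used by
#'   the 14C forward model (mol m^-2).
#' @param dark_uptake True dark-bottle uptake (mg C m^-3) for 14C.
#' @return For benthic methods a list of [incubation_record()]s; for
#'   `c14_bottle` a data frame with `depth_m`, `light_uptake`,
#'   `dark_uptake`, `par_inc`, `par_daily`.
#' @export
generate_incubations <- function(true_rates, method,
                                 geometry = NULL, noise_sd = 0, seed = NULL,
                                 respiration_ratio = 0.6,
                                 respiration_base = 20, pq = 1,
                                 light_hours = 18,
                                 par_inc = 10, par_daily = 40,
                                 dark_uptake = 0.3) {
  stopifnot(inherits(true_rates, "depth_rates"))
  method <- match.arg(method, c("dic_core", "dome", "c14_bottle"))
  if (!is.null(seed)) set.seed(seed)
  # multiplicative noise for uptake quantities; for concentration series the
  # noise is additive and referenced to the series' dynamic range (an
  # instrument resolves the *change*, not a fraction of the absolute value)
  jitter <- function(x) {
    if (noise_sd > 0) x * (1 + stats::rnorm(length(x), 0, noise_sd)) else x
  }
  jitter_series <- function(x) {
    if (noise_sd == 0) return(x)
    x + stats::rnorm(length(x), 0, noise_sd * diff(range(x)))
  }
  if (method == "c14_bottle") {
    if (true_rates$habitat != "pelagic") {
      stop("c14_bottle expects a pelagic (volumetric) rate profile")
    }
    scaling <- par_daily / par_inc
    light <- true_rates$rate / scaling + dark_uptake
    return(data.frame(depth_m = true_rates$depth_m,
                      light_uptake = jitter(light),
                      dark_uptake = jitter(rep(dark_uptake,
                                               length(true_rates$depth_m))),
                      par_inc = par_inc, par_daily = par_daily))
  }
  if (true_rates$habitat != "benthic") {
    stop(method, " expects a benthic (areal) rate profile")
  }
  if (is.null(geometry)) geometry <- .ls_geometry[[method]]
  va <- geometry$volume_L / geometry$footprint_m2
  out <- list()
  for (i in seq_along(true_rates$depth_m)) {
    z <- true_rates$depth_m[i]
    g_areal <- true_rates$rate[i]
    r_areal <- respiration_ratio * g_areal + respiration_base
    if (method == "dic_core") {
      dic0 <- 2
      g_vol <- g_areal / va
      r_vol <- r_areal / va
      tt <- c(0, 24)
      light <- incubation_record("dic_core", z, tt,
                                 jitter_series(c(dic0, dic0 + r_vol - g_vol)),
                                 light = TRUE, volume_L = geometry$volume_L,
                                 footprint_m2 = geometry$footprint_m2)
      dark <- incubation_record("dic_core", z, tt,
                                jitter_series(c(dic0, dic0 + r_vol)),
                                light = FALSE, volume_L = geometry$volume_L,
                                footprint_m2 = geometry$footprint_m2)
      out <- c(out, list(light, dark))
    } else {
      g_o2_vol <- g_areal * (32 / 12) * pq / va
      r_o2_vol <- r_areal * (32 / 12) * pq / va
      tt <- seq(0, 24, by = 0.5)
      o2 <- 9 + g_o2_vol * pmin(tt, light_hours) / light_hours -
        r_o2_vol * tt / 24
      rec <- incubation_record("dome", z, tt, jitter_series(o2), light = TRUE,
                               volume_L = geometry$volume_L,
                               footprint_m2 = geometry$footprint_m2,
                               dark_start = light_hours, dark_end = 24)
      out <- c(out, list(rec))
    }
  }
  out
}

# power-law basin A(z) = A0 (1 - z/z_max)^p with z_max = z_avg (p + 1);
# z_max clamped to the realistic 2-15.8 m span of small shallow lakes
.make_hypso <- function(z_avg, p_shape, a0, n_rows = 25L) {
  zmax <- min(max(z_avg * (p_shape + 1), 2), 15.8)
  pexp <- zmax / z_avg - 1
  d <- seq(0, zmax, length.out = n_rows)
  hypsography(d, a0 * (1 - d / zmax)^pexp)
}

# true benthic/pelagic depth-rate profiles scaled to hit target
# lake-average GPP through the package's own upscaling operators
.true_profiles <- function(hypso, kd, benthic_avg, pelagic_avg,
                           surface_par = 1200, ik = 100) {
  z1 <- log(100) / kd
  nb <- if (hypso$z_max > 8) 5L else 3L
  zb <- seq(0.5, max(1.2, min(hypso$z_max * 0.9, z1 * 1.2)),
            length.out = nb)
  shape_b <- function(z) {
    p <- surface_par * exp(-kd * z)
    p / (p + ik)
  }
  rb <- depth_rates("benthic", zb, shape_b(zb))
  bmax <- benthic_avg / upscale_benthic(rb, hypso)
  rb$rate <- rb$rate * bmax
  zp <- unique(c(0, 0.25, 0.5,
                 seq_len(max(1L, floor(min(hypso$z_max - 0.1, max(1, z1)))))))
  zp <- zp[zp < hypso$z_max]
  shape_p <- exp(-0.7 * kd * zp)
  rp <- depth_rates("pelagic", zp, shape_p)
  if (!is.na(pelagic_avg)) {
    pmax_ <- pelagic_avg / upscale_pelagic(rp, hypso)
    rp$rate <- rp$rate * pmax_
  } else {
    rp <- NULL
  }
  list(benthic = rb, pelagic = rp)
}

# synthetic DEM / land-cover / lake-mask rasters for one lake: a closed
# basin whose whole grid drains to the central lake
.make_lake_grids <- function(a_catch_m2, a0, elevation, cover_target) {
  g <- 36L
  cs <- sqrt(a_catch_m2) / g
  ctr <- (g + 1) / 2
  rr <- matrix(rep(seq_len(g), g), g, g)
  cc <- t(rr)
  dist <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  r_lake <- min(g / 3, sqrt(a0 / pi) / cs)
  lake <- dist <= r_lake
  dem <- elevation + pmax(dist - r_lake, 0) * cs * 0.04 +
    matrix(stats::runif(g * g, 0, cs * 0.004), g, g)
  dem[lake] <- elevation
  codes <- as.integer(names(default_reclass()))
  names(cover_target) <- NULL
  cov <- matrix(sample(codes, g * g, replace = TRUE, prob = cover_target),
                g, g)
  cov[lake] <- 1L
  list(dem = terrain_grid(dem, cs),
       cover = terrain_grid(cov, cs),
       lake_mask = terrain_grid(lake + 0, cs))
}

#' Generate a seeded synthetic lake-landscape dataset
#'
#' Draws `n_lakes` lakes across the three biomes, propagates land cover
#' through hydrology and water chemistry to benthic, pelagic and total GPP
#' with a recursive structural model on fixed working scales (see
#' [true_path_edges()] and the methods vignette), and emits every raw table
#' the analysis pipeline consumes: lake/catchment metadata, epilimnion
#' chemistry, PAR depth profiles, hypsography, benthic incubation series
#' (DIC cores in the Arctic and boreal, O2 domes in the subarctic), 14C
#' bottle uptakes, and optionally small DEM/cover/lake-mask rasters.
#' Chemistry is self-consistent: DIC is back-computed from the generated
#' CO2, pH and temperature so carbonate speciation reproduces the generated
#' CO2 exactly, and the hydraulic retention time derives from the lake
#' volume, runoff and drainage ratio (plus small reporting noise).
#'
#' Two lakes lack pelagic measurements and one boreal lake is a deliberate
#' high-leverage outlier (very shallow, warm, DOC- and CO2-rich), both
#' switchable off.
#'
#' @param n_lakes Number of lakes (>= 3), default 26.
#' @param biome_mix Named fractions over `arctic`, `subarctic`, `boreal`
#'   summing to 1; default 11/26, 6/26, 9/26.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param measurement_noise Relative noise on raw measurement channels
#'   (PAR readings, incubation series, 14C uptakes); the tabulated
#'   chemistry is noise-free.  Default 0.05.
#' @param include_outlier Include the high-leverage boreal outlier lake.
#' @param missing_pelagic Number of lakes (0-2) without pelagic data.
#' @param grids Generate rasters per lake; default only for bundles of at
#'   most 30 lakes.
#' @param replicates Number of replicate enclosures per benthic depth.
#' @param measurements Generate the measurement-level tables (PAR
#'   profiles, incubations, 14C).  Disable for large purely-structural
#'   bundles; the lake table is identical either way under the same seed.
#' @return A `lake_bundle` list: data frames `lakes`, `chemistry`,
#'   `par_profiles`, `hypsography`, `incubations`, `c14`; `hypso` (list of
#'   [hypsography()] objects), `grids` (or NULL), and `truth` (generating
#'   edges, residual SDs, per-lake true Kd, rate profiles and lake-average
#'   GPP).
#' @export
generate_landscape <- function(n_lakes = 26L,
                               biome_mix = NULL,
                               seed = 1L,
                               measurement_noise = 0.05,
                               include_outlier = TRUE,
                               missing_pelagic = 2L,
                               grids = NULL,
                               replicates = 2L,
                               measurements = TRUE) {
  if (n_lakes < 3L) stop("n_lakes must be at least 3")
  if (is.null(biome_mix)) biome_mix <- .ls_default_mix
  if (is.null(names(biome_mix)) ||
      !setequal(names(biome_mix), names(.ls_biomes))) {
    stop("biome_mix must be named over arctic, subarctic, boreal")
  }
  if (abs(sum(biome_mix) - 1) > 1e-8) stop("biome_mix must sum to 1")
  if (is.null(grids)) grids <- n_lakes <= 30L
  set.seed(as.integer(seed))

  mix <- biome_mix[names(.ls_biomes)]
  counts <- floor(mix * n_lakes)
  while (sum(counts) < n_lakes) {
    i <- which.max(mix * n_lakes - counts)
    counts[i] <- counts[i] + 1L
  }
  biome <- rep(names(counts), counts)
  n <- length(biome)
  id <- sprintf("L%03d", seq_len(n))
  bi <- .ls_biomes[biome]
  rn <- function(mu, sd) stats::rnorm(n, mu, sd)
  cf <- .ls_coef
  rs <- .ls_resid

  ## exogenous landscape draws
  wet_mu <- vapply(bi, function(b) b$cover[["wetland"]], 0)
  con_mu <- vapply(bi, function(b) b$cover[["coniferous"]], 0)
  wetland <- pmin(pmax(wet_mu + rn(0, 0.08), 0.005), 0.9)
  conif <- pmin(pmax(con_mu + rn(0, 0.10), 0.005), 0.9)
  wet_z <- .to_z("wetland", wetland)
  con_z <- .to_z("coniferous", conif)
  elev <- vapply(bi, function(b) stats::runif(1, b$elevation[1], b$elevation[2]), 0)
  tw_z <- rn(vapply(bi, function(b) b$t_water_mu, 0), 0.6)
  t_water <- .from_z("t_water", tw_z)
  dr_z <- rn(vapply(bi, function(b) b$dr_mu, 0), 0.8)
  dr <- .from_z("dr", dr_z)
  zavg_z0 <- rn(0, 1)
  z_avg0 <- pmin(pmax(.from_z("z_avg", zavg_z0), 1.2), 7)

  ## structural chain: hydrology
  ry_z <- cf$r_yearly[["wetland"]] * wet_z +
    cf$r_yearly[["coniferous"]] * con_z + rn(0, rs[["r_yearly"]])
  r_yearly <- pmin(pmax(.from_z("r_yearly", ry_z), 150), 1500)
  ry_z <- .to_z("r_yearly", r_yearly)
  twi_z <- cf$twi[["wetland"]] * wet_z + rn(0, rs[["twi"]])
  twi_nat <- .from_z("twi", twi_z)

  ## chemistry
  e_doc <- rn(0, rs[["doc"]])

  ## outlier: one shallow, warm, DOC/CO2-rich boreal lake
  outlier <- rep(FALSE, n)
  if (include_outlier && any(biome == "boreal")) {
    i_out <- which(biome == "boreal")[1L]
    outlier[i_out] <- TRUE
    z_avg0[i_out] <- 1.25
    zavg_z0[i_out] <- .to_z("z_avg", 1.25)
    t_water[i_out] <- max(t_water[i_out], 19)
    tw_z[i_out] <- .to_z("t_water", t_water[i_out])
    e_doc[i_out] <- abs(e_doc[i_out]) + 0.8
  }

  ## hypsography first pass needs doc/kd; hrt needs realized z_avg, so
  ## generate chemistry with the target z_avg then build basins
  hrt_note <- exp(stats::rnorm(n, 0, 0.10))  # reporting noise on HRT
  a0 <- pmin(pmax(exp(log(8e4) + 0.8 * rn(0, 1)), 1e4), 1e6)
  a_catch <- dr * a0

  # provisional hrt with target z_avg (recomputed after basin construction)
  hrt_of <- function(zv) zv / ((r_yearly / 1000) * dr) * hrt_note
  hrt_z <- .to_z("hrt", hrt_of(z_avg0))
  doc_z <- cf$doc[["wetland"]] * wet_z + cf$doc[["coniferous"]] * con_z +
    cf$doc[["hrt"]] * hrt_z + cf$doc[["r_yearly"]] * ry_z + e_doc
  doc <- pmin(pmax(.from_z("doc", doc_z), 1.0), 20)
  doc_z <- .to_z("doc", doc)
  kd_z <- cf$kd[["doc"]] * doc_z + cf$kd[["r_yearly"]] * ry_z +
    rn(0, rs[["kd"]])
  kd <- pmin(pmax(.from_z("kd", kd_z), 0.15), 5)
  kd_z <- .to_z("kd", kd)
  co2_z <- cf$co2[["twi"]] * twi_z + cf$co2[["r_yearly"]] * ry_z +
    .ls_boreal_doc_co2 * e_doc * (biome == "boreal") + rn(0, rs[["co2"]])
  co2 <- pmin(pmax(.from_z("co2", co2_z), 0.05), 2.5)
  co2_z <- .to_z("co2", co2)

  ## pH tracks the CO2 load (CO2-rich waters are acid); DIC follows from
  ## CO2, pH and temperature through the carbonate ionization fraction, so
  ## downstream speciation reproduces the generated CO2 exactly
  ph <- pmin(pmax(vapply(bi, function(b) b$ph, 0) - 0.45 * co2_z +
                    rn(0, 0.2), 5.3), 7.8)
  dic <- tn <- tp <- numeric(n)
  for (i in seq_len(n)) {
    st <- speciate(1, ph[i], t_water[i])
    dic[i] <- co2[i] / st$co2          # alpha0 share of unit DIC
  }
  tn <- exp(log(180) + 0.45 * (0.8 * doc_z + rn(0, 0.6)))
  tp <- exp(log(10) + 0.50 * (0.7 * doc_z + rn(0, 0.7)))

  ## basins: mean depth from the exogenous draw, shape exponent drawn
  ## independently; the littoral fraction is then a derived quantity
  p_shape <- exp(rn(log(1.5), 0.35))
  hypso <- vector("list", n)
  names(hypso) <- id
  z_avg <- zmax <- volume <- alit <- numeric(n)
  for (i in seq_len(n)) {
    hypso[[i]] <- .make_hypso(z_avg0[i], p_shape[i], a0[i])
    z_avg[i] <- hypso[[i]]$z_avg
    zmax[i] <- hypso[[i]]$z_max
    volume[i] <- hypso[[i]]$volume_m3
    alit[i] <- littoral_fraction(hypso[[i]], kd[i])
  }
  zavg_z <- .to_z("z_avg", z_avg)
  alit_z <- .to_z("a_littoral", alit)
  hrt <- hrt_of(z_avg)
  hrt_z <- .to_z("hrt", hrt)

  ## productivity
  st_z <- cf$structuring[["a_littoral"]] * alit_z +
    cf$structuring[["co2"]] * co2_z + cf$structuring[["z_avg"]] * zavg_z +
    rn(0, rs[["structuring"]])
  structuring <- .from_z("structuring", st_z)
  q <- .ls_quad
  zvals <- list(intercept = 1, wetland = wet_z, coniferous = con_z,
                r_yearly = ry_z, twi = twi_z, dr = dr_z, hrt = hrt_z,
                z_avg = zavg_z, doc = doc_z, kd = kd_z, co2 = co2_z,
                t_water = tw_z, a_littoral = alit_z, structuring = st_z)
  proj <- Reduce(`+`, Map(function(w, v) w * v, as.list(q$ortho),
                          zvals[names(q$ortho)]))
  quad <- q$gamma * ((doc_z - q$v0)^2 - proj)
  gpp_z <- cf$total_gpp[["kd"]] * kd_z + cf$total_gpp[["doc"]] * doc_z +
    cf$total_gpp[["co2"]] * co2_z + cf$total_gpp[["t_water"]] * tw_z +
    cf$total_gpp[["structuring"]] * st_z + quad + rn(0, rs[["total_gpp"]])
  if (any(outlier)) gpp_z[outlier] <- gpp_z[outlier] + 1.2
  total_gpp <- .from_z("total_gpp", gpp_z)
  benthic_gpp <- total_gpp * structuring / 100
  pelagic_gpp <- total_gpp - benthic_gpp

  pelagic_measured <- rep(TRUE, n)
  if (missing_pelagic > 0L) {
    cand <- which(!outlier)
    pelagic_measured[cand[seq_len(min(missing_pelagic, length(cand)))]] <- FALSE
  }

  ## air temperature bookkeeping (station value back-computed through the
  ## lapse rate so the pipeline's adjustment reproduces t_air)
  station_elev <- c(arctic = 250, subarctic = 400, boreal = 200)[biome]
  t_air <- t_water + 1.0
  station_temp <- t_air + 0.57 * (elev - station_elev) / 100

  ## measurement-level tables
  par_profiles <- hyps_tab <- inc_tab <- c14_tab <- list()
  rates <- vector("list", n)
  names(rates) <- id
  surface_par <- 1200
  for (i in seq_len(if (measurements) n else 0L)) {
    zz <- unique(c(0, 0.25, 0.5, seq_len(max(1L, floor(zmax[i])))))
    zz <- zz[zz <= zmax[i]]
    pp <- generate_par_profile(kd[i], surface_par, zz,
                               noise_sd = measurement_noise)
    par_profiles[[i]] <- cbind(lake_id = id[i], pp)
    pr <- .true_profiles(hypso[[i]], kd[i], benthic_gpp[i],
                         if (pelagic_measured[i]) pelagic_gpp[i] else NA_real_)
    rates[[i]] <- pr
    method <- .ls_biomes[[biome[i]]]$benthic_method
    reps <- list()
    for (r in seq_len(replicates)) {
      recs <- generate_incubations(pr$benthic, method,
                                   noise_sd = measurement_noise)
      reps[[r]] <- do.call(rbind, lapply(recs, function(rec) {
        data.frame(lake_id = id[i], method = rec$method, replicate = r,
                   depth_m = rec$depth_m,
                   light_flag = ifelse(rec$light, "light", "dark"),
                   time_h = rec$times_h, value = rec$conc,
                   volume_L = rec$volume_L, footprint_m2 = rec$footprint_m2,
                   dark_start = rec$dark_start, dark_end = rec$dark_end)
      }))
    }
    inc_tab[[i]] <- do.call(rbind, reps)
    if (pelagic_measured[i]) {
      cc <- generate_incubations(pr$pelagic, "c14_bottle",
                                 noise_sd = measurement_noise)
      c14_tab[[i]] <- cbind(lake_id = id[i], cc)
    }
  }

  ## remaining cover classes: biome means with lake-to-lake variation,
  ## renormalized so all six classes sum to 1 given wetland and coniferous
  cover_mat <- do.call(rbind, lapply(bi, function(b) b$cover))
  rest <- cover_mat[, c("water", "open", "deciduous", "deforested"),
                    drop = FALSE]
  rest <- rest * matrix(exp(stats::rnorm(length(rest), 0, 0.25)),
                        nrow(rest), ncol(rest))
  rest <- rest * (1 - wetland - conif) / rowSums(rest)
  lakes <- data.frame(
    lake_id = id, biome = biome, elevation = elev,
    station_elev = station_elev, station_temp = station_temp,
    t_air = t_air,
    a_lake_m2 = a0, a_catchment_ha = a_catch / 1e4,
    r_yearly = r_yearly, twi = twi_nat, dr = dr, hrt = hrt,
    z_avg = z_avg, z_max = zmax, volume_m3 = volume,
    wetland = wetland, coniferous = conif,
    water = rest[, "water"], open_area = rest[, "open"],
    deciduous = rest[, "deciduous"], deforested = rest[, "deforested"],
    a_littoral = alit,
    doc = doc, dic = dic, ph = ph, co2 = co2, t_water = t_water,
    tn = tn, tp = tp, kd = kd,
    benthic_gpp = benthic_gpp,
    pelagic_gpp = ifelse(pelagic_measured, pelagic_gpp, NA_real_),
    total_gpp = ifelse(pelagic_measured, total_gpp, NA_real_),
    structuring = ifelse(pelagic_measured, structuring, NA_real_),
    pelagic_measured = pelagic_measured, outlier = outlier,
    benthic_method = vapply(bi, function(b) b$benthic_method, ""),
    par_daily = 40, row.names = NULL
  )
  chemistry <- lakes[, c("lake_id", "doc", "dic", "ph", "t_water",
                         "tn", "tp")]

  grids_out <- NULL
  if (grids) {
    grids_out <- vector("list", n)
    names(grids_out) <- id
    for (i in seq_len(n)) {
      tgt <- bi[[i]]$cover
      tgt["wetland"] <- wetland[i]
      tgt["coniferous"] <- conif[i]
      tgt <- tgt / sum(tgt)
      grids_out[[i]] <- .make_lake_grids(a_catch[i], a0[i], elev[i],
                                         tgt[c("water", "wetland", "open",
                                               "deciduous", "coniferous",
                                               "deforested")])
    }
  }

  truth <- list(
    edges = true_path_edges(),
    residual_sd = .ls_resid,
    quad = .ls_quad,
    boreal_doc_co2 = .ls_boreal_doc_co2,
    lakes = data.frame(lake_id = id, biome = biome, kd = kd, doc = doc,
                       co2 = co2, benthic_gpp = benthic_gpp,
                       pelagic_gpp = pelagic_gpp, total_gpp = total_gpp,
                       structuring = structuring, gpp_z = gpp_z,
                       doc_z = doc_z, kd_z = kd_z, co2_z = co2_z,
                       row.names = NULL),
    rates = rates
  )

  structure(list(
    lakes = lakes, chemistry = chemistry,
    par_profiles = if (measurements) do.call(rbind, par_profiles),
    hypsography = do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(lake_id = id[i], depth_m = hypso[[i]]$depth_m,
                 area_m2 = hypso[[i]]$area_m2)
    })),
    incubations = if (measurements) do.call(rbind, inc_tab),
    c14 = if (measurements) do.call(rbind, c14_tab),
    hypso = hypso, grids = grids_out, truth = truth,
    seed = as.integer(seed), n_lakes = n
  ), class = "lake_bundle")
}

#' @export
print.lake_bundle <- function(x, ...) {
  cat(sprintf("lake_bundle: %d lakes (seed %d): %s\n", x$n_lakes, x$seed,
              paste(sprintf("%s %d", names(table(x$lakes$biome)),
                            table(x$lakes$biome)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits the CSV schemas consumed by the pipeline readers plus the truth
#' tables and a manifest recording the seed; rasters (if present) go to
#' `grids/` as ESRI ASCII.
#'
#' @param bundle A [generate_landscape()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "lake_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name),
                                           row.names = FALSE)
  w(bundle$lakes, "lakes.csv")
  w(bundle$chemistry, "chemistry.csv")
  w(bundle$par_profiles, "par_profiles.csv")
  w(bundle$hypsography, "hypsography.csv")
  w(bundle$incubations, "incubations.csv")
  if (!is.null(bundle$c14)) w(bundle$c14, "c14.csv")
  w(bundle$truth$edges, "truth_edges.csv")
  w(bundle$truth$lakes, "truth_lakes.csv")
  writeLines(c(sprintf("seed %d", bundle$seed),
               sprintf("n_lakes %d", bundle$n_lakes),
               sprintf("generator lakescape %s",
                       as.character(utils::packageVersion("lakescape")))),
             file.path(dir, "manifest.txt"))
  if (!is.null(bundle$grids)) {
    gd <- file.path(dir, "grids")
    dir.create(gd, showWarnings = FALSE)
    for (lk in names(bundle$grids)) {
      write_grid_asc(bundle$grids[[lk]]$dem,
                     file.path(gd, paste0(lk, "_dem.asc")))
      write_grid_asc(bundle$grids[[lk]]$cover,
                     file.path(gd, paste0(lk, "_cover.asc")))
      write_grid_asc(bundle$grids[[lk]]$lake_mask,
                     file.path(gd, paste0(lk, "_lake_mask.asc")))
    }
  }
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Directory path.
#' @return A `lake_bundle` (hypsography objects and rasters are
#'   reconstructed; true rate profiles are not persisted).
#' @export
read_bundle <- function(dir) {
  req <- c("lakes.csv", "chemistry.csv", "par_profiles.csv",
           "hypsography.csv", "incubations.csv")
  missing_f <- req[!file.exists(file.path(dir, req))]
  if (length(missing_f)) {
    stop("bundle at ", dir, " is missing: ", paste(missing_f, collapse = ", "))
  }
  r <- function(name) utils::read.csv(file.path(dir, name))
  lakes <- r("lakes.csv")
  ht <- r("hypsography.csv")
  hypso <- lapply(split(ht, ht$lake_id),
                  function(d) hypsography(d$depth_m, d$area_m2))
  hypso <- hypso[unique(ht$lake_id)]
  c14 <- if (file.exists(file.path(dir, "c14.csv"))) r("c14.csv") else NULL
  truth <- NULL
  if (file.exists(file.path(dir, "truth_edges.csv"))) {
    truth <- list(edges = r("truth_edges.csv"), lakes = r("truth_lakes.csv"))
  }
  manifest <- readLines(file.path(dir, "manifest.txt"))
  seed <- as.integer(sub("^seed ", "", manifest[1L]))
  grids <- NULL
  gd <- file.path(dir, "grids")
  if (dir.exists(gd)) {
    grids <- lapply(stats::setNames(nm = lakes$lake_id), function(lk) {
      list(dem = read_grid_asc(file.path(gd, paste0(lk, "_dem.asc"))),
           cover = read_grid_asc(file.path(gd, paste0(lk, "_cover.asc"))),
           lake_mask = read_grid_asc(file.path(gd,
                                               paste0(lk, "_lake_mask.asc"))))
    })
  }
  structure(list(lakes = lakes, chemistry = r("chemistry.csv"),
                 par_profiles = r("par_profiles.csv"),
                 hypsography = ht, incubations = r("incubations.csv"),
                 c14 = c14, hypso = hypso, grids = grids, truth = truth,
                 seed = seed, n_lakes = nrow(lakes)),
            class = "lake_bundle")
}
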