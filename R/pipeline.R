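#' Default path-model structure for the landscape analysis
#'
#' The fitted causal structure relating land cover to hydrology, hydrology
#' and land cover to water chemistry, and chemistry/bathymetry to total GPP
#' and autotrophic structuring.  Mirrors the generating structure of the
#' synthetic world ([true_path_edges()]), which is also the structure a
#' field analysis of these variables would posit.
#'
#' @return Character vector of `"parent -> child"` edges.
#' @export
default_path_edges <- function() {
  e <- true_path_edges()
  sprintf("%s -> %s", e$from, e$to)
}

#' Per-lake processing: light field, littoral fraction, GPP estimation
#'
#' Runs the measurement-level pipeline on a bundle: fits Kd from each PAR
#' profile, computes the littoral benthic fraction from the hypsography and
#' fitted Kd, estimates benthic GPP per depth from the incubation series
#' (paired light/dark DIC cores or domes), averages replicate enclosures,
#' estimates daily pelagic GPP per depth from the 14C table, upscales both
#' habitats over the basin, and combines them into whole-lake productivity
#' and autotrophic structuring.  Lakes without pelagic data are flagged
#' (`missing_pelagic`) and their total/structuring left undefined.
#'
#' @param bundle A `lake_bundle` (from [generate_landscape()] or
#'   [read_bundle()]) or a directory path readable by [read_bundle()].
#' @param pq Photosynthetic quotient for the dome O2-to-carbon conversion.
#' @return Data frame with one row per lake: `lake_id`, `kd_fit`,
#'   `kd_r_squared`, `a_littoral`, `benthic_avg`, `pelagic_avg`,
#'   `total_avg`, `structuring`, `flags`.
#' @export
run_lake <- function(bundle, pq = 1) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "lake_bundle"))
  for (tab in c("lakes", "par_profiles", "hypsography", "incubations")) {
    if (is.null(bundle[[tab]])) stop("bundle is missing the ", tab, " table")
  }
  out <- list()
  for (lk in bundle$lakes$lake_id) {
    pp <- bundle$par_profiles[bundle$par_profiles$lake_id == lk, ]
    lf <- fit_kd(pp$depth_m, pp$par)
    hy <- bundle$hypso[[lk]]
    alit <- littoral_fraction(hy, lf$kd)
    inc <- bundle$incubations[bundle$incubations$lake_id == lk, ]
    benthic_by_depth <- list()
    for (r in unique(inc$replicate)) {
      ir <- inc[inc$replicate == r, ]
      for (z in unique(ir$depth_m)) {
        iz <- ir[ir$depth_m == z, ]
        method <- iz$method[1L]
        est <- if (method == "dic_core") {
          mk <- function(flag) {
            s <- iz[iz$light_flag == flag, ]
            incubation_record("dic_core", z, s$time_h, s$value,
                              light = flag == "light",
                              volume_L = s$volume_L[1L],
                              footprint_m2 = s$footprint_m2[1L])
          }
          benthic_gpp_dic(mk("light"), mk("dark"))
        } else {
          rec <- incubation_record("dome", z, iz$time_h, iz$value,
                                   light = TRUE,
                                   volume_L = iz$volume_L[1L],
                                   footprint_m2 = iz$footprint_m2[1L],
                                   dark_start = iz$dark_start[1L],
                                   dark_end = iz$dark_end[1L])
          benthic_gpp_dome(rec, pq = pq)
        }
        key <- sprintf("%.17g", z)
        benthic_by_depth[[key]] <- c(benthic_by_depth[[key]], est)
      }
    }
    zb <- as.numeric(names(benthic_by_depth))
    rb <- vapply(benthic_by_depth, mean, 0)        # replicate average
    rb <- pmax(rb, 0)
    flags <- character(0)
    if (any(vapply(benthic_by_depth, mean, 0) < 0)) {
      flags <- c(flags, "negative_benthic_rate_floored")
    }
    benthic_avg <- upscale_benthic(depth_rates("benthic", zb, rb), hy)
    c14 <- bundle$c14[bundle$c14$lake_id == lk, ]
    if (!is.null(c14) && nrow(c14) >= 2L) {
      rp <- mapply(pelagic_gpp_daily, c14$light_uptake, c14$dark_uptake,
                   c14$par_inc, c14$par_daily)
      pelagic_avg <- upscale_pelagic(depth_rates("pelagic", c14$depth_m, rp),
                                     hy)
    } else {
      pelagic_avg <- NA_real_
    }
    prod <- lake_productivity(benthic_avg, pelagic_avg)
    out[[lk]] <- data.frame(
      lake_id = lk, kd_fit = lf$kd, kd_r_squared = lf$r_squared,
      a_littoral = alit, benthic_avg = prod$benthic_avg,
      pelagic_avg = prod$pelagic_avg, total_avg = prod$total_avg,
      structuring = prod$structuring,
      flags = paste(c(flags, prod$flags), collapse = ";"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Landscape-level statistics: RDA, forward-selection MLR, path analysis
#'
#' Runs the inference layer on a lake table: a redundancy analysis of the
#' water physico-chemistry (plus mean depth, elevation and air temperature)
#' constrained by the land-cover fractions with hydrology as supplementary
#' variables; forward-selection multiple regressions of (log) benthic,
#' pelagic and total GPP and of autotrophic structuring on the main water
#' and habitat drivers; and a recursive path analysis on the working
#' scales, with a display filter keeping only strong significant paths.
#' Lakes without a defined total GPP (missing pelagic habitat data) are
#' dropped from the GPP/structuring models but retained in the RDA.
#'
#' @param lakes A lake table in the layout of `generate_landscape()$lakes`
#'   (a `lake_bundle` is also accepted).
#' @param edges Path-model structure, default [default_path_edges()].
#' @param pc_min,alpha Display-filter thresholds (see [display_filter()]).
#' @return List with elements `rda` ([rda_ordination()]), `mlr` (named list
#'   of [forward_mlr()] fits), `path` ([fit_path_model()]), and
#'   `path_display` (filtered edge table).
#' @export
run_stats <- function(lakes, edges = default_path_edges(),
                      pc_min = 0.3, alpha = 0.05) {
  if (inherits(lakes, "lake_bundle")) lakes <- lakes$lakes
  need <- c("doc", "dic", "co2", "tn", "tp", "t_water", "kd", "z_avg",
            "elevation", "t_air", "wetland", "coniferous", "r_yearly",
            "twi", "dr", "hrt", "a_littoral", "benthic_gpp", "pelagic_gpp",
            "total_gpp", "structuring")
  miss <- setdiff(need, names(lakes))
  if (length(miss)) stop("lake table is missing: ", paste(miss, collapse = ", "))
  if (nrow(lakes) < 8L) stop("too few lakes for the landscape statistics")

  Y <- lakes[, c("doc", "dic", "co2", "tn", "tp", "t_water", "kd",
                 "z_avg", "elevation", "t_air")]
  # "water" serves as the compositional reference class: the six cover
  # fractions sum to 1, so one must be dropped to keep X full rank
  xcols <- intersect(c("wetland", "coniferous", "open_area", "deciduous",
                       "deforested"), names(lakes))
  X <- lakes[, xcols]
  S <- lakes[, c("r_yearly", "twi", "dr", "hrt")]
  rda_res <- rda_ordination(Y, X, S)

  ws <- working_scales(lakes)
  complete <- stats::complete.cases(ws)
  wsc <- ws[complete, ]
  cand <- wsc[, c("doc", "kd", "co2", "t_water", "a_littoral", "z_avg")]
  mlr <- list(
    benthic_gpp = forward_mlr(wsc$benthic_gpp, cand),
    pelagic_gpp = forward_mlr(wsc$pelagic_gpp, cand),
    total_gpp = forward_mlr(wsc$total_gpp, cand),
    structuring = forward_mlr(wsc$structuring, cand)
  )
  path <- fit_path_model(wsc, edges)
  list(rda = rda_res, mlr = mlr, path = path,
       path_display = display_filter(path, pc_min, alpha))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic bundle), `lake` (per-lake
#' productivity), `catchment` (terrain metrics from bundle rasters),
#' `stats` (landscape statistics), `run-all` (lake + stats).  Flags:
#' `--n-lakes`, `--seed`, `--out`, `--bundle`, `--version`.
#'
#' @param argv Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success); use
#'   `quit(status = lakescape_cli())` in a script.
#' @export
lakescape_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0L) stop("usage: <simulate|lake|catchment|stats|run-all> [--flags]")
    if (argv[1L] %in% c("--version", "-v")) {
      cat("lakescape", as.character(utils::packageVersion("lakescape")), "\n")
      return(invisible(0L))
    }
    cmd <- match.arg(argv[1L],
                     c("simulate", "lake", "catchment", "stats", "run-all"))
    opts <- list(`n-lakes` = "26", seed = "1", out = ".", bundle = NULL)
    args <- argv[-1L]
    i <- 1L
    while (i <= length(args)) {
      key <- sub("^--", "", args[i])
      if (!startsWith(args[i], "--") || i == length(args)) {
        stop("cannot parse argument: ", args[i])
      }
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
    if (cmd == "simulate") {
      b <- generate_landscape(n_lakes = as.integer(opts$`n-lakes`),
                              seed = as.integer(opts$seed))
      write_bundle(b, opts$out)
      cat("wrote bundle to", opts$out, "\n")
    } else {
      src <- if (!is.null(opts$bundle)) opts$bundle else opts$out
      b <- read_bundle(src)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      if (cmd %in% c("lake", "run-all")) {
        res <- run_lake(b)
        utils::write.csv(res, file.path(opts$out, "results_lakes.csv"),
                         row.names = FALSE)
        cat("wrote", file.path(opts$out, "results_lakes.csv"), "\n")
      }
      if (cmd == "catchment") {
        if (is.null(b$grids)) stop("bundle has no rasters")
        rows <- lapply(names(b$grids), function(lk) {
          g <- b$grids[[lk]]
          del <- delineate_catchment(g$dem, g$lake_mask)
          filled <- fill_depressions(g$dem)
          acc <- flow_accumulation_d8(filled)
          tw <- twi(filled, acc, mask = del$mask)
          fr <- cover_fractions(g$cover, del$mask, default_reclass(),
                                incidental_threshold = 0)
          data.frame(lake_id = lk, a_catchment_ha = del$a_catchment_ha,
                     twi_mean = tw$mean,
                     wetland = ifelse("wetland" %in% names(fr),
                                      fr[["wetland"]], 0),
                     coniferous = ifelse("coniferous forest" %in% names(fr),
                                         fr[["coniferous forest"]], 0))
        })
        utils::write.csv(do.call(rbind, rows),
                         file.path(opts$out, "results_catchments.csv"),
                         row.names = FALSE)
        cat("wrote", file.path(opts$out, "results_catchments.csv"), "\n")
      }
      if (cmd %in% c("stats", "run-all")) {
        st <- run_stats(b$lakes)
        utils::write.csv(st$path$edges,
                         file.path(opts$out, "results_path_edges.csv"),
                         row.names = FALSE)
        fitidx <- st$path$fit
        utils::write.csv(data.frame(index = names(fitidx),
                                    value = unlist(fitidx)),
                         file.path(opts$out, "results_fit_indices.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(axis = seq_along(st$rda$prop_explained),
                                    pct_of_total = st$rda$prop_explained),
                         file.path(opts$out, "results_rda.csv"),
                         row.names = FALSE)
        cat("wrote stats results to", opts$out, "\n")
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
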