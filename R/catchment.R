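# D8 neighbour offsets in the fixed tie-break order E, SE, S, SW, W, NW, N, NE
.d8_dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.d8_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

# Priority-flood over a numeric matrix.  Returns the filled surface and the
# pop order (drainage order: boundary-low first).  `eps` > 0 enforces a
# strict downhill gradient on raised cells.
.priority_flood <- function(z, eps = 0, extra_seeds = NULL) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  if (all(is.na(z))) stop("all-no-data grid")
  filled <- z
  visited <- matrix(FALSE, nr, nc)
  queued <- matrix(FALSE, nr, nc)
  pop_order <- matrix(NA_integer_, nr, nc)
  # queue as parallel vectors (grids are small; linear scans are fine)
  q_idx <- integer(0)
  q_pri <- numeric(0)
  push <- function(i, pri) {
    q_idx[length(q_idx) + 1L] <<- i
    q_pri[length(q_pri) + 1L] <<- pri
    queued[i] <<- TRUE
  }
  # seed with boundary cells and cells adjacent to no-data voids
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(z[r, cc])) next
    on_edge <- r == 1L || r == nr || cc == 1L || cc == nc
    if (!on_edge) {
      for (k in 1:8) {
        if (is.na(z[r + .d8_dr[k], cc + .d8_dc[k]])) { on_edge <- TRUE; break }
      }
    }
    if (on_edge) push((cc - 1L) * nr + r, z[r, cc])
  }
  # additional sink cells (e.g. a lake treated as the drainage outlet)
  for (i in extra_seeds) {
    if (!queued[i] && !is.na(z[i])) push(i, z[i])
  }
  counter <- 0L
  while (length(q_idx) > 0L) {
    j <- which.min(q_pri)
    i <- q_idx[j]; pri <- q_pri[j]
    q_idx <- q_idx[-j]; q_pri <- q_pri[-j]
    if (visited[i]) next
    visited[i] <- TRUE
    counter <- counter + 1L
    pop_order[i] <- counter
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    for (k in 1:8) {
      rr <- r + .d8_dr[k]; ccc <- cc + .d8_dc[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      ii <- (ccc - 1L) * nr + rr
      if (is.na(z[ii]) || visited[ii] || queued[ii]) next
      if (filled[ii] < pri + eps) filled[ii] <- pri + eps
      push(ii, filled[ii])
    }
  }
  list(filled = filled, pop_order = pop_order)
}

#' Fill closed depressions in a DEM
#'
#' Priority-flood filling: every interior pit is raised to its spill
#' elevation so that a monotone (non-ascending) drainage path to the grid
#' boundary exists from every cell.  Cells not in a depression are returned
#' unchanged.
#'
#' @param dem A [terrain_grid()] of elevations.
#' @return The filled [terrain_grid()].
#' @export
fill_depressions <- function(dem) {
  stopifnot(inherits(dem, "terrain_grid"))
  pf <- .priority_flood(dem$data, eps = 0)
  terrain_grid(pf$filled, dem$cellsize, dem$xll, dem$yll, dem$nodata)
}

# D8 receiver index for every cell (0 = outlet off-grid / no receiver).
# Interior flats are resolved by routing to the equal-elevation neighbour
# popped earliest by the priority flood, which guarantees acyclic drainage;
# a boundary cell with no downhill in-grid neighbour drains off-grid.
.d8_receivers <- function(z, pop_order, cellsize) {
  nr <- nrow(z); nc <- ncol(z)
  recv <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(z[r, cc])) { recv[r, cc] <- NA_integer_; next }
    best_k <- 0L; best_slope <- 0
    flat_k <- 0L; flat_pop <- pop_order[r, cc]
    on_edge <- r == 1L || r == nr || cc == 1L || cc == nc
    for (k in 1:8) {
      rr <- r + .d8_dr[k]; ccc <- cc + .d8_dc[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      if (is.na(z[rr, ccc])) { on_edge <- TRUE; next }
      d <- if (.d8_dr[k] != 0L && .d8_dc[k] != 0L) cellsize * sqrt(2) else cellsize
      s <- (z[r, cc] - z[rr, ccc]) / d
      if (s > best_slope) { best_slope <- s; best_k <- k }
      if (s == 0 && z[rr, ccc] == z[r, cc] &&
          !is.na(pop_order[rr, ccc]) && pop_order[rr, ccc] < flat_pop) {
        flat_pop <- pop_order[rr, ccc]; flat_k <- k
      }
    }
    k <- if (best_k > 0L) best_k else if (on_edge) 0L else flat_k
    if (k > 0L) {
      recv[r, cc] <- (cc + .d8_dc[k] - 1L) * nr + (r + .d8_dr[k])
    }
  }
  recv
}

#' D8 flow accumulation
#'
#' Number of cells draining through each cell (including itself), using
#' steepest-descent D8 routing with ties broken in the fixed neighbour
#' order E, SE, S, SW, W, NW, N, NE.  Flats left by depression filling are
#' drained along the priority-flood pop order.  The input should be
#' depression-free (see [fill_depressions()]); an internal zero-epsilon
#' flood is run only to obtain the drainage order.
#'
#' @param dem A depression-free [terrain_grid()].
#' @return A [terrain_grid()] of upslope cell counts.
#' @export
flow_accumulation_d8 <- function(dem) {
  stopifnot(inherits(dem, "terrain_grid"))
  z <- dem$data
  pf <- .priority_flood(z, eps = 0)
  if (any(pf$filled != z, na.rm = TRUE)) {
    stop("DEM contains unfilled depressions; run fill_depressions() first")
  }
  recv <- .d8_receivers(z, pf$pop_order, dem$cellsize)
  acc <- matrix(1, nrow(z), ncol(z))
  acc[is.na(z)] <- NA_real_
  ord <- order(pf$pop_order, decreasing = TRUE, na.last = NA)
  for (i in ord) {
    rc <- recv[i]
    if (!is.na(rc) && rc > 0L) acc[rc] <- acc[rc] + acc[i]
  }
  terrain_grid(acc, dem$cellsize, dem$xll, dem$yll, dem$nodata)
}

#' Delineate the catchment of a lake
#'
#' The catchment is the set of cells whose D8 flow path enters the lake
#' mask, plus the lake itself.  The lake is treated as a drainage sink:
#' depressions in the surrounding terrain are flood-filled with the lake
#' cells (and the grid boundary) as outlets, so the raw DEM can be passed
#' directly — the lake basin itself is never filled away.
#'
#' @param dem A [terrain_grid()] (filling is handled internally).
#' @param lake_mask A [terrain_grid()] with 1 inside the lake, 0/NA outside.
#' @return A list with `mask` (a 0/1 [terrain_grid()]) and `a_catchment_ha`
#'   (catchment area in hectares).
#' @export
delineate_catchment <- function(dem, lake_mask) {
  stopifnot(inherits(dem, "terrain_grid"), inherits(lake_mask, "terrain_grid"))
  z <- dem$data
  lk <- lake_mask$data
  if (!identical(dim(z), dim(lk))) stop("lake mask must match the DEM grid")
  lk_in <- !is.na(lk) & lk == 1
  if (!any(lk_in)) stop("lake mask is empty")
  pf <- .priority_flood(z, eps = 0, extra_seeds = which(lk_in))
  z <- pf$filled
  recv <- .d8_receivers(z, pf$pop_order, dem$cellsize)
  n <- length(z)
  # drains[i]: NA unknown, 1 reaches lake, 0 leaves the grid without it
  drains <- rep(NA_integer_, n)
  drains[which(lk_in)] <- 1L
  for (start in seq_len(n)) {
    if (!is.na(drains[start]) || is.na(z[start])) next
    path <- integer(0)
    i <- start
    repeat {
      path[length(path) + 1L] <- i
      rc <- recv[i]
      if (is.na(rc) || rc == 0L) { res <- 0L; break }
      if (!is.na(drains[rc])) { res <- drains[rc]; break }
      i <- rc
    }
    drains[path] <- res
  }
  m <- matrix(0, nrow(z), ncol(z))
  m[drains == 1L] <- 1
  m[is.na(z)] <- NA_real_
  list(mask = terrain_grid(m, dem$cellsize, dem$xll, dem$yll, dem$nodata),
       a_catchment_ha = sum(m == 1, na.rm = TRUE) * dem$cellsize^2 / 1e4)
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan beta)` with specific catchment area
#' `a = flowacc * cellsize` and `tan beta` the local steepest-descent slope,
#' floored at 1e-4 so flats stay finite.
#'
#' @param dem A [terrain_grid()] (depression-free recommended).
#' @param flowacc Flow accumulation grid from [flow_accumulation_d8()].
#' @param mask Optional 0/1 [terrain_grid()]; the mean is taken over cells
#'   where the mask is 1 (otherwise over all cells).
#' @param slope_floor Lower bound for `tan beta` (default 1e-4).
#' @return List with `grid` (TWI values) and `mean`.
#' @export
twi <- function(dem, flowacc, mask = NULL, slope_floor = 1e-4) {
  stopifnot(inherits(dem, "terrain_grid"), inherits(flowacc, "terrain_grid"))
  z <- dem$data
  nr <- nrow(z); nc <- ncol(z)
  slope <- matrix(slope_floor, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(z[r, cc])) { slope[r, cc] <- NA_real_; next }
    best <- 0
    for (k in 1:8) {
      rr <- r + .d8_dr[k]; ccc <- cc + .d8_dc[k]
      if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
      if (is.na(z[rr, ccc])) next
      d <- if (.d8_dr[k] != 0L && .d8_dc[k] != 0L) dem$cellsize * sqrt(2) else dem$cellsize
      best <- max(best, (z[r, cc] - z[rr, ccc]) / d)
    }
    slope[r, cc] <- max(best, slope_floor)
  }
  a <- flowacc$data * dem$cellsize   # specific catchment area, m
  w <- log(a / slope)
  sel <- if (is.null(mask)) !is.na(w) else !is.na(w) & mask$data == 1
  list(grid = terrain_grid(w, dem$cellsize, dem$xll, dem$yll, dem$nodata),
       mean = mean(w[sel]))
}

#' Land-cover class fractions within a catchment
#'
#' Reclassifies raw land-cover codes with a lookup table, computes each
#' class's share of the masked cells, and drops "incidental" classes whose
#' share falls below the exclusion threshold (so returned fractions can sum
#' to less than 1).
#'
#' @param cover A [terrain_grid()] of integer land-cover codes.
#' @param mask A 0/1 [terrain_grid()] (the catchment).
#' @param reclass Named character vector mapping `as.character(code)` to a
#'   class name; map a code to `"drop"` to discard it explicitly.
#' @param incidental_threshold Percentage below which a class is excluded
#'   (default 5).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
cover_fractions <- function(cover, mask, reclass, incidental_threshold = 5) {
  stopifnot(inherits(cover, "terrain_grid"), inherits(mask, "terrain_grid"))
  sel <- !is.na(cover$data) & !is.na(mask$data) & mask$data == 1
  codes <- as.character(cover$data[sel])
  unknown <- setdiff(unique(codes), names(reclass))
  if (length(unknown)) {
    stop("unmapped land-cover code(s): ", paste(unknown, collapse = ", "))
  }
  classes <- unname(reclass[codes])
  keep <- classes != "drop"
  tab <- table(classes[keep])
  frac <- as.numeric(tab) / length(codes)
  names(frac) <- names(tab)
  frac[frac * 100 >= incidental_threshold]
}

#' Lake hydrology metrics: hydraulic retention time and drainage ratio
#'
#' Annual discharge is the catchment area times the runoff depth; the
#' hydraulic retention time (HRT) is the lake volume divided by that
#' discharge, expressed in years.  The drainage ratio (DR) is catchment
#' area over lake area.
#'
#' @param volume_m3 Lake volume (m^3).
#' @param a_catchment_m2,a_lake_m2 Catchment and lake areas (m^2).
#' @param r_yearly_mm Yearly runoff (mm yr^-1), positive.
#' @return List with `discharge_m3_yr`, `hrt_yr`, `dr`.
#' @export
hydrology_metrics <- function(volume_m3, a_catchment_m2, a_lake_m2,
                              r_yearly_mm) {
  if (volume_m3 <= 0 || a_catchment_m2 <= 0 || a_lake_m2 <= 0) {
    stop("volume and areas must be positive")
  }
  if (r_yearly_mm <= 0) stop("runoff must be positive")
  q <- (r_yearly_mm / 1000) * a_catchment_m2
  list(discharge_m3_yr = q, hrt_yr = volume_m3 / q,
       dr = a_catchment_m2 / a_lake_m2)
}

#' Lapse-rate adjustment of station air temperature to lake elevation
#'
#' Applies the conventional surface lapse rate of 0.57 degrees C per 100 m
#' of elevation difference between the weather station and the lake.
#'
#' @param t_station Station air temperature (degrees C).
#' @param elev_station,elev_lake Elevations (m a.s.l.).
#' @return Adjusted temperature (degrees C).
#' @examples
#' lapse_adjust(14, 300, 600)  # 12.29
#' @export
lapse_adjust <- function(t_station, elev_station, elev_lake) {
  t_station - 0.57 * (elev_lake - elev_station) / 100
}
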