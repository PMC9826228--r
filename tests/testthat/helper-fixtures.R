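# shared fixtures, built in code

# linear cone lake: A(z) = 1000 * (1 - z/10)
cone_hypso <- function() hypsography(c(0, 10), c(1000, 0))

# flat-bottomed box lake
box_hypso <- function(a0 = 500, zmax = 4) hypsography(c(0, zmax), c(a0, a0))

# random valid hypsography (piecewise linear, non-increasing areas)
random_hypso <- function(n = 8) {
  d <- c(0, sort(runif(n - 2, 0.2, 9.8)), 10)
  a <- sort(runif(n, 10, 1000), decreasing = TRUE)
  hypsography(d, a)
}

# plane DEM sloping down towards the south (row nr), no flats
plane_dem <- function(nr = 8, nc = 6, slope = 1, cellsize = 10) {
  terrain_grid(outer(rev(seq_len(nr)) * slope * cellsize, rep(1, nc)),
               cellsize = cellsize)
}

# bowl DEM draining to the centre
bowl_dem <- function(n = 9, cellsize = 5) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  terrain_grid(d * cellsize * 0.1 + 100, cellsize = cellsize)
}

central_mask <- function(n = 9, r = 1.6, cellsize = 5) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  terrain_grid((d <= r) + 0, cellsize = cellsize)
}

# independent steepest-descent receiver oracle for DEMs without flats;
# returns linear index of receiver or 0 (tie order E, SE, S, SW, W, NW, N, NE)
oracle_receivers <- function(z, cellsize) {
  nr <- nrow(z); nc <- ncol(z)
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  recv <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    best <- 0; bk <- 0L
    for (k in 1:8) {
      rr <- r + dr[k]; c2 <- cc + dc[k]
      if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
      dd <- if (dr[k] != 0 && dc[k] != 0) cellsize * sqrt(2) else cellsize
      s <- (z[r, cc] - z[rr, c2]) / dd
      if (s > best) { best <- s; bk <- k }
    }
    if (bk > 0L) recv[r, cc] <- (cc + dc[bk] - 1L) * nr + (r + dr[bk])
  }
  recv
}

# brute-force flow accumulation from oracle receivers
oracle_accumulation <- function(z, cellsize) {
  recv <- oracle_receivers(z, cellsize)
  acc <- matrix(1, nrow(z), ncol(z))
  ord <- order(z, decreasing = TRUE)
  for (i in ord) if (recv[i] > 0L) acc[recv[i]] <- acc[recv[i]] + acc[i]
  acc
}
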