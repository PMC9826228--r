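#' Rectangular terrain grid
#'
#' Minimal raster container used by the catchment analytics: a numeric
#' matrix whose first row is the northern edge, a uniform cell size in
#' metres, a lower-left corner, and a no-data marker (stored as `NA` in the
#' matrix).
#'
#' @param data Numeric matrix (row 1 = north).
#' @param cellsize Cell edge length (m), positive.
#' @param xll,yll Coordinates of the lower-left corner (m).
#' @param nodata Value written to file for missing cells.
#' @return A `terrain_grid` object.
#' @export
terrain_grid <- function(data, cellsize, xll = 0, yll = 0, nodata = -9999) {
  stopifnot(is.matrix(data), is.numeric(data) || is.logical(data))
  if (cellsize <= 0) stop("cellsize must be positive")
  structure(list(data = data, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata),
            class = "terrain_grid")
}

#' @export
print.terrain_grid <- function(x, ...) {
  cat(sprintf("terrain_grid: %d x %d cells, cellsize %g m\n",
              nrow(x$data), ncol(x$data), x$cellsize))
  invisible(x)
}

#' Read an ESRI ASCII (.asc) grid
#'
#' @param path File path.
#' @return A [terrain_grid()].
#' @export
read_grid_asc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nskip <- if (is.null(hdr$nodata_value)) 5L else 6L
  vals <- scan(path, skip = nskip, quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  terrain_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, nodata)
}

#' Write a terrain grid as ESRI ASCII (.asc)
#'
#' @param grid A [terrain_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(grid, path) {
  stopifnot(inherits(grid, "terrain_grid"))
  m <- grid$data
  m[is.na(m)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.6f", grid$xll),
           sprintf("yllcorner %.6f", grid$yll),
           sprintf("cellsize %.6f", grid$cellsize),
           sprintf("NODATA_value %g", grid$nodata))
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
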