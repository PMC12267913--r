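#' Georeferenced single-band raster grid
#'
#' Lightweight container for the single-band rasters the package works with:
#' canopy height models (CHMs, m above ground), digital terrain models (DTMs,
#' m a.s.l.), masks and class maps. Values are stored as a numeric matrix with
#' row 1 the northernmost row; missing data are `NA` in memory and a sentinel
#' value on disk. The geotransform is restricted to axis-aligned square pixels,
#' which is all the analysis requires.
#'
#' @param values numeric matrix; row 1 is the top (north) row.
#' @param xll,yll map coordinates of the lower-left corner of the grid (m).
#' @param pixel_size pixel edge length in metres (> 0, square pixels).
#' @param nodata sentinel written to disk for `NA` cells.
#' @param crs free-text coordinate-system identifier (kept as metadata).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, pixel_size = 1,
                        nodata = -9999, crs = "local") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  g <- structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         pixel_size = as.numeric(pixel_size), nodata = as.numeric(nodata),
         crs = as.character(crs)),
    class = "raster_grid")
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d pixels @ %g m (crs: %s)\n",
              nrow(v), ncol(v), x$pixel_size, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + ncol(v) * x$pixel_size,
              x$yll, x$yll + nrow(v) * x$pixel_size))
  fin <- v[is.finite(v)]
  cat(sprintf("  values: %s, NA: %d/%d\n",
              if (length(fin)) sprintf("[%.3g, %.3g]", min(fin), max(fin)) else "none",
              sum(is.na(v)), length(v)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Map coordinates of pixel centres
#'
#' @param grid a [raster_grid()].
#' @return list with vectors `x` (by column) and `y` (by row, row 1 = north).
#' @keywords internal
#' @export
pixel_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); px <- grid$pixel_size
  list(x = grid$xll + (seq_len(nc) - 0.5) * px,
       y = grid$yll + (nr - seq_len(nr) + 0.5) * px)
}

#' Do two grids share the same geometry?
#'
#' Same shape, pixel size, origin and CRS (coordinates compared to 1e-6 m).
#' @param a,b [raster_grid()] objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$pixel_size - b$pixel_size) < 1e-6 &&
    abs(a$xll - b$xll) < 1e-6 && abs(a$yll - b$yll) < 1e-6 &&
    identical(a$crs, b$crs)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows north to
#' south). A `.prj` sidecar, if present, is read back into the `crs` field.
#' Values equal to the nodata sentinel become `NA`.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed ASCII grid (no data): ", path)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete (single square-pixel band required): ",
         path)
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square pixels (dx/dy header) are not supported: ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid has %d values, expected %d (multi-band or truncated input?): %s",
                 length(vals), nr * nc, path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else "local"
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              pixel_size = hdr$cellsize, nodata = nodata, crs = crs)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written with `%.17g` so a read/write round trip is bit-exact for
#' doubles. A `.prj` sidecar carries the `crs` string when it is not "local".
#'
#' @param grid a [raster_grid()].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  v <- grid$values
  nodata <- grid$nodata
  if (any(v == nodata, na.rm = TRUE))
    stop("finite values equal to the nodata sentinel (", nodata,
         ") would be silently lost; change grid$nodata")
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.17g", grid$xll),
           sprintf("yllcorner %.17g", grid$yll),
           sprintf("cellsize %.17g", grid$pixel_size),
           sprintf("NODATA_value %.17g", nodata))
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  if (!identical(grid$crs, "local"))
    writeLines(grid$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Decimal years between two calendar dates
#'
#' Day count divided by 365.25; e.g. 2014-10-15 to 2020-02-15 gives 5.34 yr
#' ("5 yr and 4 months").
#' @param date1,date2 `Date` or parseable character dates.
#' @return numeric years (signed).
#' @export
decimal_years <- function(date1, date2) {
  as.numeric(as.Date(date2) - as.Date(date1)) / 365.25
}

#' Pair two co-registered canopy height models
#'
#' Validates that the two CHMs are exactly aligned (shape, pixel size, origin,
#' CRS) and that the acquisition interval is positive, and computes the
#' interval in decimal years.
#'
#' @param chm1,chm2 [raster_grid()] CHMs at time 1 and time 2.
#' @param date1,date2 acquisition dates.
#' @return list of class `chm_pair` with fields `chm1`, `chm2`, `date1`,
#'   `date2`, `interval_years`.
#' @export
chm_pair <- function(chm1, chm2, date1, date2) {
  if (!identical(dim(chm1$values), dim(chm2$values)))
    stop(sprintf("CHM shape mismatch: %dx%d vs %dx%d",
                 nrow(chm1$values), ncol(chm1$values),
                 nrow(chm2$values), ncol(chm2$values)))
  if (!same_geometry(chm1, chm2))
    stop(sprintf(paste0("CHM geometry mismatch: origin offset (%.3g, %.3g) m, ",
                        "pixel size %g vs %g"),
                 chm2$xll - chm1$xll, chm2$yll - chm1$yll,
                 chm1$pixel_size, chm2$pixel_size))
  for (g in list(chm1, chm2))
    if (any(g$values < 0, na.rm = TRUE))
      stop("CHM contains negative heights")
  iy <- decimal_years(date1, date2)
  if (!is.finite(iy) || iy <= 0)
    stop("acquisition interval must be positive (date2 after date1)")
  structure(list(chm1 = chm1, chm2 = chm2,
                 date1 = as.Date(date1), date2 = as.Date(date2),
                 interval_years = iy),
            class = "chm_pair")
}

#' Quality-masking and cell-retention thresholds
#'
#' Defaults reproduce the standard acquisition-quality rules: pixels with
#' pulse density < 2 m^-2 or scan angle > 20 degrees are masked, 1-ha cells
#' with > 5% missing data or without a single forest type covering >= 75% of
#' their area are dropped.
#'
#' @param min_pulse_density pulses m^-2.
#' @param max_scan_angle degrees.
#' @param max_missing_fraction unitless in \[0, 1\].
#' @param min_type_purity unitless in \[0, 1\].
#' @return list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_pulse_density = 2, max_scan_angle = 20,
                               max_missing_fraction = 0.05,
                               min_type_purity = 0.75) {
  stopifnot(min_pulse_density >= 0, max_scan_angle >= 0,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_type_purity > 0, min_type_purity <= 1)
  structure(list(min_pulse_density = min_pulse_density,
                 max_scan_angle = max_scan_angle,
                 max_missing_fraction = max_missing_fraction,
                 min_type_purity = min_type_purity),
            class = "quality_thresholds")
}

#' Mask low-quality CHM pixels
#'
#' Sets to `NA` every pixel whose pulse density falls below
#' `q$min_pulse_density` or whose scan angle exceeds `q$max_scan_angle`.
#' Auxiliary rasters are optional: when absent that criterion is assumed to
#' pass (synthetic data has no acquisition artifacts). Idempotent.
#'
#' @param chm [raster_grid()] CHM.
#' @param density optional pulse-density raster aligned with `chm`.
#' @param scan_angle optional scan-angle raster (degrees) aligned with `chm`.
#' @param q a [quality_thresholds()].
#' @return the masked CHM.
#' @export
apply_quality_mask <- function(chm, density = NULL, scan_angle = NULL,
                               q = quality_thresholds()) {
  for (aux in list(density, scan_angle))
    if (!is.null(aux) && !same_geometry(chm, aux))
      stop("auxiliary quality raster is not aligned with the CHM")
  v <- chm$values
  if (!is.null(density))
    v[!is.na(density$values) & density$values < q$min_pulse_density] <- NA_real_
  if (!is.null(density)) v[is.na(density$values)] <- NA_real_
  if (!is.null(scan_angle))
    v[!is.na(scan_angle$values) & scan_angle$values > q$max_scan_angle] <- NA_real_
  if (!is.null(scan_angle)) v[is.na(scan_angle$values)] <- NA_real_
  out <- chm; out$values <- v
  out
}

#' Tile a raster into square analysis cells
#'
#' Partitions the raster into non-overlapping `cell_size` x `cell_size`
#' windows (default 100 m = 1 ha) anchored at the top-left pixel. Windows are
#' half-open in pixel space, so every pixel of a complete cell belongs to
#' exactly one window; partial cells at the south/east edges are flagged
#' `complete = FALSE` and excluded from analysis by downstream code.
#'
#' @param grid a [raster_grid()].
#' @param cell_size cell edge in metres; must be an integer multiple of the
#'   pixel size.
#' @return data.frame with one row per cell: `cell_row`, `cell_col` (1-based
#'   cell indices from the north-west), `row0`, `col0` (1-based pixel offsets
#'   of the window's top-left pixel), `nrow`, `ncol` (window size in pixels),
#'   `complete`, and pixel-centre map coordinates `x`, `y` of the cell centre.
#' @export
tile_cells <- function(grid, cell_size = 100) {
  px <- grid$pixel_size
  k <- cell_size / px
  if (abs(k - round(k)) > 1e-9)
    stop("cell_size must be an integer multiple of pixel_size")
  k <- as.integer(round(k))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  n_cr <- ceiling(nr / k); n_cc <- ceiling(nc / k)
  out <- expand.grid(cell_row = seq_len(n_cr), cell_col = seq_len(n_cc))
  out$row0 <- (out$cell_row - 1L) * k + 1L
  out$col0 <- (out$cell_col - 1L) * k + 1L
  out$nrow <- pmin(k, nr - out$row0 + 1L)
  out$ncol <- pmin(k, nc - out$col0 + 1L)
  out$complete <- out$nrow == k & out$ncol == k
  out$x <- grid$xll + (out$col0 - 1 + out$ncol / 2) * px
  top <- grid$yll + nr * px
  out$y <- top - (out$row0 - 1 + out$nrow / 2) * px
  out[order(out$cell_row, out$cell_col), , drop = FALSE]
}

#' Extract the value matrix of one cell window
#' @param grid a [raster_grid()].
#' @param cell one row of the [tile_cells()] table.
#' @return numeric matrix.
#' @keywords internal
#' @export
cell_window <- function(grid, cell) {
  grid$values[cell$row0:(cell$row0 + cell$nrow - 1L),
              cell$col0:(cell$col0 + cell$ncol - 1L), drop = FALSE]
}

#' Decide whether an analysis cell is retained, and its forest type
#'
#' A cell is invalid when incomplete, when its missing-data fraction exceeds
#' `q$max_missing_fraction`, or when no forest type reaches
#' `q$min_type_purity` of its area; otherwise the majority type is returned.
#'
#' @param chm_window numeric matrix of CHM values for the cell (NA = missing).
#' @param q a [quality_thresholds()].
#' @param type_fractions named numeric vector of per-type area fractions
#'   (summing to <= 1); `NULL` skips the purity rule.
#' @param complete is the cell a full window?
#' @return list with `valid` (logical) and `forest_type` (character or `NA`).
#' @export
cell_validity <- function(chm_window, q = quality_thresholds(),
                          type_fractions = NULL, complete = TRUE) {
  if (!is.null(type_fractions) && sum(type_fractions) > 1 + 1e-9)
    stop("type_fractions must sum to <= 1")
  missing_frac <- mean(is.na(chm_window))
  if (!complete || missing_frac > q$max_missing_fraction)
    return(list(valid = FALSE, forest_type = NA_character_))
  if (is.null(type_fractions))
    return(list(valid = TRUE, forest_type = NA_character_))
  i <- which.max(type_fractions)
  if (length(i) == 0L || type_fractions[i] < q$min_type_purity)
    return(list(valid = FALSE, forest_type = NA_character_))
  list(valid = TRUE, forest_type = names(type_fractions)[i])
}

#' Per-cell area fractions of a categorical raster
#'
#' @param type_grid [raster_grid()] of integer type codes (or NA).
#' @param cell one row of the [tile_cells()] table.
#' @param levels type codes to tabulate; names become the fraction names.
#' @return named numeric vector of fractions of the cell area.
#' @keywords internal
#' @export
cell_type_fractions <- function(type_grid, cell, levels) {
  w <- cell_window(type_grid, cell)
  n <- length(w)
  out <- vapply(levels, function(l) sum(w == l, na.rm = TRUE) / n, numeric(1))
  names(out) <- names(levels)
  out
}
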