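# Terrain derivatives for the covariate layer: block aggregation, Horn slope,
# Planchon-Darboux pit filling, D8 flow accumulation and ln(a / tan b) wetness.
# All grids these run on are coarse aggregates (10-25 m), so pure-R loops over
# a few thousand cells are ample.

# D8 neighbor offsets in the fixed tie-break order E, SE, S, SW, W, NW, N, NE
# (row offset is +1 southwards since row 1 is the north edge).
.d8 <- data.frame(dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
                  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))

# Shift a matrix by (dr, dc), padding with `fill`.
.shift <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

.overlap_weights <- function(n_in, res_in, n_out, res_out) {
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * res_out; b <- i * res_out
    j0 <- max(1L, floor(a / res_in) + 1L)
    j1 <- min(n_in, ceiling(b / res_in))
    for (j in j0:j1)
      w[i, j] <- max(0, min(b, j * res_in) - max(a, (j - 1) * res_in)) / res_out
  }
  w
}

#' Resample a raster to a coarser resolution by area-weighted mean
#'
#' Each output pixel is the overlap-area-weighted mean of the source pixels it
#' covers, so non-integer resolution ratios (e.g. 10 m to 25 m) are exact.
#' An output pixel touching any missing source pixel is set to `NA`. The
#' extent must be an integer multiple of the target resolution; trailing
#' rows/columns that do not fill a whole output pixel are dropped with a
#' warning.
#'
#' @param grid a [raster_grid()].
#' @param target_resolution output pixel size in metres (>= pixel size).
#' @return a [raster_grid()] at the target resolution.
#' @export
resample_mean <- function(grid, target_resolution) {
  px <- grid$pixel_size
  stopifnot(target_resolution >= px)
  v <- grid$values
  nr_out <- floor(nrow(v) * px / target_resolution)
  nc_out <- floor(ncol(v) * px / target_resolution)
  if (nr_out < 1L || nc_out < 1L)
    stop("raster smaller than one output pixel")
  keep_r <- floor(nr_out * target_resolution / px)
  keep_c <- floor(nc_out * target_resolution / px)
  if (keep_r < nrow(v) || keep_c < ncol(v)) {
    warning("extent not a multiple of target_resolution; trailing edge dropped")
    v <- v[seq_len(keep_r), seq_len(keep_c), drop = FALSE]
  }
  wr <- .overlap_weights(nrow(v), px, nr_out, target_resolution)
  wc <- .overlap_weights(ncol(v), px, nc_out, target_resolution)
  na <- is.na(v)
  v0 <- v; v0[na] <- 0
  out <- wr %*% v0 %*% t(wc)
  bad <- (wr > 0) %*% na %*% t(wc > 0)
  out[bad > 0] <- NA_real_
  ytop <- grid$yll + nrow(grid$values) * px
  raster_grid(out, xll = grid$xll,
              yll = ytop - nr_out * target_resolution,
              pixel_size = target_resolution, nodata = grid$nodata,
              crs = grid$crs)
}

#' Aggregate a raster by an integer factor (block mean)
#'
#' Blocks containing any missing pixel become `NA`; trailing rows/columns not
#' filling a whole block are dropped with a warning.
#'
#' @param grid a [raster_grid()].
#' @param factor integer aggregation factor (>= 1).
#' @return a [raster_grid()] with `factor`-times larger pixels.
#' @export
aggregate_raster <- function(grid, factor) {
  stopifnot(factor >= 1, abs(factor - round(factor)) < 1e-9)
  resample_mean(grid, grid$pixel_size * round(factor))
}

#' Terrain slope in degrees (Horn 3x3 kernel)
#'
#' The de facto GIS standard finite-difference estimator; border pixels (and
#' pixels with any missing neighbor) are `NA`.
#'
#' @param dtm a [raster_grid()] DTM, conventionally the 10-m aggregate.
#' @return a [raster_grid()] of slope in degrees.
#' @export
terrain_slope <- function(dtm) {
  z <- dtm$values
  if (nrow(z) < 3L || ncol(z) < 3L) stop("grid smaller than 3x3")
  px <- dtm$pixel_size
  s <- function(dr, dc) .shift(z, dr, dc)
  # x increases east (+col), y: rows grow southwards; magnitude only is used
  p <- ((s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
          (s(-1, -1) + 2 * s(0, -1) + s(1, -1))) / (8 * px)
  q <- ((s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
          (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))) / (8 * px)
  deg <- atan(sqrt(p^2 + q^2)) * 180 / pi
  out <- dtm; out$values <- deg
  out
}

#' Fill terrain depressions (Planchon-Darboux)
#'
#' Raises every cell no higher than necessary so that each has a monotone
#' descending path (gradient at least `eps` per step) to the grid edge.
#' Idempotent and never below the input surface. Cells adjacent to missing
#' data are treated as edge outlets.
#'
#' @param dtm a [raster_grid()].
#' @param eps minimum enforced drop per cell step (m); a tiny positive value
#'   resolves flats deterministically for D8 routing.
#' @return filled [raster_grid()].
#' @export
fill_pits <- function(dtm, eps = 1e-4) {
  z <- dtm$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 1L || nc < 1L) stop("empty grid")
  na <- is.na(z)
  boundary <- matrix(FALSE, nr, nc)
  boundary[1, ] <- TRUE; boundary[nr, ] <- TRUE
  boundary[, 1] <- TRUE; boundary[, nc] <- TRUE
  for (k in seq_len(nrow(.d8)))
    boundary <- boundary | .shift(na, .d8$dr[k], .d8$dc[k], fill = FALSE)
  w <- matrix(Inf, nr, nc)
  w[boundary] <- z[boundary]
  w[na] <- NA_real_
  repeat {
    nb_min <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(.d8))) {
      sh <- .shift(w, .d8$dr[k], .d8$dc[k], fill = Inf)
      sh[is.na(sh)] <- Inf
      nb_min <- pmin(nb_min, sh + eps)
    }
    w_new <- pmax(z, pmin(w, nb_min))
    w_new[na] <- NA_real_
    changed <- w_new != w
    converged <- !any(changed[!na]) && !any(is.infinite(w_new[!na]))
    w <- w_new
    if (converged) break
  }
  out <- dtm; out$values <- w
  out
}

# Steepest-descent D8 receiver for each cell: linear index of the neighbor
# with the largest positive drop/distance, ties broken by the fixed
# E,SE,S,SW,W,NW,N,NE order; NA (no receiver) marks an outlet.
.d8_receivers <- function(z, px) {
  nr <- nrow(z); nc <- ncol(z)
  idx <- matrix(seq_along(z), nr, nc)
  best_drop <- matrix(0, nr, nc)
  recv <- matrix(NA_integer_, nr, nc)
  for (k in seq_len(nrow(.d8))) {
    dr <- .d8$dr[k]; dc <- .d8$dc[k]
    dist <- px * sqrt(dr^2 + dc^2)
    zn <- .shift(z, dr, dc)
    drop <- (z - zn) / dist
    nb <- .shift(idx, dr, dc)
    better <- !is.na(drop) & drop > best_drop
    best_drop[better] <- drop[better]
    recv[better] <- nb[better]
  }
  recv[is.na(z)] <- NA_integer_
  recv
}

#' D8 flow accumulation
#'
#' Routes each cell's area to its single steepest-descent neighbor of eight
#' and accumulates contributing area downslope. Accumulation counts the
#' cell's own area, so a local maximum carries one pixel area. Expects a
#' pit-filled surface; unresolved flats drain by the deterministic
#' E,SE,S,SW,W,NW,N,NE tie-break built into the receiver choice.
#'
#' @param dtm_filled a pit-filled [raster_grid()].
#' @return a [raster_grid()] of contributing area in m^2.
#' @export
flow_accumulation <- function(dtm_filled) {
  z <- dtm_filled$values
  px <- dtm_filled$pixel_size
  recv <- .d8_receivers(z, px)
  acc <- rep(1, length(z))
  acc[is.na(z)] <- NA_real_
  ord <- order(z, decreasing = TRUE, na.last = NA)
  for (i in ord) {
    r <- recv[i]
    if (!is.na(r)) acc[r] <- acc[r] + acc[i]
  }
  out <- dtm_filled
  out$values <- matrix(acc * px^2, nrow(z), ncol(z))
  out
}

#' Topographic wetness index
#'
#' TWI = ln(a / tan b), with a the specific catchment area (D8 accumulation
#' divided by the cell width) and b the local Horn slope of the pit-filled
#' surface, computed at a coarsened resolution (default 25 m) from the 10-m
#' DTM aggregate to smooth over small pits and mounds. `tan b` is floored at
#' `eps_tan` to keep TWI finite on flats. Invariant under elevation shifts.
#'
#' @param dtm a [raster_grid()] DTM (conventionally the 10-m aggregate).
#' @param target_resolution working resolution in metres (default 25).
#' @param eps_tan floor for tan(slope) (default 0.001).
#' @return a [raster_grid()] of TWI at the target resolution (border `NA`
#'   where slope is undefined).
#' @export
twi <- function(dtm, target_resolution = 25, eps_tan = 0.001) {
  coarse <- if (abs(target_resolution - dtm$pixel_size) < 1e-9) dtm
            else resample_mean(dtm, target_resolution)
  filled <- fill_pits(coarse)
  acc <- flow_accumulation(filled)
  slp <- terrain_slope(filled)
  sca <- acc$values / filled$pixel_size
  tanb <- pmax(tan(slp$values * pi / 180), eps_tan)
  out <- filled
  out$values <- log(sca / tanb)
  out
}

# Per-cell mean of a (possibly coarser) raster, keyed by the 1-ha cell grid
# anchored at (xll, ytop). Pixels are assigned to cells by their centres.
.zonal_mean <- function(grid, xll, ytop, cell_size) {
  ctr <- pixel_centers(grid)
  v <- grid$values
  cc <- floor((ctr$x - xll) / cell_size) + 1L
  cr <- floor((ytop - ctr$y) / cell_size) + 1L
  df <- data.frame(cr = rep(cr, times = ncol(v)),
                   cc = rep(cc, each = nrow(v)),
                   val = as.vector(v))
  ag <- stats::aggregate(val ~ cr + cc, data = df, FUN = mean,
                         na.rm = TRUE, na.action = stats::na.pass)
  ag$val[is.nan(ag$val)] <- NA_real_
  ag
}

#' Per-cell topographic covariates
#'
#' Computes, for each analysis cell, mean elevation (native DTM), mean slope
#' (Horn slope of the 10-m DTM aggregate) and mean TWI (25-m working
#' resolution), ignoring missing pixels. Cells wholly missing get `NA`.
#'
#' @param dtm native-resolution [raster_grid()] DTM.
#' @param cells cell table from [tile_cells()] on the reference grid.
#' @param cell_size analysis cell edge (m), as used for `cells`.
#' @param slope_resolution resolution for the slope DTM aggregate (m).
#' @param twi_resolution working resolution of TWI (m).
#' @return data.frame: `cell_row`, `cell_col`, `elevation`, `slope`, `twi`.
#' @export
cell_topography <- function(dtm, cells, cell_size = 100,
                            slope_resolution = 10, twi_resolution = 25) {
  dtm10 <- if (slope_resolution > dtm$pixel_size)
    resample_mean(dtm, slope_resolution) else dtm
  slope10 <- terrain_slope(dtm10)
  twi25 <- twi(dtm10, twi_resolution)
  ytop <- dtm$yll + nrow(dtm$values) * dtm$pixel_size
  z_elev <- .zonal_mean(dtm, dtm$xll, ytop, cell_size)
  z_slope <- .zonal_mean(slope10, dtm$xll, ytop, cell_size)
  z_twi <- .zonal_mean(twi25, dtm$xll, ytop, cell_size)
  out <- cells[, c("cell_row", "cell_col")]
  pick <- function(z, r, c) {
    i <- match(paste(r, c), paste(z$cr, z$cc))
    z$val[i]
  }
  out$elevation <- pick(z_elev, out$cell_row, out$cell_col)
  out$slope <- pick(z_slope, out$cell_row, out$cell_col)
  out$twi <- pick(z_twi, out$cell_row, out$cell_col)
  out
}
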