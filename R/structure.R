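#' Outlier-robust, bounded coefficient of height variation
#'
#' Quantile-ratio coefficient of variation, (q95 - q5) / (q95 + q5), computed
#' with linearly interpolated quantiles. For non-negative heights it is
#' bounded in \[0, 1) and insensitive to the extreme 5% tails, which makes it
#' far more stable than sd/mean on canopy height distributions with emergent
#' outliers. All-zero input returns 0 by convention.
#'
#' @param values numeric vector of canopy heights (m); `NA` dropped.
#' @return unitless CV in \[0, 1).
#' @export
robust_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("robust_cv needs at least 2 values")
  q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  if (q[1] + q[2] == 0) return(0)
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Canopy structural metrics for one analysis cell
#'
#' The four standard per-cell descriptors of canopy 3D structure:
#' \describe{
#'   \item{h_mean}{mean of valid CHM pixels (m).}
#'   \item{h_max}{98th percentile of the CHM (m), linear interpolation.}
#'   \item{h_cv}{[robust_cv()] of the heights, unitless in \[0, 1).}
#'   \item{gf}{gap fraction: proportion of valid pixels below
#'     `gap_height_cutoff` (default 10 m, i.e. GF10).}
#' }
#'
#' @param chm_window numeric matrix of CHM values for the cell.
#' @param gap_height_cutoff height cutoff for the gap fraction (m).
#' @param min_valid_fraction minimum fraction of valid pixels required.
#' @return list with `h_mean`, `h_max`, `h_cv`, `gf`, `n_valid`.
#' @export
cell_structure <- function(chm_window, gap_height_cutoff = 10,
                           min_valid_fraction = 0.95) {
  v <- chm_window[!is.na(chm_window)]
  if (length(v) < min_valid_fraction * length(chm_window))
    stop(sprintf("insufficient valid pixels in cell (%d of %d)",
                 length(v), length(chm_window)))
  list(h_mean = mean(v),
       h_max = stats::quantile(v, 0.98, names = FALSE, type = 7),
       h_cv = robust_cv(v),
       gf = mean(v < gap_height_cutoff),
       n_valid = length(v))
}

#' Per-cell structure table for a CHM
#'
#' Applies [cell_structure()] to every retained cell. Cells that are
#' incomplete or exceed the missing-data allowance are skipped.
#'
#' @param chm a [raster_grid()] CHM.
#' @param cells cell table from [tile_cells()].
#' @param gap_height_cutoff height cutoff for GF10 (m).
#' @param q a [quality_thresholds()] (controls the missing-data allowance).
#' @return data.frame with one row per retained cell.
#' @export
cell_structure_table <- function(chm, cells, gap_height_cutoff = 10,
                                 q = quality_thresholds()) {
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    w <- cell_window(chm, cell)
    if (!cell$complete || mean(is.na(w)) > q$max_missing_fraction) return(NULL)
    s <- cell_structure(w, gap_height_cutoff,
                        min_valid_fraction = 1 - q$max_missing_fraction)
    data.frame(cell_row = cell$cell_row, cell_col = cell$cell_col,
               x = cell$x, y = cell$y,
               h_mean = s$h_mean, h_max = s$h_max, h_cv = s$h_cv,
               gf10 = s$gf, n_valid = s$n_valid)
  })
  do.call(rbind, rows)
}
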