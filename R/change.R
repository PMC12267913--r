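#' Dynamic class codes
#'
#' Integer codes used in change maps and truth labels: 1 gap formation,
#' 2 canopy disturbance, 3 gap persistence, 4 gap closure, 5 intact canopy.
#' @export
change_classes <- c(gap_formation = 1L, canopy_disturbance = 2L,
                    gap_persistence = 3L, gap_closure = 4L,
                    intact_canopy = 5L)

#' Change-classification parameters
#'
#' @param gap_def a [gap_definition()] applied to both epochs.
#' @param disturbance_drop height decrease (m) a pixel must exceed (strictly)
#'   to be a disturbance candidate; default 5.
#' @param disturbance_min_area minimum area (m^2) of a connected candidate
#'   region; default 25.
#' @param interval_years acquisition interval in decimal years.
#' @return list of class `change_params`.
#' @export
change_params <- function(gap_def = gap_definition(), disturbance_drop = 5,
                          disturbance_min_area = 25, interval_years) {
  stopifnot(disturbance_drop > 0, disturbance_min_area > 0,
            interval_years > 0)
  structure(list(gap_def = gap_def, disturbance_drop = disturbance_drop,
                 disturbance_min_area = disturbance_min_area,
                 interval_years = interval_years),
            class = "change_params")
}

#' Height difference between the two epochs
#'
#' @param pair a [chm_pair()].
#' @return a [raster_grid()] of per-pixel height change (m, t2 - t1); `NA`
#'   wherever either epoch is missing.
#' @export
chm_delta <- function(pair) {
  out <- pair$chm1
  out$values <- pair$chm2$values - pair$chm1$values
  out
}

#' Detect canopy disturbance regions
#'
#' Disturbance is contiguous canopy height loss strictly greater than
#' `disturbance_drop` over at least `disturbance_min_area`, outside the
#' qualifying gap sets of both epochs (loss that opens a gap is gap
#' formation, not disturbance).
#'
#' @param delta height-change raster from [chm_delta()].
#' @param gap1,gap2 `gap_set`s of epochs 1 and 2.
#' @param p a [change_params()].
#' @return a [raster_grid()] with 1 on disturbance pixels, 0 elsewhere, `NA`
#'   where `delta` is missing.
#' @export
detect_disturbance <- function(delta, gap1, gap2, p) {
  cand <- !is.na(delta$values) & delta$values < -p$disturbance_drop &
    !.in_gap(gap1) & !.in_gap(gap2)
  lab <- .label_components(cand, p$gap_def$connectivity)
  px <- delta$pixel_size
  sizes <- tabulate(lab[lab > 0L])
  ok <- which(sizes * px^2 >= p$disturbance_min_area - 1e-9)
  out <- delta
  out$values <- (lab > 0L & lab %in% ok) + 0
  out$values[is.na(delta$values)] <- NA_real_
  out
}

#' Classify per-pixel canopy change into the five dynamic classes
#'
#' Membership in the epoch-wise qualifying gap sets takes precedence:
#' gap at both epochs = persistence; gap only at t1 = closure; gap only at
#' t2 = formation; otherwise a pixel inside a qualifying disturbance region
#' ([detect_disturbance()]) = disturbance; everything else = intact canopy.
#' The five classes plus missing data partition the raster exactly.
#'
#' @param pair a [chm_pair()].
#' @param p a [change_params()]; defaults to the pair's interval and the
#'   standard gap definition.
#' @param gap1,gap2 optional precomputed `gap_set`s (detected from the pair's
#'   CHMs when omitted).
#' @param types optional forest-type raster (for relative-mode gaps).
#' @return list of class `change_map`: `class_map` (a [raster_grid()] of
#'   codes, see [change_classes]), `delta`, `gap1`, `gap2`, `params`.
#' @export
classify_change <- function(pair, p = NULL, gap1 = NULL, gap2 = NULL,
                            types = NULL) {
  if (is.null(p))
    p <- change_params(interval_years = pair$interval_years)
  if (is.null(gap1)) gap1 <- detect_gaps(pair$chm1, p$gap_def, types)
  if (is.null(gap2)) gap2 <- detect_gaps(pair$chm2, p$gap_def, types)
  delta <- chm_delta(pair)
  dist <- detect_disturbance(delta, gap1, gap2, p)
  g1 <- .in_gap(gap1); g2 <- .in_gap(gap2)
  cls <- matrix(change_classes[["intact_canopy"]],
                nrow(delta$values), ncol(delta$values))
  cls[dist$values > 0 & !is.na(dist$values)] <- change_classes[["canopy_disturbance"]]
  cls[!g1 & g2] <- change_classes[["gap_formation"]]
  cls[g1 & !g2] <- change_classes[["gap_closure"]]
  cls[g1 & g2] <- change_classes[["gap_persistence"]]
  cls[is.na(delta$values)] <- NA_real_
  class_map <- delta; class_map$values <- cls
  structure(list(class_map = class_map, delta = delta,
                 gap1 = gap1, gap2 = gap2, params = p),
            class = "change_map")
}

#' Per-cell canopy dynamics rates
#'
#' For each retained analysis cell, per-class area fractions, height-change
#' rates and volume-change rates, plus their grouping into canopy gains
#' (persistence + closure + intact, signed), losses (formation + disturbance,
#' reported as absolute values) and net change (gains + signed losses).
#'
#' Units: volume rates are m^3 per hectare of valid cell area per year
#' (signed per class); `height_<class>` is the class-conditional mean height
#' change rate (m/yr over that class's pixels), while `height_cell_<class>`
#' and the gains/losses/net height totals are normalised by the whole cell
#' (m/yr per cell), the two readings of a per-hectare height rate.
#'
#' @param change a `change_map` from [classify_change()].
#' @param cells cell table from [tile_cells()].
#' @param q a [quality_thresholds()] (missing-data allowance).
#' @param types optional forest-type raster of integer codes; adds
#'   `forest_type` and applies the purity rule.
#' @param type_levels named integer vector mapping type names to codes
#'   (required with `types`).
#' @return data.frame, one row per retained cell.
#' @export
summarize_cells <- function(change, cells, q = quality_thresholds(),
                            types = NULL, type_levels = NULL) {
  cls <- change$class_map$values
  dlt <- change$delta$values
  px <- change$class_map$pixel_size
  iy <- change$params$interval_years
  cls_names <- names(change_classes)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    rr <- cell$row0:(cell$row0 + cell$nrow - 1L)
    cc <- cell$col0:(cell$col0 + cell$ncol - 1L)
    cw <- cls[rr, cc, drop = FALSE]
    dw <- dlt[rr, cc, drop = FALSE]
    n_all <- length(cw)
    valid <- !is.na(cw)
    n_valid <- sum(valid)
    forest_type <- NA_character_
    if (!is.null(types)) {
      fr <- cell_type_fractions(types, cell,
                                stats::setNames(type_levels, names(type_levels)))
      cv <- cell_validity(dw, q, fr, complete = cell$complete)
      if (!cv$valid) return(NULL)
      forest_type <- cv$forest_type
    } else {
      if (!cell$complete || (n_all - n_valid) / n_all > q$max_missing_fraction)
        return(NULL)
    }
    area_ha <- n_valid * px^2 / 1e4
    out <- data.frame(cell_row = cell$cell_row, cell_col = cell$cell_col,
                      x = cell$x, y = cell$y, forest_type = forest_type,
                      n_valid = n_valid, nodata_fraction = 1 - n_valid / n_all)
    vol_signed <- numeric(length(cls_names))
    for (k in seq_along(cls_names)) {
      code <- change_classes[[k]]
      in_k <- valid & cw == code
      nk <- sum(in_k)
      dh <- dw[in_k]
      out[[paste0("frac_", cls_names[k])]] <- nk / n_valid
      out[[paste0("height_", cls_names[k])]] <-
        if (nk) mean(dh) / iy else 0
      out[[paste0("height_cell_", cls_names[k])]] <-
        if (nk) sum(dh) / n_valid / iy else 0
      vol_signed[k] <- sum(dh) * px^2 / iy / area_ha
      out[[paste0("volume_", cls_names[k])]] <- vol_signed[k]
    }
    gain_k <- match(c("gap_persistence", "gap_closure", "intact_canopy"),
                    cls_names)
    loss_k <- match(c("gap_formation", "canopy_disturbance"), cls_names)
    out$gains_volume <- sum(vol_signed[gain_k])
    out$losses_volume <- abs(sum(vol_signed[loss_k]))
    out$net_volume <- sum(vol_signed)
    gain_px <- valid & cw %in% change_classes[gain_k]
    loss_px <- valid & cw %in% change_classes[loss_k]
    out$gains_height <- sum(dw[gain_px]) / n_valid / iy
    out$losses_height <- abs(sum(dw[loss_px])) / n_valid / iy
    out$net_height <- sum(dw[valid]) / n_valid / iy
    out
  })
  do.call(rbind, rows)
}
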