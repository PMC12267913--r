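#' Canopy gap definition
#'
#' Parameters of the gap segmentation. In `fixed` mode a pixel is a gap
#' candidate when its height is strictly below `height_cutoff` (default 10 m,
#' consistent with GF10's "< 10 m"); in `relative` mode the cutoff is
#' `relative_fraction` times a forest-type-specific reference height.
#' Candidate pixels are merged into connected components (8-neighbor by
#' default) and components smaller than `min_area` are discarded.
#'
#' @param mode `"fixed"` or `"relative"`.
#' @param height_cutoff fixed height cutoff (m), used when `mode = "fixed"`.
#' @param relative_fraction fraction of the reference height
#'   (default 0.5), used when `mode = "relative"`.
#' @param reference_height named numeric vector of per-type mean canopy
#'   heights (m), required for `mode = "relative"`.
#' @param min_area minimum gap area (m^2), default 25.
#' @param connectivity 4 or 8 (default 8: diagonal adjacency merges).
#' @return list of class `gap_definition`.
#' @export
gap_definition <- function(mode = c("fixed", "relative"), height_cutoff = 10,
                           relative_fraction = 0.5, reference_height = NULL,
                           min_area = 25, connectivity = 8) {
  mode <- match.arg(mode)
  stopifnot(height_cutoff > 0, relative_fraction > 0, min_area > 0,
            connectivity %in% c(4, 8))
  if (mode == "relative" && is.null(reference_height))
    stop("relative mode requires reference_height (per forest type)")
  structure(list(mode = mode, height_cutoff = height_cutoff,
                 relative_fraction = relative_fraction,
                 reference_height = reference_height,
                 min_area = min_area, connectivity = as.integer(connectivity)),
            class = "gap_definition")
}

#' Gap candidate mask from a CHM
#'
#' Pixel-wise test against the applied cutoff: strictly `h < cutoff`. Heights
#' exactly at the cutoff are not gap candidates. Missing pixels are excluded
#' (`NA` in the mask).
#'
#' @param chm a [raster_grid()] CHM.
#' @param d a [gap_definition()].
#' @param types optional [raster_grid()] of forest-type codes, required for
#'   relative mode; `d$reference_height` must be named by those codes.
#' @return a [raster_grid()] with values 1 (candidate), 0, or `NA`.
#' @export
gap_mask <- function(chm, d = gap_definition(), types = NULL) {
  v <- chm$values
  if (d$mode == "fixed") {
    cutoff <- d$height_cutoff
    m <- v < cutoff
  } else {
    if (is.null(types)) stop("relative mode requires a forest-type raster")
    if (!same_geometry(chm, types)) stop("type raster not aligned with CHM")
    ref <- d$reference_height[as.character(types$values)]
    cutoff <- matrix(d$relative_fraction * ref, nrow(v), ncol(v))
    m <- v < cutoff
  }
  out <- chm
  out$values <- m + 0  # logical -> 0/1, keeps NA
  out
}

# Connected-component labels of a logical matrix via the pixel-adjacency
# graph (igraph::components, as raster clump tools do). Returns an integer
# matrix, 0 = background, components numbered in raster-scan order (by row,
# then column, from the top-left) of their first pixel.
.label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  fg <- which(mask)  # column-major linear indices
  lab <- matrix(0L, nr, nc)
  if (!length(fg)) return(lab)
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    both <- mask & .shift(mask, o[1], o[2], fill = FALSE)
    i <- which(both)
    if (length(i)) {
      j <- i + o[1] + o[2] * nr
      edges <- c(edges, rbind(vid[i], vid[j]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # raster-scan (row-major) index of each foreground pixel
  scan_idx <- ((fg - 1L) %% nr) * nc + ((fg - 1L) %/% nr) + 1L
  first <- tapply(scan_idx, memb, min)
  new_id <- integer(length(first))
  new_id[order(first)] <- seq_along(first)
  lab[fg] <- new_id[memb]
  lab
}

#' Label qualifying gaps in a candidate mask
#'
#' Connected components of the candidate mask under the definition's
#' connectivity; components below `min_area` are discarded and the survivors
#' are renumbered 1..K in raster-scan order of their first pixel.
#'
#' @param mask candidate mask from [gap_mask()] (a [raster_grid()] of 0/1/NA).
#' @param d a [gap_definition()].
#' @return list of class `gap_set`: `label_map` (a [raster_grid()] of gap ids,
#'   0 = non-gap), `gaps` (data.frame: `id`, `n_pixels`, `area` m^2, centroid
#'   `x`, `y`), and `definition`.
#' @export
label_gaps <- function(mask, d = gap_definition()) {
  px <- mask$pixel_size
  m <- mask$values > 0
  lab <- .label_components(m, d$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * px^2 >= d$min_area - 1e-9)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  ctr <- pixel_centers(mask)
  gaps <- if (length(keep)) {
    idx <- which(lab > 0L)
    id <- lab[idx]
    rr <- (idx - 1L) %% nrow(m) + 1L
    cc <- (idx - 1L) %/% nrow(m) + 1L
    data.frame(id = sort(unique(id)),
               n_pixels = as.vector(tabulate(id)),
               area = as.vector(tabulate(id)) * px^2,
               x = as.vector(tapply(ctr$x[cc], id, mean)),
               y = as.vector(tapply(ctr$y[rr], id, mean)))
  } else {
    data.frame(id = integer(0), n_pixels = integer(0), area = numeric(0),
               x = numeric(0), y = numeric(0))
  }
  label_map <- mask
  label_map$values <- lab + 0
  label_map$values[is.na(mask$values)] <- NA_real_
  structure(list(label_map = label_map, gaps = gaps, definition = d),
            class = "gap_set")
}

#' Detect qualifying gaps in a CHM
#'
#' Convenience wrapper: [gap_mask()] then [label_gaps()].
#' @inheritParams gap_mask
#' @return a `gap_set` (see [label_gaps()]).
#' @export
detect_gaps <- function(chm, d = gap_definition(), types = NULL) {
  label_gaps(gap_mask(chm, d, types), d)
}

# Logical matrix: pixel belongs to a qualifying gap.
.in_gap <- function(gap_set) {
  m <- gap_set$label_map$values
  !is.na(m) & m > 0
}

#' Per-gap statistics and landscape gap fraction
#'
#' @param gap_set a `gap_set` from [label_gaps()].
#' @param chm the CHM the gaps were detected in.
#' @return data.frame with one row per gap (`id`, `n_pixels`, `area`, centroid
#'   `x`, `y`, `floor_min`, `floor_mean`, `floor_max` in m) and attribute
#'   `gap_fraction` = labeled area / valid CHM area.
#' @export
gap_statistics <- function(gap_set, chm) {
  lab <- gap_set$label_map$values
  g <- gap_set$gaps
  if (nrow(g)) {
    idx <- which(!is.na(lab) & lab > 0)
    id <- lab[idx]
    h <- chm$values[idx]
    g$floor_min <- as.vector(tapply(h, id, min))
    g$floor_mean <- as.vector(tapply(h, id, mean))
    g$floor_max <- as.vector(tapply(h, id, max))
  } else {
    g$floor_min <- g$floor_mean <- g$floor_max <- numeric(0)
  }
  valid <- sum(!is.na(chm$values))
  attr(g, "gap_fraction") <- if (valid) sum(!is.na(lab) & lab > 0) / valid else 0
  g
}

#' Write gap centroids as GeoJSON
#'
#' Point features (gap centroids) with area and floor-height properties, in
#' the grid's planar coordinates.
#'
#' @param gaps data.frame from [gap_statistics()] (or a `gap_set$gaps`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gaps_geojson <- function(gaps, path) {
  feats <- lapply(seq_len(nrow(gaps)), function(i) {
    props <- as.list(gaps[i, setdiff(names(gaps), c("x", "y"))])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(gaps$x[i], gaps$y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
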