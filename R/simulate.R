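# Synthetic landscape simulator: a terrain gradient defining three forest-type
# zones, type-specific spatially correlated canopy height fields, and
# between-epoch canopy dynamics (intact growth, gap closure, gap persistence,
# new gap formation, partial-height disturbance) applied as disk-shaped events
# with per-pixel truth labels. Event magnitudes keep a safety margin (default
# 2 m) away from the detection thresholds so that, without measurement noise,
# the change classifier must reproduce the truth exactly.

#' Synthetic landscape configuration
#'
#' Defaults describe a 25-ha landscape (500 x 500 m at 1-m pixels) with a
#' ridge-and-valley terrain from c. 50 to 230 m a.s.l., three elevation-banded
#' forest types (alluvial valleys, sandstone mid-slopes, kerangas tops) with
#' canopy mean heights ordered alluvial > sandstone > kerangas, and per-type
#' dynamics rates chosen so the expected alluvial:kerangas volume loss ratio
#' is about 4.7 and the gain ratio about 2.5 (see [expected_rates()]).
#'
#' @param extent landscape size c(x, y) in metres.
#' @param pixel_size pixel edge (m).
#' @param seed integer seed; the whole bundle is deterministic per seed.
#' @param terrain list: `base`, `relief` (m), `wavelength` (m ridge spacing),
#'   `noise_sd` (m), `noise_range` (m correlation range of terrain noise).
#' @param type_thresholds elevation cutoffs c(alluvial_max, sandstone_max):
#'   below the first = alluvial, below the second = sandstone, else kerangas.
#' @param canopy per-type list of `mean`, `sd` (m) and correlation `range`
#'   (m) of the canopy height field.
#' @param dynamics per-type list of `initial_gap_rate` and `formation_rate`
#'   (gaps ha^-1 interval^-1), `closure_fraction`, `growth` (m yr^-1),
#'   `disturbance_rate` (patches ha^-1 interval^-1) and `disturbance_drop`
#'   (c(min, max) m, uniform).
#' @param gap_area c(min, max) m^2 of event disk areas (uniform).
#' @param gap_cutoff gap height threshold the events are designed around (m).
#' @param margin safety margin (m) between event magnitudes and the
#'   detection thresholds; 0 disables it (threshold-sensitivity studies).
#' @param drift_sd sd (m) of the height drift on persistent gap floors.
#' @param closure_rise c(min, max) m added above `gap_cutoff + margin` when a
#'   gap closes.
#' @param noise_sd measurement noise sd (m) added to the epoch-2 CHM.
#' @param date1,date2 acquisition dates (give a 5.34-yr interval by default).
#' @return list of class `landscape_config`.
#' @export
landscape_config <- function(
    extent = c(500, 500), pixel_size = 1, seed = 1,
    terrain = list(base = 50, relief = 180, wavelength = 1000,
                   noise_sd = 3, noise_range = 60),
    type_thresholds = c(alluvial_max = 110, sandstone_max = 180),
    canopy = list(
      alluvial = list(mean = 42, sd = 8, range = 25),
      sandstone = list(mean = 35, sd = 6, range = 22),
      kerangas = list(mean = 24, sd = 2.5, range = 18)),
    dynamics = list(
      alluvial = list(initial_gap_rate = 6, formation_rate = 5.8,
                      closure_fraction = 0.5, growth = 0.30,
                      disturbance_rate = 5.8, disturbance_drop = c(10, 16)),
      sandstone = list(initial_gap_rate = 4, formation_rate = 4,
                       closure_fraction = 0.45, growth = 0.20,
                       disturbance_rate = 4, disturbance_drop = c(9, 14)),
      kerangas = list(initial_gap_rate = 2, formation_rate = 2.2,
                      closure_fraction = 0.35, growth = 0.12,
                      disturbance_rate = 2.2, disturbance_drop = c(7.5, 9.5))),
    gap_area = c(30, 120), gap_cutoff = 10, margin = 2, drift_sd = 0.3,
    closure_rise = c(0, 6), noise_sd = 0.25,
    date1 = "2014-10-15", date2 = "2020-02-15") {
  stopifnot(all(extent > 0), pixel_size > 0, margin >= 0,
            diff(type_thresholds) > 0, gap_area[1] >= 30,
            all(vapply(dynamics, function(d)
      d$closure_fraction >= 0 && d$closure_fraction <= 1 &&
        d$formation_rate >= 0 && d$disturbance_rate >= 0 &&
        d$initial_gap_rate >= 0, logical(1))))
  means <- vapply(canopy, `[[`, numeric(1), "mean")
  stopifnot(means[["alluvial"]] > means[["sandstone"]],
            means[["sandstone"]] > means[["kerangas"]])
  structure(list(extent = extent, pixel_size = pixel_size,
                 seed = as.integer(seed), terrain = terrain,
                 type_thresholds = type_thresholds, canopy = canopy,
                 dynamics = dynamics, gap_area = gap_area,
                 gap_cutoff = gap_cutoff, margin = margin,
                 drift_sd = drift_sd, closure_rise = closure_rise,
                 noise_sd = noise_sd, date1 = date1, date2 = date2,
                 interval_years = decimal_years(date1, date2)),
            class = "landscape_config")
}

#' Forest-type code table
#' @export
forest_types <- c(alluvial = 1L, sandstone = 2L, kerangas = 3L)

# Correlated Gaussian field (mean 0, sd 1) by spectral synthesis: white noise
# filtered in the Fourier domain with an exp(-|f| * range) amplitude decay.
# Uses the caller's RNG stream.
.grf <- function(nr, nc, range_m, px) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_m <= 0) return(w)
  fr <- c(0:floor(nr / 2), -seq_len(ceiling(nr / 2) - 1)) / (nr * px)
  fc <- c(0:floor(nc / 2), -seq_len(ceiling(nc / 2) - 1)) / (nc * px)
  fmag <- sqrt(outer(fr^2, fc^2, "+"))
  amp <- exp(-fmag * range_m)
  f <- stats::fft(w) * amp
  out <- Re(stats::fft(f, inverse = TRUE)) / length(w)
  out / stats::sd(out)
}

#' Generate the synthetic terrain
#'
#' Deterministic ridge-and-valley surface: base elevation plus a sinusoidal
#' ridge across x and a gentle cross-slope in y (together spanning exactly
#' `base` to `base + relief` before noise), plus spectrally synthesised
#' correlated noise.
#'
#' @param cfg a [landscape_config()].
#' @return a [raster_grid()] DTM (m a.s.l.).
#' @export
gen_terrain <- function(cfg) {
  set.seed(cfg$seed + 11L)
  px <- cfg$pixel_size
  nc <- round(cfg$extent[1] / px); nr <- round(cfg$extent[2] / px)
  x <- (seq_len(nc) - 0.5) * px
  y <- (nr - seq_len(nr) + 0.5) * px
  tr <- cfg$terrain
  sx <- 0.5 - 0.5 * cos(2 * pi * x / tr$wavelength)
  sy <- y / (nr * px)
  shape <- 0.85 * matrix(sx, nr, nc, byrow = TRUE) +
    0.15 * matrix(sy, nr, nc)
  z <- tr$base + tr$relief * shape
  if (tr$noise_sd > 0)
    z <- z + tr$noise_sd * .grf(nr, nc, tr$noise_range, px)
  raster_grid(z, pixel_size = px)
}

#' Assign forest types by elevation band
#'
#' @param dtm a [raster_grid()] DTM.
#' @param cfg a [landscape_config()].
#' @return a [raster_grid()] of type codes (see [forest_types]).
#' @export
assign_types <- function(dtm, cfg) {
  th <- cfg$type_thresholds
  z <- dtm$values
  t <- matrix(forest_types[["kerangas"]], nrow(z), ncol(z))
  t[z < th[2]] <- forest_types[["sandstone"]]
  t[z < th[1]] <- forest_types[["alluvial"]]
  t[is.na(z)] <- NA_real_
  out <- dtm; out$values <- t
  out
}

# Linear (column-major) indices of a disk of ~area_m2 centred at (r0, c0),
# bumping the radius until at least min_px pixels are covered.
.disk_pixels <- function(r0, c0, area_m2, px, nr, nc, min_px = 26L) {
  radius <- sqrt(area_m2 / pi) / px
  repeat {
    w <- ceiling(radius)
    rs <- max(1L, r0 - w):min(nr, r0 + w)
    cs <- max(1L, c0 - w):min(nc, c0 + w)
    dr2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    sel <- which(dr2 <= radius^2)
    if (length(sel) >= min_px) break
    radius <- radius + 0.25
  }
  rr <- rep(rs, times = length(cs))[sel]
  cc <- rep(cs, each = length(rs))[sel]
  (cc - 1L) * nr + rr
}

# 1-pixel Chebyshev dilation of a set of linear indices (keeps events
# 8-connectivity-separated from each other and from existing gaps).
.dilate1 <- function(idx, nr, nc) {
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    r2 <- rr + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

#' Generate the epoch-1 canopy height model
#'
#' Per forest type, a spatially correlated height field with the configured
#' mean/sd/range, floored at `gap_cutoff + margin` so the background canopy
#' can never read as gap, with disk-shaped initial gaps (floors uniform on
#' \[0, cutoff - margin\]) injected at the type's `initial_gap_rate` under
#' overlap rejection.
#'
#' @param dtm,types rasters from [gen_terrain()] / [assign_types()].
#' @param cfg a [landscape_config()].
#' @return list: `chm` ([raster_grid()]), `gap_map` (integer matrix of
#'   initial gap ids, 0 elsewhere), `gaps` (data.frame registry of the
#'   injected gaps).
#' @export
gen_chm <- function(dtm, types, cfg) {
  set.seed(cfg$seed + 23L)
  px <- cfg$pixel_size
  tv <- types$values
  nr <- nrow(tv); nc <- ncol(tv)
  h <- matrix(0, nr, nc)
  for (tn in names(forest_types)) {
    code <- forest_types[[tn]]
    cp <- cfg$canopy[[tn]]
    sel <- which(tv == code)
    if (!length(sel)) next
    field <- cp$mean + (if (cp$sd > 0) cp$sd * .grf(nr, nc, cp$range, px)
                        else matrix(0, nr, nc))
    h[sel] <- field[sel]
  }
  floor_bg <- cfg$gap_cutoff + cfg$margin
  h <- pmax(h, floor_bg)
  occupied <- matrix(FALSE, nr, nc)
  gap_map <- matrix(0L, nr, nc)
  regs <- list(); gid <- 0L
  edge <- ceiling(sqrt(max(cfg$gap_area) / pi) / px) + 3L
  interior <- matrix(FALSE, nr, nc)
  interior[(edge + 1):(nr - edge), (edge + 1):(nc - edge)] <- TRUE
  for (tn in names(forest_types)) {
    code <- forest_types[[tn]]
    dyn <- cfg$dynamics[[tn]]
    zone_ha <- sum(tv == code, na.rm = TRUE) * px^2 / 1e4
    n_gaps <- stats::rpois(1, dyn$initial_gap_rate * zone_ha)
    cand <- which(tv == code & interior)
    for (g in seq_len(n_gaps)) {
      if (!length(cand)) break
      placed <- FALSE
      for (try in 1:300) {
        ctr <- cand[sample.int(length(cand), 1L)]
        r0 <- (ctr - 1L) %% nr + 1L; c0 <- (ctr - 1L) %/% nr + 1L
        area <- stats::runif(1, cfg$gap_area[1], cfg$gap_area[2])
        d <- .disk_pixels(r0, c0, area, px, nr, nc)
        dd <- .dilate1(d, nr, nc)
        if (any(occupied[dd])) next
        gid <- gid + 1L
        floors <- stats::runif(length(d), 0, cfg$gap_cutoff - cfg$margin)
        h[d] <- floors
        gap_map[d] <- gid
        occupied[dd] <- TRUE
        regs[[gid]] <- data.frame(id = gid, forest_type = tn,
                                  row = r0, col = c0,
                                  n_pixels = length(d),
                                  area = length(d) * px^2,
                                  floor_mean = mean(floors))
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place an initial gap in ", tn)
    }
  }
  chm <- dtm; chm$values <- h
  list(chm = chm, gap_map = gap_map,
       gaps = if (length(regs)) do.call(rbind, regs) else
         data.frame(id = integer(0), forest_type = character(0),
                    row = integer(0), col = integer(0),
                    n_pixels = integer(0), area = numeric(0),
                    floor_mean = numeric(0)))
}

#' Evolve the canopy one acquisition interval forward
#'
#' Applies, in order: intact growth (`growth * interval` on all non-gap
#' pixels), gap closure (a Bernoulli `closure_fraction` subset of the
#' epoch-1 gaps is raised to `gap_cutoff + margin + U(closure_rise)`),
#' gap persistence (remaining gap floors drift by clipped Gaussian steps,
#' staying below `gap_cutoff - margin`), gap formation and canopy
#' disturbance (Poisson-placed disks per forest-type zone, overlap-rejected
#' and kept one pixel clear of all other events; disturbance disks only
#' where the pre-change canopy is tall enough that the drop cannot open a
#' gap), then Gaussian measurement noise on the epoch-2 CHM. Every pixel
#' receives a truth label at event-application time.
#'
#' @param chm1 epoch-1 CHM from [gen_chm()].
#' @param types forest-type raster.
#' @param cfg a [landscape_config()].
#' @param gap_map integer matrix of epoch-1 gap ids (from [gen_chm()]); when
#'   `NULL` it is recovered by segmenting `chm1` with the configured cutoff.
#' @return list: `chm2` ([raster_grid()]), `truth` ([raster_grid()] of codes
#'   as in [change_classes]), `events` (registry data.frame: `event_id`,
#'   `kind`, `forest_type`, `row`, `col`, `n_pixels`, `area`, `magnitude`).
#' @export
evolve_chm <- function(chm1, types, cfg, gap_map = NULL) {
  set.seed(cfg$seed + 37L)
  px <- cfg$pixel_size
  h1 <- chm1$values
  tv <- types$values
  nr <- nrow(h1); nc <- ncol(h1)
  iy <- cfg$interval_years
  if (is.null(gap_map)) {
    gs <- detect_gaps(chm1, gap_definition(height_cutoff = cfg$gap_cutoff))
    gap_map <- gs$label_map$values
    gap_map[is.na(gap_map)] <- 0
    storage.mode(gap_map) <- "integer"
  }
  in_gap1 <- gap_map > 0L
  h2 <- h1
  truth <- matrix(change_classes[["intact_canopy"]], nr, nc)
  events <- list(); eid <- 0L
  # intact growth on every non-gap pixel (later events overwrite their own)
  for (tn in names(forest_types)) {
    sel <- !in_gap1 & tv == forest_types[[tn]]
    h2[sel] <- h2[sel] + cfg$dynamics[[tn]]$growth * iy
  }
  # closure / persistence of epoch-1 gaps, decided per gap object
  gap_ids <- setdiff(sort(unique(as.vector(gap_map))), 0L)
  for (g in gap_ids) {
    idx <- which(gap_map == g)
    ctr <- idx[which.min(abs(idx - stats::median(idx)))]
    tn <- names(forest_types)[match(tv[ctr], forest_types)]
    dyn <- cfg$dynamics[[tn]]
    eid <- eid + 1L
    if (stats::runif(1) < dyn$closure_fraction) {
      new_h <- cfg$gap_cutoff + cfg$margin +
        stats::runif(length(idx), cfg$closure_rise[1], cfg$closure_rise[2])
      mag <- mean(new_h - h1[idx])
      h2[idx] <- new_h
      truth[idx] <- change_classes[["gap_closure"]]
      kind <- "closure"
    } else {
      drift <- stats::rnorm(length(idx), 0, cfg$drift_sd)
      new_h <- pmin(pmax(h1[idx] + drift, 0), cfg$gap_cutoff - cfg$margin)
      mag <- mean(new_h - h1[idx])
      h2[idx] <- new_h
      truth[idx] <- change_classes[["gap_persistence"]]
      kind <- "persistence"
    }
    events[[eid]] <- data.frame(event_id = eid, kind = kind,
                                forest_type = tn,
                                row = (ctr - 1L) %% nr + 1L,
                                col = (ctr - 1L) %/% nr + 1L,
                                n_pixels = length(idx),
                                area = length(idx) * px^2,
                                magnitude = mag)
  }
  occupied <- matrix(FALSE, nr, nc)
  occupied[.dilate1(which(in_gap1), nr, nc)] <- TRUE
  edge <- ceiling(sqrt(max(cfg$gap_area) / pi) / px) + 3L
  interior <- matrix(FALSE, nr, nc)
  interior[(edge + 1):(nr - edge), (edge + 1):(nc - edge)] <- TRUE
  place_events <- function(tn, kind) {
    code <- forest_types[[tn]]
    dyn <- cfg$dynamics[[tn]]
    rate <- if (kind == "formation") dyn$formation_rate else dyn$disturbance_rate
    zone_ha <- sum(tv == code, na.rm = TRUE) * px^2 / 1e4
    n_ev <- stats::rpois(1, rate * zone_ha)
    cand <- which(tv == code & interior)
    for (k in seq_len(n_ev)) {
      if (!length(cand)) break
      placed <- FALSE
      for (try in 1:300) {
        ctr <- cand[sample.int(length(cand), 1L)]
        r0 <- (ctr - 1L) %% nr + 1L; c0 <- (ctr - 1L) %/% nr + 1L
        area <- stats::runif(1, cfg$gap_area[1], cfg$gap_area[2])
        d <- .disk_pixels(r0, c0, area, px, nr, nc)
        dd <- .dilate1(d, nr, nc)
        if (any(occupied[dd])) next
        if (kind == "formation") {
          floors <- stats::runif(length(d), 0, cfg$gap_cutoff - cfg$margin)
          mag <- mean(h1[d] - floors)
          h2[d] <<- floors
          truth[d] <<- change_classes[["gap_formation"]]
        } else {
          drop <- stats::runif(1, dyn$disturbance_drop[1],
                               dyn$disturbance_drop[2])
          # the dropped canopy must stay clear of the gap cutoff
          if (min(h1[d]) - drop < cfg$gap_cutoff + cfg$margin + 0.5) next
          mag <- drop
          h2[d] <<- h1[d] - drop
          truth[d] <<- change_classes[["canopy_disturbance"]]
        }
        occupied[dd] <<- TRUE
        eid <<- eid + 1L
        events[[eid]] <<- data.frame(event_id = eid, kind = kind,
                                     forest_type = tn, row = r0, col = c0,
                                     n_pixels = length(d),
                                     area = length(d) * px^2,
                                     magnitude = mag)
        placed <- TRUE
        break
      }
      if (!placed)
        warning("could not place a ", kind, " event in ", tn, call. = FALSE)
    }
  }
  for (tn in names(forest_types)) place_events(tn, "formation")
  for (tn in names(forest_types)) place_events(tn, "disturbance")
  if (cfg$noise_sd > 0)
    h2 <- pmax(h2 + stats::rnorm(length(h2), 0, cfg$noise_sd), 0)
  chm2 <- chm1; chm2$values <- h2
  truth_grid <- chm1; truth_grid$values <- truth
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = integer(0), kind = character(0),
               forest_type = character(0), row = integer(0),
               col = integer(0), n_pixels = integer(0), area = numeric(0),
               magnitude = numeric(0))
  list(chm2 = chm2, truth = truth_grid, events = ev)
}

#' Generate per-pixel acquisition-quality rasters
#'
#' Constant passing values (pulse density 10 m^-2, scan angle 10 deg) with
#' optional injected failing rectangles for exercising the masking rules.
#'
#' @param template a [raster_grid()] giving the geometry.
#' @param fail_patches optional list of lists with `row0`, `col0`, `nrow`,
#'   `ncol` and optional `density` / `scan_angle` values for the patch.
#' @return list of rasters `density`, `scan_angle`.
#' @export
gen_quality_rasters <- function(template, fail_patches = NULL) {
  nr <- nrow(template$values); nc <- ncol(template$values)
  dens <- matrix(10, nr, nc); ang <- matrix(10, nr, nc)
  for (p in fail_patches) {
    rs <- p$row0:(p$row0 + p$nrow - 1L); cs <- p$col0:(p$col0 + p$ncol - 1L)
    if (!is.null(p$density)) dens[rs, cs] <- p$density
    if (!is.null(p$scan_angle)) ang[rs, cs] <- p$scan_angle
  }
  d <- template; d$values <- dens
  a <- template; a$values <- ang
  list(density = d, scan_angle = a)
}

#' Expected per-type volume gain and loss rates of a configuration
#'
#' Closed-form expectations (m^3 ha^-1 yr^-1) of the canopy volume losses
#' (formation + disturbance) and gains (intact growth + closure) implied by
#' a configuration, from the event-rate, area and magnitude distributions.
#' Used to choose the default design point (alluvial:kerangas loss ratio
#' about 4.7, gain ratio about 2.5) and as the configured truth that
#' simulation-based estimates are compared against.
#'
#' @param cfg a [landscape_config()].
#' @return data.frame with one row per forest type: `losses`, `gains`
#'   (m^3 ha^-1 yr^-1) and their components.
#' @export
expected_rates <- function(cfg) {
  iy <- cfg$interval_years
  a_gap <- mean(cfg$gap_area)
  e_floor <- (cfg$gap_cutoff - cfg$margin) / 2
  e_close <- cfg$gap_cutoff + cfg$margin + mean(cfg$closure_rise)
  rows <- lapply(names(forest_types), function(tn) {
    dyn <- cfg$dynamics[[tn]]
    mu <- cfg$canopy[[tn]]$mean
    e_drop <- mean(dyn$disturbance_drop)
    loss_formation <- dyn$formation_rate * a_gap * (mu - e_floor) / iy
    loss_disturbance <- dyn$disturbance_rate * a_gap * e_drop / iy
    event_px <- (dyn$initial_gap_rate + dyn$formation_rate +
                   dyn$disturbance_rate) * a_gap
    gain_intact <- dyn$growth * (1e4 - event_px)
    gain_closure <- dyn$initial_gap_rate * a_gap * dyn$closure_fraction *
      (e_close - e_floor) / iy
    data.frame(forest_type = tn,
               losses = loss_formation + loss_disturbance,
               gains = gain_intact + gain_closure,
               loss_formation = loss_formation,
               loss_disturbance = loss_disturbance,
               gain_intact = gain_intact, gain_closure = gain_closure)
  })
  do.call(rbind, rows)
}

#' Simulate a full landscape bundle
#'
#' Terrain, forest types, epoch-1 CHM, evolved epoch-2 CHM with truth labels
#' and event registry, and the aligned [chm_pair()]. Deterministic per
#' `cfg$seed`.
#'
#' @param cfg a [landscape_config()].
#' @return list of class `landscape_sim`: `dtm`, `types`, `chm1`, `chm2`,
#'   `truth`, `events`, `pair`, `config`.
#' @export
simulate_landscape <- function(cfg = landscape_config()) {
  dtm <- gen_terrain(cfg)
  types <- assign_types(dtm, cfg)
  g1 <- gen_chm(dtm, types, cfg)
  ev <- evolve_chm(g1$chm, types, cfg, g1$gap_map)
  pair <- chm_pair(g1$chm, ev$chm2, cfg$date1, cfg$date2)
  structure(list(dtm = dtm, types = types, chm1 = g1$chm, chm2 = ev$chm2,
                 initial_gaps = g1$gaps, truth = ev$truth,
                 events = ev$events, pair = pair, config = cfg),
            class = "landscape_sim")
}

#' Per-cell dynamics rates from the simulator's truth labels
#'
#' Same aggregation as [summarize_cells()] but using the truth label map
#' instead of the classifier output: the registry-derived reference that
#' pipeline estimates are validated against.
#'
#' @param sim a `landscape_sim` from [simulate_landscape()].
#' @param cells cell table from [tile_cells()].
#' @param q a [quality_thresholds()].
#' @return data.frame as from [summarize_cells()].
#' @export
truth_dynamics <- function(sim, cells, q = quality_thresholds()) {
  p <- change_params(interval_years = sim$config$interval_years)
  fake <- structure(list(class_map = sim$truth,
                         delta = chm_delta(sim$pair),
                         params = p),
                    class = "change_map")
  summarize_cells(fake, cells, q, types = sim$types,
                  type_levels = forest_types)
}
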