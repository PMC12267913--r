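# End-to-end orchestration: build the per-cell analysis table by joining the
# terrain, structure and dynamics summaries, and run the whole chain
# (simulate -> terrain -> structure -> gaps -> change -> stats) from a config
# with a machine-readable manifest. The thin command-line wrapper in
# exec/canopyflux dispatches to these functions.

#' Assemble the per-cell analysis records
#'
#' Joins per-cell forest type, topography (elevation, slope, TWI), canopy
#' structure (from the epoch-1 CHM) and dynamics rates into the single table
#' behind all landscape statistics: one row per retained 1-ha cell with its
#' centroid map coordinates.
#'
#' @param pair a [chm_pair()].
#' @param dtm native-resolution DTM ([raster_grid()]).
#' @param types forest-type raster of codes (see [forest_types]).
#' @param cell_size analysis cell edge (m), default 100 (1 ha).
#' @param q a [quality_thresholds()].
#' @param p a [change_params()]; defaults to the standard definition with the
#'   pair's interval.
#' @param change optional precomputed `change_map` from [classify_change()].
#' @return data.frame of cell records.
#' @export
cell_records <- function(pair, dtm, types, cell_size = 100,
                         q = quality_thresholds(), p = NULL, change = NULL) {
  if (is.null(change)) change <- classify_change(pair, p)
  cells <- tile_cells(pair$chm1, cell_size)
  dyn <- summarize_cells(change, cells, q, types = types,
                         type_levels = forest_types)
  if (is.null(dyn) || !nrow(dyn)) stop("no valid cells")
  topo <- cell_topography(dtm, cells, cell_size)
  struct <- cell_structure_table(pair$chm1, cells, q = q)
  key <- function(d) paste(d$cell_row, d$cell_col)
  out <- dyn
  i <- match(key(out), key(topo))
  out$elevation <- topo$elevation[i]
  out$slope <- topo$slope[i]
  out$twi <- topo$twi[i]
  j <- match(key(out), key(struct))
  out$h_mean <- struct$h_mean[j]
  out$h_max <- struct$h_max[j]
  out$h_cv <- struct$h_cv[j]
  out$gf10 <- struct$gf10[j]
  out[!is.na(out$elevation) & !is.na(out$h_max), , drop = FALSE]
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order on a synthetic
#' landscape: `simulate` (terrain, types, CHM pair with truth),
#' `terrain`, `structure`, `gaps`, `change`, `stats`; writes rasters
#' (ESRI ASCII), CSV tables, a JSON stats summary and a JSON run manifest
#' under `out_dir`.
#'
#' @param config a [landscape_config()], or a path to a JSON file of
#'   [landscape_config()] arguments.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (dependencies are added
#'   automatically); default all.
#' @param seed optional integer overriding the config seed.
#' @return the manifest, invisibly (list: stages, outputs, parameters, seed,
#'   version, timestamps).
#' @export
run_pipeline <- function(config = landscape_config(), out_dir = "canopyflux_run",
                         stages = c("simulate", "terrain", "structure",
                                    "gaps", "change", "stats"),
                         seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    args <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(landscape_config, args)
  }
  if (!inherits(config, "landscape_config"))
    stop("config must be a landscape_config or a JSON path")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  known <- c("simulate", "terrain", "structure", "gaps", "change", "stats")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  deps <- list(terrain = "simulate", structure = "simulate",
               gaps = "simulate", change = "simulate",
               stats = c("terrain", "structure", "change"))
  for (s in intersect(stages, names(deps))) {
    miss <- setdiff(deps[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage(s): ", paste(miss, collapse = ", "))
  }
  stages <- known[known %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  t0 <- Sys.time()
  log_stage <- function(s) message(sprintf("[canopyflux] %s", s))
  put <- function(path) { outputs <<- c(outputs, path); path }

  log_stage("simulate")
  sim <- simulate_landscape(config)
  write_raster(sim$dtm, put(file.path(out_dir, "dtm.asc")))
  write_raster(sim$types, put(file.path(out_dir, "types.asc")))
  write_raster(sim$chm1, put(file.path(out_dir, "chm_t1.asc")))
  write_raster(sim$chm2, put(file.path(out_dir, "chm_t2.asc")))
  write_raster(sim$truth, put(file.path(out_dir, "truth.asc")))
  utils::write.csv(sim$events, put(file.path(out_dir, "events.csv")),
                   row.names = FALSE)
  cells <- tile_cells(sim$chm1, 100)

  if ("terrain" %in% stages) {
    log_stage("terrain")
    topo <- cell_topography(sim$dtm, cells)
    utils::write.csv(topo, put(file.path(out_dir, "topography.csv")),
                     row.names = FALSE)
  }
  if ("structure" %in% stages) {
    log_stage("structure")
    st <- cell_structure_table(sim$chm1, cells)
    utils::write.csv(st, put(file.path(out_dir, "structure.csv")),
                     row.names = FALSE)
  }
  if ("gaps" %in% stages) {
    log_stage("gaps")
    for (epoch in c(1, 2)) {
      gs <- detect_gaps(if (epoch == 1) sim$chm1 else sim$chm2,
                        gap_definition(height_cutoff = config$gap_cutoff))
      tab <- gap_statistics(gs, if (epoch == 1) sim$chm1 else sim$chm2)
      write_raster(gs$label_map,
                   put(file.path(out_dir, sprintf("gaps_t%d.asc", epoch))))
      utils::write.csv(tab,
                       put(file.path(out_dir, sprintf("gaps_t%d.csv", epoch))),
                       row.names = FALSE)
      write_gaps_geojson(tab,
                         put(file.path(out_dir,
                                       sprintf("gaps_t%d.geojson", epoch))))
    }
  }
  records <- NULL
  if ("change" %in% stages) {
    log_stage("change")
    change <- classify_change(sim$pair)
    write_raster(change$class_map, put(file.path(out_dir, "change_class.asc")))
    records <- cell_records(sim$pair, sim$dtm, sim$types, change = change)
    utils::write.csv(records, put(file.path(out_dir, "dynamics.csv")),
                     row.names = FALSE)
  }
  if ("stats" %in% stages) {
    log_stage("stats")
    stats_out <- list()
    counts <- table(records$forest_type)
    for (resp in c("gains_volume", "losses_volume", "net_volume")) {
      stats_out[[resp]] <- if (sum(counts >= 2) >= 2) {
        an <- anova_by_type(records, resp)
        list(anova = an$anova, group_means = as.list(an$group_means))
      } else {
        list(note = "fewer than 2 forest types with 2 cells: ANOVA skipped",
             group_means = as.list(tapply(records[[resp]],
                                          records$forest_type, mean)))
      }
    }
    for (resp in c("gains_volume", "losses_volume")) {
      if (nrow(records) < 6) {
        stats_out[[paste0(resp, "_models")]] <-
          list(note = "too few cells for regression models")
        next
      }
      full <- fit_multiple(records, resp,
                           c("elevation", "twi", "h_max", "h_cv"))
      topo_only <- fit_multiple(records, resp, c("elevation", "twi"))
      m <- list(r2_full = full$r2, r2_topography = topo_only$r2)
      if (nrow(records) >= 30) {
        rng <- residual_range(records, full)
        m$residual_range_m <- as.numeric(rng)
        m$spatial_r2_full <- spatial_loo_cv(
          records, resp, c("elevation", "twi", "h_max", "h_cv"), rng)$r2
        m$spatial_r2_topography <- spatial_loo_cv(
          records, resp, c("elevation", "twi"), rng)$r2
      } else {
        m$note <- "fewer than 30 cells: spatial cross-validation skipped"
      }
      stats_out[[paste0(resp, "_models")]] <- m
    }
    jsonlite::write_json(stats_out, put(file.path(out_dir, "stats.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest <- list(
    tool = "canopyflux",
    version = as.character(utils::packageVersion("canopyflux")),
    seed = config$seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("canopy", "dynamics"))],
    canopy = config$canopy, dynamics = config$dynamics,
    outputs = outputs,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
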