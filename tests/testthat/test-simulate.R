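test_that("the landscape bundle is deterministic per seed", {
  s1 <- simulate_landscape(small_config(4))
  s2 <- simulate_landscape(small_config(4))
  expect_identical(s1$dtm$values, s2$dtm$values)
  expect_identical(s1$chm1$values, s2$chm1$values)
  expect_identical(s1$chm2$values, s2$chm2$values)
  expect_identical(s1$truth$values, s2$truth$values)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_landscape(small_config(5))
  expect_false(identical(s1$chm2$values, s3$chm2$values))
})

test_that("terrain follows its closed form and stays within the relief bounds", {
  cfg <- landscape_config(extent = c(200, 200),
                          terrain = list(base = 50, relief = 200,
                                         wavelength = 400, noise_sd = 0,
                                         noise_range = 60))
  dtm <- gen_terrain(cfg)
  x <- (seq_len(200) - 0.5)
  y <- (200 - seq_len(200) + 0.5)
  expected <- 50 + 200 * (0.85 * matrix(0.5 - 0.5 * cos(2 * pi * x / 400),
                                        200, 200, byrow = TRUE) +
                            0.15 * matrix(y / 200, 200, 200))
  expect_equal(dtm$values, expected, tolerance = 1e-12)
  expect_gte(min(dtm$values), 50)
  expect_lte(max(dtm$values), 250)
})

test_that("forest types follow the elevation bands", {
  cfg <- landscape_config(type_thresholds = c(alluvial_max = 100,
                                              sandstone_max = 180))
  dtm <- rg(matrix(c(90, 150, 200, 100), 2, 2))
  ty <- assign_types(dtm, cfg)
  expect_equal(ty$values[1, 1], forest_types[["alluvial"]])
  expect_equal(ty$values[2, 1], forest_types[["sandstone"]])
  expect_equal(ty$values[1, 2], forest_types[["kerangas"]])
  expect_equal(ty$values[2, 2], forest_types[["sandstone"]])  # boundary: >= goes up
})

test_that("the epoch-1 canopy matches its configuration", {
  # zero variance, no gaps: constant height per type at the type mean
  cfg <- small_config(6)
  for (tn in names(cfg$canopy)) cfg$canopy[[tn]]$sd <- 0
  for (tn in names(cfg$dynamics)) cfg$dynamics[[tn]]$initial_gap_rate <- 0
  dtm <- gen_terrain(cfg); ty <- assign_types(dtm, cfg)
  g <- gen_chm(dtm, ty, cfg)
  for (tn in names(forest_types)) {
    sel <- ty$values == forest_types[[tn]]
    if (any(sel))
      expect_true(all(g$chm$values[sel] == cfg$canopy[[tn]]$mean))
  }
  expect_identical(nrow(g$gaps), 0L)

  # an injected gap is recovered by the detector with its exact area
  cfg2 <- small_config(7)
  dtm2 <- gen_terrain(cfg2); ty2 <- assign_types(dtm2, cfg2)
  g2 <- gen_chm(dtm2, ty2, cfg2)
  found <- detect_gaps(g2$chm)
  expect_identical(nrow(found$gaps), nrow(g2$gaps))
  expect_equal(sort(found$gaps$area), sort(g2$gaps$area))

  # taller types give taller cells: h_max ordered alluvial > sandstone > kerangas
  sim <- simulate_landscape(landscape_config(seed = 8))
  rec <- cell_records(sim$pair, sim$dtm, sim$types)
  hm <- tapply(rec$h_max, rec$forest_type, mean)
  expect_gt(hm[["alluvial"]], hm[["sandstone"]])
  expect_gt(hm[["sandstone"]], hm[["kerangas"]])
})

test_that("evolution honours its limiting cases", {
  cfg <- small_config(9, noise_sd = 0)
  for (tn in names(cfg$dynamics)) {
    cfg$dynamics[[tn]]$formation_rate <- 0
    cfg$dynamics[[tn]]$disturbance_rate <- 0
    cfg$dynamics[[tn]]$closure_fraction <- 0
    cfg$dynamics[[tn]]$growth <- 0
  }
  cfg$drift_sd <- 0
  dtm <- gen_terrain(cfg); ty <- assign_types(dtm, cfg)
  g <- gen_chm(dtm, ty, cfg)
  ev <- evolve_chm(g$chm, ty, cfg, g$gap_map)
  expect_identical(ev$chm2$values, g$chm$values)
  expect_true(all(ev$truth$values %in%
                    change_classes[c("intact_canopy", "gap_persistence")]))

  # closure fraction 1: every epoch-1 gap pixel closes, no gaps remain
  cfg2 <- small_config(10, noise_sd = 0)
  for (tn in names(cfg2$dynamics)) {
    cfg2$dynamics[[tn]]$formation_rate <- 0
    cfg2$dynamics[[tn]]$disturbance_rate <- 0
    cfg2$dynamics[[tn]]$closure_fraction <- 1
  }
  dtm2 <- gen_terrain(cfg2); ty2 <- assign_types(dtm2, cfg2)
  g2 <- gen_chm(dtm2, ty2, cfg2)
  ev2 <- evolve_chm(g2$chm, ty2, cfg2, g2$gap_map)
  expect_true(all(ev2$truth$values[g2$gap_map > 0] ==
                    change_classes[["gap_closure"]]))
  expect_identical(nrow(detect_gaps(ev2$chm2)$gaps), 0L)
})

test_that("formation events arrive at the configured Poisson rate", {
  # rate 2 ha^-1 on 25 ha -> counts ~ Poisson(50); check the mean over seeds
  base <- landscape_config(
    noise_sd = 0,
    terrain = list(base = 50, relief = 180, wavelength = 1000, noise_sd = 0,
                   noise_range = 60),
    canopy = list(alluvial = list(mean = 42, sd = 0, range = 25),
                  sandstone = list(mean = 35, sd = 0, range = 22),
                  kerangas = list(mean = 24, sd = 0, range = 18)))
  counts <- numeric(200)
  for (s in seq_along(counts)) {
    cfg <- base; cfg$seed <- 1000L + s
    for (tn in names(cfg$dynamics)) {
      cfg$dynamics[[tn]]$initial_gap_rate <- 0
      cfg$dynamics[[tn]]$disturbance_rate <- 0
      cfg$dynamics[[tn]]$formation_rate <- 2
    }
    sim <- simulate_landscape(cfg)
    counts[s] <- sum(sim$events$kind == "formation")
  }
  se <- sqrt(50 / length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se)
  # registry areas equal labelled pixel counts
  sim <- simulate_landscape(small_config(11))
  for (k in c("formation", "persistence", "closure")) {
    code <- switch(k, formation = "gap_formation", closure = "gap_closure",
                   persistence = "gap_persistence")
    expect_equal(sum(sim$events$n_pixels[sim$events$kind == k]),
                 sum(sim$truth$values == change_classes[[code]]))
  }
})

test_that("quality rasters default to passing and can inject failures", {
  tmpl <- rg(matrix(30, 200, 200))
  qr <- gen_quality_rasters(tmpl)
  masked <- apply_quality_mask(tmpl, qr$density, qr$scan_angle)
  expect_identical(masked$values, tmpl$values)

  patch <- list(row0 = 1L, col0 = 1L, nrow = 30L, ncol = 30L, density = 1)
  qr2 <- gen_quality_rasters(tmpl, list(patch))
  masked2 <- apply_quality_mask(tmpl, qr2$density, qr2$scan_angle)
  expect_identical(which(is.na(masked2$values)),
                   which(qr2$density$values < 2))
  # a 30x30 failing patch pushes its 1-ha cell past the 5% missing rule
  cells <- tile_cells(tmpl, 100)
  w <- cell_window(masked2, cells[1, ])
  expect_false(cell_validity(w)$valid)
})

test_that("pipeline rates match registry-derived truth rates", {
  sim <- simulate_landscape(small_config(12, extent = c(300, 300)))
  cells <- tile_cells(sim$chm1, 100)
  est <- summarize_cells(classify_change(sim$pair), cells,
                         types = sim$types, type_levels = forest_types)
  tru <- truth_dynamics(sim, cells)
  expect_identical(nrow(est), nrow(tru))
  for (col in c("gains_volume", "losses_volume", "net_volume"))
    expect_equal(est[[col]], tru[[col]], tolerance = 0.01)
})
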