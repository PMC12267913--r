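test_that("block aggregation averages and propagates missing data", {
  g <- rg(matrix(100, 40, 40))
  a <- aggregate_raster(g, 10)
  expect_identical(dim(a$values), c(4L, 4L))
  expect_true(all(a$values == 100))
  expect_equal(a$pixel_size, 10)

  b <- rg(matrix(c(1, 3, 2, 4), 2, 2))  # block {1,2,3,4}
  expect_equal(aggregate_raster(b, 2)$values[1, 1], 2.5)

  v <- matrix(1, 4, 4); v[1, 1] <- NA
  agg <- aggregate_raster(rg(v), 2)
  expect_true(is.na(agg$values[1, 1]))
  expect_false(anyNA(agg$values[-1]))

  expect_warning(aggregate_raster(rg(matrix(0, 25, 25)), 10), "dropped")
})

test_that("area-weighted resampling handles non-integer factors exactly", {
  # constant field stays constant through a 10 m -> 25 m resample
  g <- raster_grid(matrix(7, 50, 50), pixel_size = 10)
  r <- resample_mean(g, 25)
  expect_identical(dim(r$values), c(20L, 20L))
  expect_true(all(abs(r$values - 7) < 1e-12))
  # ramp of pixel values: area-weighted means match a fine-grid oracle that
  # upsamples the 10-m step function to 1 m and block-averages at 25 m
  x <- (seq_len(50) - 0.5) * 10
  gx <- raster_grid(matrix(x, 50, 50, byrow = TRUE), pixel_size = 10)
  rx <- resample_mean(gx, 25)
  fine <- rep(x, each = 10)
  oracle <- vapply(seq_len(20),
                   function(i) mean(fine[(i - 1) * 25 + 1:25]), numeric(1))
  expect_equal(rx$values[1, ], oracle, tolerance = 1e-9)
})

test_that("Horn slope matches closed forms on planes", {
  flat <- raster_grid(matrix(5, 8, 8), pixel_size = 10)
  s <- terrain_slope(flat)
  expect_true(all(s$values[2:7, 2:7] == 0))
  expect_true(all(is.na(s$values[1, ])))

  x <- (seq_len(8) - 0.5) * 10
  p45 <- raster_grid(matrix(x, 8, 8, byrow = TRUE), pixel_size = 10)
  s45 <- terrain_slope(p45)
  expect_equal(max(abs(s45$values[2:7, 2:7] - 45)), 0, tolerance = 1e-9)

  p01 <- raster_grid(matrix(0.1 * x, 8, 8, byrow = TRUE), pixel_size = 10)
  s01 <- terrain_slope(p01)
  expect_equal(unique(as.vector(round(s01$values[2:7, 2:7], 6))),
               round(atan(0.1) * 180 / pi, 6))
  expect_error(terrain_slope(raster_grid(matrix(0, 2, 2))), "3x3")
})

test_that("pit filling matches a brute-force oracle and is idempotent", {
  # monotone plane: pit-free, unchanged
  x <- (seq_len(6) - 0.5) * 10
  plane <- raster_grid(matrix(x, 6, 6, byrow = TRUE), pixel_size = 10)
  expect_equal(fill_pits(plane)$values, plane$values, tolerance = 1e-12)

  # single 1-cell depression of depth 2 raised to its spill elevation
  z <- matrix(10, 5, 5); z[3, 3] <- 8
  f <- fill_pits(rg(z))
  expect_equal(f$values, fill_oracle(z), tolerance = 1e-9)
  expect_gte(f$values[3, 3], 10 - 1e-9)

  # bowl: interior filled to the rim (+- the tiny drainage gradient)
  set.seed(42)
  bowl <- matrix(20, 7, 7)
  bowl[2:6, 2:6] <- 12
  bowl[4, 4] <- 10
  fb <- fill_pits(rg(bowl))
  expect_equal(fb$values, fill_oracle(bowl), tolerance = 1e-9)

  # properties on random terrain: never lowers; idempotent; shift-equivariant
  for (s in 1:5) {
    set.seed(s)
    z <- matrix(runif(100, 0, 50), 10, 10)
    f1 <- fill_pits(rg(z))
    expect_true(all(f1$values >= z - 1e-12))
    expect_equal(fill_pits(f1)$values, f1$values, tolerance = 1e-9)
    expect_equal(fill_pits(rg(z + 100))$values, f1$values + 100,
                 tolerance = 1e-9)
  }
})

test_that("D8 accumulation follows hand-traceable chains and conserves area", {
  # single descending row: cell k from the top end accumulates k+1 cells
  z <- matrix(seq(10, 1, length.out = 10), nrow = 1)
  acc <- flow_accumulation(rg(z))
  expect_equal(as.vector(acc$values), 1:10)

  # pure x-gradient: accumulation increases along columns, constant in rows
  x <- (seq_len(10) - 0.5)
  tilt <- rg(matrix(rev(x), 10, 10, byrow = TRUE))
  acc <- flow_accumulation(tilt)
  expect_true(all(apply(acc$values, 2, function(col) length(unique(col)) == 1)))
  expect_equal(acc$values[1, ], seq_len(10))

  # local maximum drains nothing in: accumulation = own area
  z <- matrix(1, 5, 5); z[3, 3] <- 10
  acc <- flow_accumulation(rg(z))
  expect_equal(acc$values[3, 3], 1)

  # conservation: the accumulation reaching outlet cells sums to the count
  for (s in 1:5) {
    set.seed(s)
    f <- fill_pits(rg(matrix(runif(225, 0, 30), 15, 15)))
    acc <- flow_accumulation(f)
    # outlets: cells with no strictly lower 8-neighbour (checked by loops)
    z <- f$values
    is_outlet <- matrix(TRUE, 15, 15)
    for (r in 1:15) for (c in 1:15) {
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= 15 && c2 >= 1 && c2 <= 15 &&
            z[r2, c2] < z[r, c]) is_outlet[r, c] <- FALSE
      }
    }
    expect_equal(sum(acc$values[is_outlet]), 225)
  }
})

test_that("TWI is translation-invariant, slope-monotone, and wetter in valleys", {
  set.seed(7)
  z <- matrix(runif(900, 0, 40), 30, 30)
  base <- raster_grid(z, pixel_size = 10)
  t1 <- twi(base, 25)
  t2 <- twi(raster_grid(z + 500, pixel_size = 10), 25)
  expect_equal(t1$values, t2$values, tolerance = 1e-9)

  # steeper of two planes -> lower TWI everywhere (interior)
  x <- (seq_len(40) - 0.5) * 10
  gentle <- twi(raster_grid(matrix(0.05 * x, 40, 40, byrow = TRUE),
                            pixel_size = 10), 20)
  steep <- twi(raster_grid(matrix(0.5 * x, 40, 40, byrow = TRUE),
                           pixel_size = 10), 20)
  interior <- 2:(nrow(gentle$values) - 1)
  expect_true(all(steep$values[interior, interior] <
                    gentle$values[interior, interior]))

  # V-valley: valley-axis cells wetter than ridge-edge cells
  col_x <- abs(seq_len(20) - 10.5)  # distance from the valley axis
  y <- seq_len(20)
  vz <- outer(y * 0.2, col_x * 5, "+")  # tilted V
  vt <- twi(raster_grid(vz, pixel_size = 25), 25)
  valley <- mean(vt$values[2:19, 10:11])
  ridge <- mean(vt$values[2:19, c(2, 19)])
  expect_gt(valley, ridge)
})

test_that("cell topography takes per-cell means of the right layers", {
  # constant layers -> constant summaries
  g <- rg(matrix(120, 200, 200))
  cells <- tile_cells(g, 100)
  topo <- cell_topography(g, cells)
  expect_true(all(topo$elevation == 120))
  expect_true(all(abs(topo$slope) < 1e-9, na.rm = TRUE))

  # elevation plane: cell mean equals the plane at the cell centroid
  x <- (seq_len(200) - 0.5)
  gx <- rg(matrix(0.5 * x, 200, 200, byrow = TRUE))
  cells2 <- tile_cells(gx, 100)
  topo <- cell_topography(gx, cells2)
  expect_equal(topo$elevation, 0.5 * cells2$x, tolerance = 1e-9)

  # half-and-half cell averages to the midpoint
  v <- matrix(100, 100, 100); v[, 51:100] <- 200
  th <- cell_topography(rg(v), tile_cells(rg(v), 100))
  expect_equal(th$elevation, 150)
})
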