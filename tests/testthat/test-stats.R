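make_records <- function(n, seed = 1, types = c("alluvial", "sandstone", "kerangas")) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 4000), y = runif(n, 0, 4000),
             forest_type = sample(types, n, replace = TRUE))
}

test_that("ANOVA separates well-separated groups and not identical ones", {
  rec <- make_records(90)
  mu <- c(alluvial = 10, sandstone = 20, kerangas = 30)
  rec$resp <- rnorm(90, mu[rec$forest_type], 1)
  out <- anova_by_type(rec, "resp")
  expect_lt(out$anova$p, 1e-10)
  expect_true(all(out$pairwise$p_adj < 0.001))

  # two groups with identical values -> F = 0
  rec3 <- data.frame(forest_type = rep(c("a", "b"), each = 20),
                     resp = rep(rnorm(20, 5), 2))
  expect_lt(anova_by_type(rec3, "resp")$anova$F, 1e-20)
  expect_error(anova_by_type(data.frame(forest_type = "a", resp = 1), "resp"),
               ">= 2")
})

test_that("loss responses are |y| then log(y + 1), with a clean inverse", {
  y <- c(0, -10, 250)
  z <- loss_transform(y)
  expect_equal(as.numeric(z), log(c(1, 11, 251)))
  expect_equal(loss_backtransform(z), c(0, 10, 250))
  expect_true(all(loss_backtransform(rnorm(100, 0, 5)) >= 0))
})

test_that("univariate interaction fits recover known slopes", {
  # near-deterministic single type: slope 2, r -> 1
  rec <- make_records(100, types = "alluvial")
  rec$p <- rnorm(100)
  rec$resp <- 2 * rec$p + rnorm(100, 0, 1e-8)
  fit <- fit_univariate(rec, "resp", "p")
  expect_equal(unname(fit$type_slopes["alluvial"]), 2, tolerance = 1e-6)
  expect_equal(fit$pooled$r, 1, tolerance = 1e-6)

  # type-specific slopes {1, 2, 3} at sigma = 0.1, n = 200/type
  set.seed(8)
  slopes <- c(alluvial = 1, sandstone = 2, kerangas = 3)
  rec <- data.frame(forest_type = rep(names(slopes), each = 200),
                    x = runif(600, 0, 4000), y = runif(600, 0, 4000))
  rec$p <- rnorm(600)
  rec$resp <- slopes[rec$forest_type] * rec$p + rnorm(600, 0, 0.1)
  fit <- fit_univariate(rec, "resp", "p")
  for (tn in names(slopes)) {
    sub <- rec[rec$forest_type == tn, ]
    se <- summary(lm(resp ~ p, data = sub))$coefficients["p", "Std. Error"]
    expect_lt(abs(fit$type_slopes[tn] - slopes[tn]), 3 * se)
  }

  # no relationship: |pooled r| small
  set.seed(9)
  rec0 <- make_records(500)
  rec0$p <- rnorm(500); rec0$resp <- rnorm(500)
  expect_lt(abs(fit_univariate(rec0, "resp", "p")$pooled$r), 0.1)

  # a type with < 3 records is dropped from the interaction fit
  rec1 <- make_records(61, types = "alluvial")
  rec1$forest_type[1] <- "kerangas"
  rec1$p <- rnorm(61); rec1$resp <- rec1$p + rnorm(61, 0, 0.01)
  fit1 <- fit_univariate(rec1, "resp", "p")
  expect_identical(fit1$dropped_types, "kerangas")
  expect_false("kerangas" %in% names(fit1$type_slopes))
})

test_that("multiple regression recovers orthogonal effects and nests R^2", {
  set.seed(10)
  n <- 200
  rec <- make_records(n)
  rec$elevation <- rnorm(n); rec$twi <- rnorm(n)
  rec$h_max <- rnorm(n); rec$h_cv <- rnorm(n)
  rec$resp <- 3 * rec$elevation - 2 * rec$twi + rnorm(n, 0, 1e-9)
  fit <- fit_multiple(rec, "resp", c("elevation", "twi"))
  cf <- coef(fit$model)
  # standardized coefficients scale by each predictor's sd
  expect_equal(unname(cf["elevation"]), 3 * sd(rec$elevation), tolerance = 1e-6)
  expect_equal(unname(cf["twi"]), -2 * sd(rec$twi), tolerance = 1e-6)

  rec$resp <- 3 * rec$elevation - 2 * rec$twi + rec$h_max + rnorm(n)
  full <- fit_multiple(rec, "resp", c("elevation", "twi", "h_max", "h_cv"))
  reduced <- fit_multiple(rec, "resp", c("elevation", "twi"))
  expect_gte(full$r2, reduced$r2)

  # row-order invariance
  perm <- sample(n)
  full_p <- fit_multiple(rec[perm, ], "resp",
                         c("elevation", "twi", "h_max", "h_cv"))
  expect_equal(full_p$r2, full$r2, tolerance = 1e-12)

  rec$dup <- rec$elevation
  expect_warning(fit_multiple(rec, "resp", c("elevation", "dup")),
                 "rank-deficient")
})

test_that("the residual range is recovered from spherical fields and is 0 for noise", {
  # white-noise residuals: no structure, range reported as 0
  set.seed(13)
  rec <- make_records(200)
  rec$p <- rnorm(200)
  rec$resp <- rnorm(200)
  fit <- fit_multiple(rec, "resp", "p")
  expect_lte(as.numeric(residual_range(rec, fit, bin_width = 100)), 100)

  # constant residuals: zero sill, range 0
  fit0 <- list(residuals = rep(0, 200))
  expect_equal(as.numeric(residual_range(rec, fit0)), 0)

  # spherical field with range 300 m: mean recovery within 30%
  grid <- expand.grid(x = seq(50, 2950, 100), y = seq(50, 2950, 100))
  est <- numeric(5)
  set.seed(14)
  for (s in 1:5) {
    rec <- data.frame(grid, forest_type = "alluvial", p = rnorm(nrow(grid)))
    rec$resp <- spherical_field(grid, 300)
    fit <- fit_multiple(rec, "resp", "p")
    est[s] <- as.numeric(residual_range(rec, fit, bin_width = 100))
  }
  expect_lt(abs(mean(est) - 300) / 300, 0.3)
})

test_that("buffered LOO reduces to ordinary LOO at range 0 and finds true skill", {
  set.seed(15)
  n <- 200
  rec <- make_records(n)
  rec$p <- rnorm(n)
  rec$resp <- 2 * rec$p + rnorm(n, 0, 1e-9)
  cv <- spatial_loo_cv(rec, "resp", "p", range = 0)
  expect_equal(cv$r2, 1, tolerance = 1e-6)
  expect_identical(cv$n_skipped, 0L)

  # true linear signal + white noise: R^2 near the signal-variance fraction
  r2s <- sapply(1:10, function(s) {
    set.seed(100 + s)
    rec <- make_records(200, seed = 100 + s)
    rec$p <- rnorm(200)
    rec$resp <- 2 * rec$p + rnorm(200, 0, 1)
    spatial_loo_cv(rec, "resp", "p", range = 0)$r2
  })
  expect_lt(abs(mean(r2s) - 4 / 5), 0.05)

  # an over-wide buffer leaves too few training cells and counts skips
  rec$resp <- rec$p
  cv_big <- spatial_loo_cv(rec, "resp", "p", range = 1e6)
  expect_identical(cv_big$n_skipped, nrow(rec))
})
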