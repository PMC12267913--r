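# Statistical layer over the per-cell records: ANOVA among forest types,
# univariate regressions with a forest-type interaction, multiple regressions
# on standardized predictors, and spatially buffered leave-one-out
# cross-validation with the buffer radius taken from a fitted residual
# semivariogram.

.is_loss_response <- function(response) grepl("loss", response)

#' Log transform for canopy loss rates
#'
#' Losses are analysed as absolute values and are strongly right-skewed, so
#' they are log-transformed before model fitting: `log(|y| + offset)`. The
#' offset (default 1 m^3 ha^-1 yr^-1, the smallest unit-scale constant)
#' keeps zero-loss cells finite and is recorded on the result.
#'
#' @param y numeric vector of loss rates.
#' @param offset additive constant before the log.
#' @return transformed vector with attribute `offset`.
#' @export
loss_transform <- function(y, offset = 1) {
  structure(log(abs(y) + offset), offset = offset)
}

#' Invert [loss_transform()]
#' @param z transformed values.
#' @param offset the offset used in the forward transform.
#' @return non-negative loss rates.
#' @export
loss_backtransform <- function(z, offset = 1)
  pmax(exp(as.numeric(z)) - offset, 0)

.response_vector <- function(records, response, log_losses = NULL) {
  y <- records[[response]]
  if (is.null(y)) stop("response not found: ", response)
  if (is.null(log_losses)) log_losses <- .is_loss_response(response)
  if (log_losses) y <- loss_transform(y)
  structure(y, log_transformed = log_losses)
}

#' One-way ANOVA of a dynamics rate among forest types
#'
#' Compares a per-cell response among forest types with a one-way ANOVA and
#' Tukey HSD pairwise comparisons (family-wise adjusted).
#'
#' @param records per-cell records with a `forest_type` column.
#' @param response name of the response column.
#' @param log_losses log-transform absolute losses first? Default: `TRUE`
#'   for responses whose name contains "loss".
#' @return list: `anova` (data.frame with `F`, `df_between`, `df_within`,
#'   `p`), `pairwise` (Tukey HSD table), `group_means`, `n`.
#' @export
anova_by_type <- function(records, response, log_losses = NULL) {
  y <- .response_vector(records, response, log_losses)
  g <- factor(records$forest_type)
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 forest types with >= 2 records each")
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  names(pairwise) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  list(anova = data.frame(F = s$`F value`[1],
                          df_between = s$Df[1], df_within = s$Df[2],
                          p = s$`Pr(>F)`[1]),
       pairwise = pairwise,
       group_means = tapply(y, g, mean),
       n = length(y))
}

#' Univariate regression with a forest-type interaction
#'
#' Fits `response ~ predictor * forest_type` (type-specific intercepts and
#' slopes) together with the pooled fit across all cells and the pooled
#' Pearson correlation. Types with fewer than 3 records are excluded from
#' the interaction fit (their slopes are absent).
#'
#' @inheritParams anova_by_type
#' @param predictor name of the predictor column.
#' @return list: `coefficients` (interaction-model summary table),
#'   `type_slopes` (named per-type slopes), `pooled` (intercept, slope,
#'   Pearson `r`, `r2`), `r2`, `n`, `log_transformed`, `dropped_types`.
#' @export
fit_univariate <- function(records, response, predictor, log_losses = NULL) {
  y <- .response_vector(records, response, log_losses)
  x <- records[[predictor]]
  if (is.null(x)) stop("predictor not found: ", predictor)
  g <- factor(records$forest_type)
  counts <- table(g)
  small <- names(counts)[counts < 3L]
  keep <- !(as.character(g) %in% small)
  d <- data.frame(y = y[keep], x = x[keep], g = droplevels(g[keep]))
  lev <- levels(d$g)
  fit <- if (length(lev) >= 2L) stats::lm(y ~ x * g, data = d)
         else stats::lm(y ~ x, data = d)
  cf <- stats::coef(fit)
  slopes <- stats::setNames(rep(cf[["x"]], length(lev)), lev)
  for (l in lev[-1]) {
    term <- paste0("x:g", l)
    if (term %in% names(cf)) slopes[l] <- slopes[l] + cf[[term]]
  }
  pooled <- stats::lm(y ~ x)
  list(coefficients = summary(fit)$coefficients,
       type_slopes = slopes,
       pooled = list(intercept = stats::coef(pooled)[[1]],
                     slope = stats::coef(pooled)[[2]],
                     r = stats::cor(x, y),
                     r2 = summary(pooled)$r.squared),
       r2 = summary(fit)$r.squared,
       n = nrow(d),
       log_transformed = isTRUE(attr(y, "log_transformed")),
       dropped_types = small)
}

#' Multiple regression on standardized predictors
#'
#' Ordinary least squares of a dynamics rate on a subset of the cell-level
#' covariates (typically elevation, TWI, h_max, h_cv), each standardized to
#' zero mean and unit variance. Reports the naive in-sample R^2; effect
#' sizes of correlated predictors are deliberately not ranked.
#'
#' @inheritParams anova_by_type
#' @param predictors character vector of predictor column names.
#' @return list of class `canopyflux_fit`: `model` (the `lm`),
#'   `coefficients`, `r2`, `n`, `residuals`, `rank_deficient`, `predictors`,
#'   `response`, `log_transformed`, `offset`.
#' @export
fit_multiple <- function(records, response, predictors, log_losses = NULL) {
  stopifnot(length(predictors) >= 1L)
  y <- .response_vector(records, response, log_losses)
  X <- records[, predictors, drop = FALSE]
  if (nrow(X) < length(predictors) + 2L) stop("too few records")
  Xs <- as.data.frame(scale(X))
  d <- cbind(y = as.numeric(y), Xs)
  fit <- stats::lm(y ~ ., data = d)
  cf <- stats::coef(fit)
  rank_def <- any(is.na(cf))
  if (rank_def) warning("rank-deficient design: ",
                        paste(names(cf)[is.na(cf)], collapse = ", "))
  structure(list(model = fit,
                 coefficients = summary(fit)$coefficients,
                 r2 = summary(fit)$r.squared,
                 n = nrow(d),
                 residuals = stats::residuals(fit),
                 rank_deficient = rank_def,
                 predictors = predictors, response = response,
                 log_transformed = isTRUE(attr(y, "log_transformed")),
                 offset = 1),
            class = "canopyflux_fit")
}

# Matheron classical semivariogram of a residual vector at coordinates
# (x, y): gamma(h) = mean(diff^2)/2 within distance bins.
.semivariogram <- function(res, x, y, bin_width, max_lag) {
  n <- length(res)
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  dd <- sqrt(dx^2 + dy^2)
  up <- upper.tri(dd)
  h <- dd[up]
  g2 <- (outer(res, res, "-")[up])^2
  keep <- h > 0 & h <= max_lag
  h <- h[keep]; g2 <- g2[keep]
  bin <- floor(h / bin_width)
  data.frame(lag = (as.numeric(names(tapply(g2, bin, mean))) + 0.5) * bin_width,
             gamma = as.vector(tapply(g2, bin, mean)) / 2,
             n_pairs = as.vector(tapply(g2, bin, length)))
}

.spherical <- function(h, c0, c1, a) {
  ifelse(h >= a, c0 + c1,
         c0 + c1 * (1.5 * h / pmax(a, 1e-12) - 0.5 * (h / pmax(a, 1e-12))^3))
}

#' Residual spatial autocorrelation range
#'
#' Empirical (Matheron) semivariogram of a model's residuals, binned at the
#' analysis cell size up to half the landscape diameter, with a spherical
#' model fitted by unweighted least squares. Returns the fitted range, the
#' buffer radius for [spatial_loo_cv()]. When the fitted partial sill is
#' negligible (< 5% of the total sill) the residuals carry no usable spatial
#' structure and the range is reported as 0.
#'
#' @param records per-cell records with centroid columns `x`, `y`.
#' @param model a `canopyflux_fit` from [fit_multiple()] (or any object with
#'   a `residuals` field aligned with `records`).
#' @param bin_width semivariogram bin width (m); defaults to 100 (the 1-ha
#'   cell size).
#' @return range in metres, with attributes `sill`, `nugget` and
#'   `empirical` (the binned semivariogram).
#' @export
residual_range <- function(records, model, bin_width = 100) {
  res <- model$residuals
  if (length(res) < 30L) stop("need at least 30 records for the variogram")
  if (stats::var(res) < 1e-12) return(structure(0, sill = 0, nugget = 0))
  x <- records$x; y <- records$y
  diam <- sqrt(diff(range(x))^2 + diff(range(y))^2)
  max_lag <- diam / 2
  emp <- .semivariogram(res, x, y, bin_width, max_lag)
  obj <- function(p) {
    g <- .spherical(emp$lag, p[1], p[2], p[3])
    sum((g - emp$gamma)^2)
  }
  v <- stats::var(res)
  best <- NULL
  for (a0 in c(bin_width, max_lag / 4, max_lag / 2, max_lag)) {
    o <- stats::optim(c(v / 2, v / 2, a0), obj, method = "L-BFGS-B",
                      lower = c(0, 0, 1e-6),
                      upper = c(2 * v, 2 * v, 2 * max_lag))
    if (is.null(best) || o$value < best$value) best <- o
  }
  c0 <- best$par[1]; c1 <- best$par[2]; a <- best$par[3]
  rng <- if (c1 < 0.05 * (c0 + c1)) 0 else min(a, max_lag)
  structure(rng, sill = c0 + c1, nugget = c0, empirical = emp)
}

#' Spatially buffered leave-one-out cross-validation
#'
#' For each cell, refits the regression on all cells whose centroid lies
#' strictly beyond `range` metres from the held-out cell (Euclidean
#' exclusion disk), predicts the held-out value, and summarises predictive
#' skill as spatial R^2 = 1 - SSE/SST over the held-out predictions. With
#' `range = 0` this reduces to ordinary leave-one-out. Cells whose buffer
#' leaves fewer than p + 2 training cells are skipped and counted.
#'
#' @inheritParams fit_multiple
#' @param range buffer radius in metres (e.g. from [residual_range()]).
#' @return list of class `spatial_cv`: `range`, `r2`, `n`, `n_skipped`,
#'   `observed`, `predicted` (on the modelling scale), `predicted_back`
#'   (back-transformed, non-negative, for log-loss responses),
#'   `log_transformed`.
#' @export
spatial_loo_cv <- function(records, response, predictors, range = 0,
                           log_losses = NULL) {
  stopifnot(range >= 0)
  y <- .response_vector(records, response, log_losses)
  logt <- isTRUE(attr(y, "log_transformed"))
  y <- as.numeric(y)
  X <- as.matrix(records[, predictors, drop = FALSE])
  n <- length(y); p <- ncol(X)
  cx <- records$x; cy <- records$y
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d2 <- (cx - cx[i])^2 + (cy - cy[i])^2
    train <- which(d2 > range^2)
    if (length(train) < p + 2L) next
    fit <- stats::lm.fit(cbind(1, X[train, , drop = FALSE]), y[train])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred[i] <- sum(c(1, X[i, ]) * beta)
  }
  ok <- !is.na(pred)
  sse <- sum((y[ok] - pred[ok])^2)
  sst <- sum((y[ok] - mean(y[ok]))^2)
  structure(list(range = range,
                 r2 = 1 - sse / sst,
                 n = sum(ok), n_skipped = sum(!ok),
                 observed = y, predicted = pred,
                 predicted_back = if (logt) loss_backtransform(pred) else pred,
                 log_transformed = logt),
            class = "spatial_cv")
}
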