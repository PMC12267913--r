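# Independent oracles and fixture builders used across the suite.

# Brute-force connected-component labelling by iterated min-label
# propagation: every foreground pixel starts with its own (row-major) label
# and repeatedly takes the minimum of its neighbourhood until a fixpoint.
# Components are then renumbered 1..K by their smallest row-major index,
# matching the raster-scan numbering contract.
label_oracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  scan_id <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)  # row-major ids
  lab <- ifelse(mask, scan_id, Inf)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  shift_inf <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift_inf(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[is.finite(lab)]))
  out <- matrix(0L, nr, nc)
  out[is.finite(lab)] <- match(lab[is.finite(lab)], ids)
  out
}

# Brute-force depression filling: repeatedly raise every cell that has no
# neighbour (8-conn) at least `eps` lower and is not on the edge, up to the
# lowest value that gives it one. O(n^2) sweeps; fine for tiny grids.
fill_oracle <- function(z, eps = 1e-4) {
  nr <- nrow(z); nc <- ncol(z)
  w <- matrix(Inf, nr, nc)
  w[1, ] <- z[1, ]; w[nr, ] <- z[nr, ]; w[, 1] <- z[, 1]; w[, nc] <- z[, nc]
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      nb <- Inf
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
          nb <- min(nb, w[r2, c2] + eps)
      }
      cand <- max(z[r, c], min(w[r, c], nb))
      if (cand != w[r, c]) { w[r, c] <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  w
}

# A raster_grid from a matrix with 1-m pixels at the origin.
rg <- function(values, pixel_size = 1) raster_grid(values, pixel_size = pixel_size)

# CHM pair with the standard survey dates (5.34-yr interval).
pair_of <- function(v1, v2, pixel_size = 1) {
  chm_pair(rg(v1, pixel_size), rg(v2, pixel_size), "2014-10-15", "2020-02-15")
}

# Draw a spatially correlated field with an exact spherical covariance via
# Cholesky factorisation (independent of the package's spectral generator).
spherical_field <- function(coords, range, sill = 1, nugget = 1e-6) {
  d <- as.matrix(stats::dist(coords))
  cv <- ifelse(d >= range, 0,
               sill * (1 - 1.5 * d / range + 0.5 * (d / range)^3))
  L <- chol(cv + diag(nugget, nrow(d)))
  as.vector(t(L) %*% stats::rnorm(nrow(d)))
}

# Small fast landscape configuration for simulation-heavy tests.
small_config <- function(seed, extent = c(200, 200), ...) {
  landscape_config(seed = seed, extent = extent,
                   terrain = list(base = 50, relief = 180, wavelength = 400,
                                  noise_sd = 2, noise_range = 40), ...)
}
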