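# Independent oracles and fixtures shared across test files.

# Brute-force greedy max-min selection: recomputes every Euclidean distance
# from scratch at each step. Deliberately independent of kennard_stone()'s
# cached-distance implementation.
ks_oracle <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- d(i, j)
      if (dij > bestd) { best <- c(i, j); bestd <- dij }
    }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    mind <- vapply(cand, function(i) min(vapply(sel, function(j) d(i, j), 0)), 0)
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# Ordinary least squares fitted values via the normal equations
# (pseudoinverse on the centered problem) -- the full-rank PLSR oracle.
ols_fitted <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  b <- qr.solve(Xc, yc)
  mean(y) + drop(Xc %*% b)
}

# A published 13-row tablet screening report (metrics as printed), used as
# a ranking fixture for select_best().
screening_report_fixture <- function() {
  tibble::tibble(
    config_id = 1:13,
    n_factors = c(5L, 9L, 4L, 3L, 5L, 5L, 9L, 7L, 5L, 7L, 8L, 8L, 8L),
    r2_model = c(0.9142, 0.9545, 0.9083, 0.9355, 0.9605, 0.9264, 0.9394,
                 0.9716, 0.9823, 0.9840, 0.9741, 0.9481, 0.9716),
    r2_pearson = c(0.9328, 0.9309, 0.9287, 0.9438, 0.9591, 0.9312, 0.9410,
                   0.9417, 0.9579, 0.9562, 0.9639, 0.9508, 0.9632),
    rmsep = c(2.4797, 2.4850, 2.5648, 2.2418, 2.0673, 2.4780, 2.3093,
              2.2801, 2.0986, 2.0155, 1.7611, 2.1874, 1.7786),
    bias = c(0.1986, -0.0359, 0.1862, 0.2695, -0.1105, -0.0123, -0.2371,
             -0.3258, -0.1973, -0.4150, 0.0495, -0.1130, 0.0176)
  )
}

# Small deterministic spectra set for plumbing tests: quadratic-ish traces
# on a coarse grid with reference values.
tiny_set <- function(n = 5, p = 21, seed = 42) {
  withr::with_seed(seed, {
    wn <- seq(1000, 1000 + (p - 1) * 10, by = 10)
    y <- seq(2, 10, length.out = n)
    X <- outer(y, sin(wn / 200)) + matrix(rnorm(n * p, 0, 0.01), n, p)
    spectra_set(wn, X, tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      nominal_mg = y, reference_mg = y
    ))
  })
}

# Noise-free design shortcut
quiet_design <- function(form = "tablet", ...) {
  synthetic_design(form = form, noise_sd = 0, scatter_sd = 0,
                   baseline_offset_sd = 0, baseline_slope_sd = 0,
                   tablet_surface_sd = 0, reference_recovery = 1,
                   reference_rsd = 0, ...)
}
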