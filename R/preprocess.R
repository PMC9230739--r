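#' Standard normal variate (SNV)
#'
#' Centers and scales a single spectrum to zero mean and unit standard
#' deviation (sample, n-1 convention), the classical per-spectrum correction
#' for multiplicative scatter between replicate solid-sample measurements.
#'
#' @param x Numeric intensity vector, length >= 2, non-constant.
#' @return The transformed vector (mean 0, sd 1).
#' @examples
#' snv(c(1, 2, 3))
#' @export
snv <- function(x) {
  if (length(x) < 2) stop_chemocal("SNV needs at least 2 points", "parameter_error")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_chemocal("constant spectrum: SNV undefined (zero variance)",
                  "degenerate_error")
  }
  (x - mean(x)) / s
}

#' Area normalization
#'
#' Divides a spectrum by its total absolute intensity so that
#' `sum(abs(out)) == 1`. The absolute-value sum is a discrete total-area
#' proxy; on a uniform grid the constant spacing factor cancels after mean
#' centering in the regression, so no trapezoidal weighting is applied.
#'
#' @param x Numeric intensity vector with `sum(abs(x)) > 0`.
#' @return The normalized vector.
#' @examples
#' area_normalize(c(1, 1, 2))
#' @export
area_normalize <- function(x) {
  a <- sum(abs(x))
  if (!is.finite(a) || a == 0) {
    stop_chemocal("all-zero spectrum: area normalization undefined",
                  "degenerate_error")
  }
  x / a
}

# Savitzky-Golay weight matrix for one full window.
# Returns an (m x m) matrix E: row r gives the weights that evaluate the
# deriv-th derivative of the local least-squares polynomial at window
# position t0 = r - h - 1 (so row h+1 is the usual centered filter).
# Weights are per index step; division by spacing^deriv happens at the caller.
sg_weights <- function(window_points, polynomial_order, derivative_order) {
  m <- window_points
  h <- (m - 1) / 2
  t <- (-h):h
  V <- outer(t, 0:polynomial_order, `^`)
  # coefficient extractor: a = C %*% y  (least squares polynomial fit)
  C <- solve(crossprod(V), t(V))
  j <- 0:polynomial_order
  keep <- j >= derivative_order
  fac <- numeric(length(j))
  fac[keep] <- factorial(j[keep]) / factorial(j[keep] - derivative_order)
  E <- matrix(0, m, m)
  for (r in seq_len(m)) {
    t0 <- t[r]
    pow <- numeric(length(j))
    pow[keep] <- t0^(j[keep] - derivative_order)
    E[r, ] <- (fac * pow) %*% C
  }
  E
}

check_sg_params <- function(derivative_order, polynomial_order, window_points) {
  if (!(derivative_order %in% c(1L, 2L)) && derivative_order != 0) {
    stop_chemocal("derivative_order must be 0, 1 or 2", "parameter_error")
  }
  if (window_points %% 2 != 1 || window_points <= polynomial_order) {
    stop_chemocal("window_points must be odd and > polynomial_order",
                  "parameter_error")
  }
  if (derivative_order > polynomial_order) {
    stop_chemocal("derivative_order must be <= polynomial_order",
                  "parameter_error")
  }
  invisible(TRUE)
}

grid_spacing <- function(grid, rel_tol = 1e-6) {
  d <- diff(grid)
  if (length(d) == 0) stop_chemocal("grid too short", "parameter_error")
  if (max(d) - min(d) > rel_tol * max(abs(d))) {
    stop_chemocal("grid is not evenly spaced: derivative undefined", "grid_error")
  }
  mean(d)
}

# Row-wise SG derivative on a matrix; interior by shifted-column sums,
# edges by re-evaluating the first/last full-window polynomial off-center.
sg_derivative_matrix <- function(X, grid, derivative_order,
                                 polynomial_order = 2, window_points = 11) {
  check_sg_params(derivative_order, polynomial_order, window_points)
  n <- nrow(X); p <- ncol(X)
  m <- window_points
  if (p < m) {
    stop_chemocal("window larger than the spectrum", "parameter_error")
  }
  dx <- grid_spacing(grid)
  E <- sg_weights(m, polynomial_order, derivative_order) / dx^derivative_order
  h <- (m - 1) / 2
  w0 <- E[h + 1, ]

  out <- matrix(0, n, p)
  # interior: out[, c] = sum_k w0[k+h+1] * X[, c+k]
  centers <- (h + 1):(p - h)
  acc <- matrix(0, n, length(centers))
  for (k in (-h):h) {
    acc <- acc + w0[k + h + 1] * X[, centers + k, drop = FALSE]
  }
  out[, centers] <- acc
  # edges
  out[, 1:h] <- X[, 1:m, drop = FALSE] %*% t(E[1:h, , drop = FALSE])
  out[, (p - h + 1):p] <-
    X[, (p - m + 1):p, drop = FALSE] %*% t(E[(h + 2):m, , drop = FALSE])
  dimnames(out) <- dimnames(X)
  out
}

#' Savitzky-Golay derivative
#'
#' Smoothed spectral derivative: each output point is the
#' `derivative_order`-th derivative (per cm^-1, using the grid spacing) of
#' the local least-squares polynomial fitted over a centered window. Edge
#' points are produced by re-evaluating the first/last full-window
#' polynomial at the off-center positions, so the output keeps the input
#' length and interval bookkeeping never shifts.
#'
#' @param x Numeric intensity vector (length >= `window_points`).
#' @param grid Wavenumber grid (evenly spaced to 1e-6 relative).
#' @param derivative_order 1 or 2.
#' @param polynomial_order Local polynomial order (>= derivative_order).
#' @param window_points Odd window width in points (> polynomial_order).
#' @return The derivative vector, same length as `x`, units a.u. per cm^-1
#'   (or per cm^-2 for the second derivative).
#' @export
sg_derivative <- function(x, grid, derivative_order,
                          polynomial_order = 2, window_points = 11) {
  drop(sg_derivative_matrix(matrix(x, nrow = 1), grid, derivative_order,
                            polynomial_order, window_points))
}

#' Build or parse a pretreatment recipe
#'
#' A `preprocess_spec` is an ordered list of pretreatment steps applied
#' left-to-right (so `"area_norm+snv"` area-normalizes first, then applies
#' SNV). Recognized tokens: `original` (or the empty string) for no-op,
#' `area_norm`, `snv`, and `d1(...)`/`d2(...)` for first/second
#' Savitzky-Golay derivatives with `poly=` and `window=` arguments
#' (defaults poly 2, window 11).
#'
#' @param x A specification string, e.g. `"snv+d1(poly=2,window=11)"`, or a
#'   list of step descriptors, or an existing `preprocess_spec`.
#' @return A `preprocess_spec` object.
#' @examples
#' preprocess_spec("area_norm+snv")
#' preprocess_spec("snv+d1(poly=2,window=21)")
#' @export
preprocess_spec <- function(x = "original") {
  if (inherits(x, "preprocess_spec")) return(x)
  if (is.list(x)) {
    steps <- x
  } else if (is.character(x) && length(x) == 1) {
    x <- trimws(x)
    if (x == "" || tolower(x) %in% c("original", "none")) {
      steps <- list()
    } else {
      steps <- lapply(trimws(strsplit(x, "+", fixed = TRUE)[[1]]), parse_step)
    }
  } else {
    stop_chemocal("cannot interpret preprocess specification", "format_error")
  }
  for (s in steps) {
    if (!s$kind %in% c("snv", "area_norm", "sg_derivative")) {
      stop_chemocal(sprintf("unknown step kind '%s'", s$kind), "format_error")
    }
    if (s$kind == "sg_derivative") {
      check_sg_params(s$derivative_order, s$polynomial_order, s$window_points)
    }
  }
  structure(list(steps = steps), class = "preprocess_spec")
}

parse_step <- function(token) {
  token <- tolower(token)
  if (token %in% c("snv", "area_norm")) return(list(kind = token))
  m <- regmatches(token, regexec("^d([12])(\\((.*)\\))?$", token))[[1]]
  if (length(m)) {
    d <- as.integer(m[2])
    poly <- 2L; window <- 11L
    if (nzchar(m[4])) {
      for (kv in strsplit(m[4], ",")[[1]]) {
        parts <- strsplit(trimws(kv), "=")[[1]]
        if (length(parts) != 2) {
          stop_chemocal(sprintf("cannot parse derivative argument '%s'", kv),
                        "format_error")
        }
        val <- as.integer(parts[2])
        switch(trimws(parts[1]),
               poly = { poly <- val },
               window = { window <- val },
               stop_chemocal(sprintf("unknown derivative argument '%s'", parts[1]),
                             "format_error"))
      }
    }
    return(list(kind = "sg_derivative", derivative_order = d,
                polynomial_order = poly, window_points = window))
  }
  stop_chemocal(sprintf("unknown pretreatment token '%s'", token), "format_error")
}

#' @export
format.preprocess_spec <- function(x, ...) {
  if (!length(x$steps)) return("original")
  paste(vapply(x$steps, function(s) {
    if (s$kind == "sg_derivative") {
      sprintf("d%d(poly=%d,window=%d)", s$derivative_order,
              s$polynomial_order, s$window_points)
    } else s$kind
  }, ""), collapse = "+")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("<preprocess_spec>", format(x), "\n")
  invisible(x)
}

#' Apply a pretreatment recipe to a spectra set
#'
#' Steps are applied sample-wise, in the listed order. The wavenumber grid
#' and the sample metadata (including reference values) are unchanged; only
#' intensities are transformed.
#'
#' @param set A `spectra_set`.
#' @param spec Anything [preprocess_spec()] accepts.
#' @return The transformed `spectra_set`.
#' @export
apply_pipeline <- function(set, spec = "original") {
  spec <- preprocess_spec(spec)
  X <- set$absorbance
  ids <- set$samples$sample_id
  for (s in spec$steps) {
    if (s$kind == "snv") {
      sds <- apply(X, 1, sd)
      bad <- which(!is.finite(sds) | sds == 0)
      if (length(bad)) {
        stop_chemocal(sprintf("SNV failed for sample '%s': zero variance",
                              ids[bad[1]]), "degenerate_error")
      }
      X <- (X - rowMeans(X)) / sds
    } else if (s$kind == "area_norm") {
      areas <- rowSums(abs(X))
      bad <- which(!is.finite(areas) | areas == 0)
      if (length(bad)) {
        stop_chemocal(sprintf("area normalization failed for sample '%s': zero area",
                              ids[bad[1]]), "degenerate_error")
      }
      X <- X / areas
    } else {
      X <- sg_derivative_matrix(X, set$wavenumber, s$derivative_order,
                                s$polynomial_order, s$window_points)
    }
  }
  set$absorbance <- X
  set
}
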