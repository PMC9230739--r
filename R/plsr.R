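#' Fit a PLSR calibration by NIPALS
#'
#' Sequential NIPALS extraction of latent factors from the column-mean-
#' centered spectral matrix and the mean-centered reference vector, with
#' deflation of X (and y) after each factor. No variance scaling is applied:
#' the pretreatment steps are expected to do any scaling work. The returned
#' regression vector reproduces the factor model's fitted values, so
#' prediction is a single centered matrix-vector product.
#'
#' @param X Numeric matrix, samples x variables (e.g. retained wavenumbers).
#' @param y Numeric reference vector (mg/unit), one value per row of X.
#' @param n_factors Number of latent factors, at most `min(nrow(X) - 1,
#'   ncol(X))`.
#' @param tol Inner NIPALS convergence tolerance on the weight vector
#'   (univariate-y NIPALS converges in one pass; the guard covers degenerate
#'   inputs).
#' @param max_iter Inner iteration cap.
#' @return A `plsr_model` object with components `n_factors`, `x_mean`,
#'   `y_mean`, `weights`, `x_loadings`, `y_loadings`, `scores`,
#'   `coefficients` (the regression vector), `fitted`, and the training `y`.
#' @export
fit_plsr <- function(X, y, n_factors, tol = 1e-12, max_iter = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_chemocal("length(y) must equal nrow(X)", "input_error")
  if (sd(y) == 0) stop_chemocal("reference values have zero variance", "design_error")
  if (n_factors < 1 || n_factors > min(n - 1, p)) {
    stop_chemocal("n_factors must be in 1..min(n_samples - 1, n_features)",
                  "rank_error")
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  scale0 <- sqrt(sum(E^2))

  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  Q <- numeric(n_factors)
  T <- matrix(0, n, n_factors)

  for (a in seq_len(n_factors)) {
    u <- f
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- drop(crossprod(E, u))
      nw <- sqrt(sum(w_new^2))
      if (nw <= tol * max(scale0, 1)) {
        stop_chemocal(sprintf(
          "X deflated to (numerical) zero at factor %d: n_factors too large for the data rank", a),
          "rank_error")
      }
      w_new <- w_new / nw
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
      # with a single y column the score/weight pair is already stationary
      if (it >= 1) break
    }
    t_sc <- drop(E %*% w)
    tt <- sum(t_sc^2)
    if (tt <= (tol * max(scale0, 1))^2) {
      stop_chemocal(sprintf("degenerate score vector at factor %d", a), "rank_error")
    }
    p_load <- drop(crossprod(E, t_sc)) / tt
    q <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q * t_sc
    W[, a] <- w; P[, a] <- p_load; Q[a] <- q; T[, a] <- t_sc
  }

  B <- W %*% solve(crossprod(P, W), Q)
  fitted <- drop(y_mean + sweep(X, 2, x_mean) %*% B)

  structure(list(
    n_factors = as.integer(n_factors),
    x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = Q, scores = T,
    coefficients = drop(B),
    fitted = fitted, y = y,
    wavenumber = {
      v <- suppressWarnings(as.numeric(colnames(X)))
      if (length(v) && !anyNA(v)) v else numeric()
    },
    intervals = NULL, preprocess = NULL
  ), class = "plsr_model")
}

# Regression vectors for every truncated factor count 1..A in one pass;
# used by cross-validation so each fold is fitted once at max_factors.
plsr_coef_path <- function(model) {
  A <- model$n_factors
  p <- nrow(model$weights)
  out <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- model$weights[, 1:a, drop = FALSE]
    Pa <- model$x_loadings[, 1:a, drop = FALSE]
    out[, a] <- Wa %*% solve(crossprod(Pa, Wa), model$y_loadings[1:a])
  }
  out
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent factor(s), %d variables\n",
              x$n_factors, length(x$coefficients)))
  cat(sprintf("  calibration: n = %d, RMSEC = %.4g, R2 = %.4f\n",
              length(x$y), rmsep(x$fitted, x$y), r2_model(x$fitted, x$y)))
  invisible(x)
}

#' Predict analyte content from a fitted PLSR model
#'
#' For a plain matrix, columns must match the variables the model was
#' trained on. For a `spectra_set`, the model's stored interval selection
#' and pretreatment recipe (when present, i.e. the model came from
#' [run_grid()] or [plsr_calibrate()]) are applied first, after a grid
#' compatibility check.
#'
#' @param object A `plsr_model`.
#' @param newdata Numeric matrix or `spectra_set`.
#' @param ... Unused.
#' @return Numeric vector of predicted contents (mg/unit).
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    set <- newdata
    if (!is.null(object$intervals)) set <- select_intervals(set, object$intervals)
    if (!is.null(object$preprocess)) set <- apply_pipeline(set, object$preprocess)
    if (length(object$wavenumber)) check_same_grid(set$wavenumber, object$wavenumber)
    X <- set$absorbance
  } else {
    X <- as.matrix(newdata)
  }
  if (ncol(X) != length(object$coefficients)) {
    stop_chemocal("newdata has the wrong number of variables for this model",
                  "compatibility_error")
  }
  drop(object$y_mean + sweep(X, 2, object$x_mean) %*% object$coefficients)
}

#' Cross-validate a PLSR fit over candidate factor counts
#'
#' For each candidate factor count 1..`max_factors`, every held-out sample
#' (leave-one-out) or segment is predicted by a model fitted without it;
#' RMSECV and the cross-validated R-squared (1 - PRESS/SS_tot) are reported
#' per count. The default scheme is leave-one-out up to 100 samples and 10
#' seeded random segments beyond that.
#'
#' @param X Numeric matrix, samples x variables.
#' @param y Reference vector.
#' @param max_factors Largest factor count to consider (capped so the
#'   smallest training fold can support it).
#' @param scheme `"auto"`, `"loo"`, or `"segments"`.
#' @param n_segments Segment count for the segment scheme.
#' @param seed Seed for random segment assignment.
#' @return A `plsr_cv` tibble with columns `n_factors`, `rmsecv`, `r2_cv`,
#'   `press`.
#' @export
cross_validate <- function(X, y, max_factors, scheme = c("auto", "loo", "segments"),
                           n_segments = 10, seed = 1) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (scheme == "auto") scheme <- if (n <= 100) "loo" else "segments"
  if (scheme == "segments" && n_segments > n) {
    stop_chemocal("more segments than samples", "parameter_error")
  }
  folds <- if (scheme == "loo") as.list(seq_len(n)) else {
    assignment <- withr::with_seed(seed, sample(rep(seq_len(n_segments),
                                                    length.out = n)))
    split(seq_len(n), assignment)
  }
  min_train <- n - max(lengths(folds))
  if (max_factors > min(min_train - 1, ncol(X))) {
    stop_chemocal("max_factors too large for the smallest training fold",
                  "parameter_error")
  }

  pred <- matrix(NA_real_, n, max_factors)
  for (fold in folds) {
    fit <- fit_plsr(X[-fold, , drop = FALSE], y[-fold], max_factors)
    Bs <- plsr_coef_path(fit)
    Xc <- sweep(X[fold, , drop = FALSE], 2, fit$x_mean)
    pred[fold, ] <- fit$y_mean + Xc %*% Bs
  }
  press <- colSums((pred - y)^2)
  ss_tot <- sum((y - mean(y))^2)
  out <- tibble(
    n_factors = seq_len(max_factors),
    rmsecv = sqrt(press / n),
    r2_cv = 1 - press / ss_tot,
    press = press
  )
  structure(out, class = c("plsr_cv", class(out)),
            scheme = scheme, n_segments = if (scheme == "segments") n_segments else NA)
}

#' Choose the latent factor count from cross-validation
#'
#' `min_rmsecv` takes the factor count minimizing RMSECV (lowest count on
#' ties). `parsimonious` takes the smallest count whose RMSECV is within
#' `(1 + tol)` of the minimum, trading a little error for a simpler model.
#'
#' @param cv A `plsr_cv` result.
#' @param rule `"min_rmsecv"` (default) or `"parsimonious"`.
#' @param tol Relative tolerance for the parsimonious rule.
#' @return The selected factor count (integer).
#' @export
select_n_factors <- function(cv, rule = c("min_rmsecv", "parsimonious"),
                             tol = 0.05) {
  rule <- match.arg(rule)
  if (!nrow(cv)) stop_chemocal("empty cross-validation result", "input_error")
  best <- min(cv$rmsecv)
  if (rule == "min_rmsecv") {
    cv$n_factors[which.min(cv$rmsecv)]
  } else {
    cv$n_factors[which(cv$rmsecv <= (1 + tol) * best)[1]]
  }
}

#' Calibrate a PLSR model on a spectra set
#'
#' High-level wrapper tying the pieces together for one model
#' configuration: interval selection, pretreatment, cross-validated factor
#' choice, and the final fit. The returned model stores the recipe so
#' [predict.plsr_model()] can be applied directly to raw spectra.
#'
#' @param set A `spectra_set` with reference values attached.
#' @param intervals Optional interval selection (anything
#'   [wavenumber_intervals()] accepts).
#' @param preprocess Pretreatment recipe (see [preprocess_spec()]).
#' @param n_factors Either a fixed factor count or `NULL` to select by
#'   cross-validation.
#' @param max_factors CV search cap when `n_factors` is `NULL`.
#' @param cv_scheme,cv_seed Passed to [cross_validate()].
#' @param factor_rule Passed to [select_n_factors()].
#' @return A `plsr_model` with `intervals`, `preprocess`, `cv` attached.
#' @export
plsr_calibrate <- function(set, intervals = NULL, preprocess = "original",
                           n_factors = NULL, max_factors = 10,
                           cv_scheme = "auto", cv_seed = 1,
                           factor_rule = "min_rmsecv") {
  y <- reference_values(set)
  if (is.null(y)) stop_chemocal("spectra set has no reference values", "design_error")
  work <- set
  if (!is.null(intervals)) work <- select_intervals(work, intervals)
  work <- apply_pipeline(work, preprocess)
  X <- work$absorbance
  colnames(X) <- as.character(work$wavenumber)

  cap <- min(max_factors, nrow(X) - 2, ncol(X))
  cv <- NULL
  if (is.null(n_factors)) {
    cv <- cross_validate(X, y, cap, scheme = cv_scheme, seed = cv_seed)
    n_factors <- select_n_factors(cv, rule = factor_rule)
  }
  model <- fit_plsr(X, y, n_factors)
  model$intervals <- if (is.null(intervals)) NULL else wavenumber_intervals(intervals)
  model$preprocess <- preprocess_spec(preprocess)
  model$wavenumber <- work$wavenumber
  model$cv <- cv
  model
}

#' Save / load a PLSR model as JSON
#'
#' The document stores the retained grid, interval selection, pretreatment
#' recipe, centering constants and regression vector at full double
#' precision, so a reloaded model re-predicts identically.
#'
#' @param model A `plsr_model`.
#' @param path Output path (`.json`).
#' @return `plsr_to_json()` returns `path` invisibly; `plsr_from_json()`
#'   returns the restored `plsr_model`.
#' @export
plsr_to_json <- function(model, path) {
  # numeric payloads are written as C99 hexadecimal floats: decimal JSON
  # numbers round-trip at most 15-17 significant digits, hex floats exactly
  doc <- list(
    n_factors = model$n_factors,
    x_mean = sprintf("%a", model$x_mean),
    y_mean = sprintf("%a", model$y_mean),
    coefficients = sprintf("%a", model$coefficients),
    wavenumber = sprintf("%a", model$wavenumber),
    intervals = if (is.null(model$intervals)) NULL else
      as.data.frame(model$intervals),
    preprocess = if (is.null(model$preprocess)) "original" else
      format(model$preprocess)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname plsr_to_json
#' @export
plsr_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    n_factors = as.integer(doc$n_factors),
    x_mean = as.numeric(doc$x_mean),
    y_mean = as.numeric(doc$y_mean),
    coefficients = as.numeric(doc$coefficients),
    wavenumber = if (length(doc$wavenumber)) as.numeric(doc$wavenumber)
      else numeric(),
    intervals = if (is.null(doc$intervals)) NULL else as_tibble(doc$intervals),
    preprocess = preprocess_spec(doc$preprocess %||% "original"),
    weights = NULL, x_loadings = NULL, y_loadings = NULL, scores = NULL,
    fitted = NULL, y = NULL
  ), class = "plsr_model")
}

#' Tidy a fitted PLSR model
#'
#' @param x A `plsr_model`.
#' @param ... Unused.
#' @return A tibble with one row per retained variable: `wavenumber` (when
#'   known) and `estimate`, the regression-vector coefficient.
#' @export
tidy.plsr_model <- function(x, ...) {
  wn <- x$wavenumber
  if (!length(wn) || anyNA(wn)) wn <- seq_along(x$coefficients)
  tibble(wavenumber = wn, estimate = x$coefficients)
}

#' One-row summary of a fitted PLSR model
#'
#' @param x A `plsr_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_factors`, `nobs`, `rmsec`, `r2_model` (NA
#'   for models restored from JSON, which carry no training data).
#' @export
glance.plsr_model <- function(x, ...) {
  if (is.null(x$fitted)) {
    return(tibble(n_factors = x$n_factors, nobs = NA_integer_,
                  rmsec = NA_real_, r2_model = NA_real_))
  }
  tibble(
    n_factors = x$n_factors,
    nobs = length(x$y),
    rmsec = rmsep(x$fitted, x$y),
    r2_model = r2_model(x$fitted, x$y)
  )
}
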