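#' Root-mean-square error of prediction
#'
#' `sqrt(mean((pred - ref)^2))`, in the units of the reference values
#' (mg/unit here). The same formula evaluated on the calibration fit is the
#' RMSEC; [cross_validate()] reports it on held-out samples as RMSECV.
#'
#' @param pred Predicted values.
#' @param ref Reference values (same length).
#' @return A non-negative scalar.
#' @examples
#' rmsep(c(2, 3, 6), c(1, 1, 3))  # sqrt(14/3)
#' @export
rmsep <- function(pred, ref) {
  check_paired(pred, ref, min_n = 1)
  sqrt(mean((pred - ref)^2))
}

#' @rdname rmsep
#' @export
rmsec <- rmsep

#' Mean signed prediction error (bias)
#'
#' `mean(pred - ref)`: the accuracy component of the RMSEP, positive when
#' the model over-predicts.
#'
#' @inheritParams rmsep
#' @return A scalar in reference units.
#' @export
bias <- function(pred, ref) {
  check_paired(pred, ref, min_n = 1)
  mean(pred - ref)
}

#' Squared Pearson correlation between predictions and references
#'
#' @inheritParams rmsep
#' @return A scalar in \[0, 1\].
#' @export
r2_pearson <- function(pred, ref) {
  check_paired(pred, ref, min_n = 2)
  if (sd(pred) == 0 || sd(ref) == 0) {
    stop_chemocal("zero variance: correlation undefined", "degenerate_error")
  }
  cor(pred, ref)^2
}

#' Coefficient of determination on the calibration set
#'
#' `1 - SS_res/SS_tot`. Unlike the squared-correlation variants this can be
#' negative for a model worse than the mean; the raw value is reported
#' (no clamping).
#'
#' @param fitted Fitted values.
#' @param ref Reference values.
#' @return A scalar (<= 1).
#' @export
r2_model <- function(fitted, ref) {
  check_paired(fitted, ref, min_n = 2)
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) {
    stop_chemocal("zero total sum of squares: R2 undefined", "degenerate_error")
  }
  1 - sum((fitted - ref)^2) / ss_tot
}

check_paired <- function(pred, ref, min_n = 1) {
  if (length(pred) != length(ref)) {
    stop_chemocal("pred and ref must have the same length", "input_error")
  }
  if (length(pred) < min_n) {
    stop_chemocal(sprintf("need at least %d paired values", min_n), "input_error")
  }
  if (!all(is.finite(pred)) || !all(is.finite(ref))) {
    stop_chemocal("non-finite values in pred/ref", "input_error")
  }
  invisible(TRUE)
}

#' Paired statistical comparison of two methods
#'
#' Tests whether the candidate method's determinations differ systematically
#' from the reference method's on the same samples. The default is the
#' two-sided paired t-test on the differences; a permutation (sign-flip)
#' alternative is provided for when normality of the differences is in
#' doubt.
#'
#' @param pred Candidate-method values.
#' @param ref Reference-method values (paired).
#' @param alpha Significance level for the verdict (default 0.05, i.e. a 95
#'   percent confidence level).
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_permutations Sign-flip draws for the permutation method.
#' @param seed Seed for the permutation method.
#' @return A one-row tibble: `p_value`, `mean_difference`, `n`, `method`,
#'   `verdict` (`"no significant difference"` or
#'   `"significant difference"`).
#' @export
paired_comparison <- function(pred, ref, alpha = 0.05,
                              method = c("t", "permutation"),
                              n_permutations = 9999, seed = 1) {
  method <- match.arg(method)
  check_paired(pred, ref, min_n = 3)
  d <- pred - ref
  if (sd(d) == 0) {
    rlang::warn("all paired differences identical; reporting p = 1")
    p <- 1
  } else if (method == "t") {
    p <- t.test(d)$p.value
  } else {
    obs <- abs(mean(d))
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(i) {
        abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE))) >= obs
      }, TRUE))
    })
    p <- (exceed + 1) / (n_permutations + 1)
  }
  tibble(
    p_value = p,
    mean_difference = mean(d),
    n = length(d),
    method = method,
    verdict = if (p > alpha) "no significant difference" else "significant difference"
  )
}

#' Residual heteroscedasticity diagnostics
#'
#' Quantitative proxy for the visual residual-vs-reference inspection:
#' the Spearman rank correlation between absolute residuals and reference
#' values, with a one-sided (increasing-spread) p-value from a seeded
#' permutation of the residual assignment.
#'
#' @param pred Predicted values (n >= 5).
#' @param ref Reference values.
#' @param n_permutations Permutation draws (default 999).
#' @param seed Permutation seed.
#' @return A list of class `residual_diagnostics`: `residuals`,
#'   `hetero_stat` (Spearman rho), `hetero_p`, `n`.
#' @export
residual_diagnostics <- function(pred, ref, n_permutations = 999, seed = 1) {
  check_paired(pred, ref, min_n = 5)
  res <- pred - ref
  obs <- cor(abs(res), ref, method = "spearman")
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      cor(abs(sample(res)), ref, method = "spearman") >= obs
    }, TRUE))
  })
  structure(list(
    residuals = res,
    hetero_stat = obs,
    hetero_p = (exceed + 1) / (n_permutations + 1),
    n = length(res)
  ), class = "residual_diagnostics")
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<residual_diagnostics> n = %d, Spearman |res| vs ref = %.3f, p = %.4f\n",
    x$n, x$hetero_stat, x$hetero_p))
  invisible(x)
}

#' Assemble the standard metrics row for one model
#'
#' @param fitted,y_cal Calibration fitted values and references.
#' @param pred,y_val Validation predictions and references (optional).
#' @param cv A `plsr_cv` result (optional) from which RMSECV / cross-
#'   validated R-squared at `n_factors` are read.
#' @param n_factors Latent factor count used.
#' @return A one-row tibble with `n_factors`, `r2_model`, `r2_cv`,
#'   `r2_pearson`, `rmsec`, `rmsecv`, `rmsep`, `bias`, `n_cal`, `n_val`.
#' @export
model_metrics <- function(fitted, y_cal, pred = NULL, y_val = NULL,
                          cv = NULL, n_factors = NA_integer_) {
  row <- tibble(
    n_factors = as.integer(n_factors),
    r2_model = r2_model(fitted, y_cal),
    r2_cv = NA_real_,
    r2_pearson = NA_real_,
    rmsec = rmsep(fitted, y_cal),
    rmsecv = NA_real_,
    rmsep = NA_real_,
    bias = NA_real_,
    n_cal = length(y_cal),
    n_val = 0L
  )
  if (!is.null(cv) && !is.na(n_factors)) {
    i <- match(n_factors, cv$n_factors)
    if (!is.na(i)) {
      row$r2_cv <- cv$r2_cv[i]
      row$rmsecv <- cv$rmsecv[i]
    }
  }
  if (!is.null(pred)) {
    row$r2_pearson <- r2_pearson(pred, y_val)
    row$rmsep <- rmsep(pred, y_val)
    row$bias <- bias(pred, y_val)
    row$n_val <- length(y_val)
  }
  row
}
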