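#' Plot a spectra set
#'
#' Overlays the absorbance traces, colored by nominal content when that
#' metadata is present. Dense sets are thinned to at most `max_samples`
#' traces (evenly across the set) to keep the figure readable.
#'
#' @param object A `spectra_set`.
#' @param max_samples Maximum number of traces to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_set <- function(object, max_samples = 30, ...) {
  n <- n_spectra(object)
  if (n > max_samples) {
    object <- subset_samples(object, unique(round(seq(1, n, length.out = max_samples))))
  }
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                        group = .data$sample_id))
  if ("nominal_mg" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$nominal_mg),
                                linewidth = 0.3) +
      ggplot2::scale_color_viridis_c(name = "nominal (mg)")
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.5, linewidth = 0.3)
  }
  p + ggplot2::scale_x_reverse() +  # FTIR plotting convention
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "absorbance (a.u.)")
}

#' Plot a cross-validation curve
#'
#' RMSECV against the candidate latent-factor count, with the minimum
#' highlighted.
#'
#' @param object A `plsr_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plsr_cv <- function(object, ...) {
  best <- object[which.min(object$rmsecv), ]
  ggplot2::ggplot(object, ggplot2::aes(.data$n_factors, .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = best, color = "red", size = 3) +
    ggplot2::labs(x = "latent factors", y = "RMSECV (mg/unit)")
}

#' Calibration plot for a fitted PLSR model
#'
#' Fitted against reference contents on the calibration set, with the
#' identity line.
#'
#' @param object A `plsr_model` holding its training data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plsr_model <- function(object, ...) {
  if (is.null(object$fitted)) {
    stop_chemocal("model carries no training data to plot", "input_error")
  }
  df <- tibble(reference = object$y, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "reference content (mg/unit)",
                  y = "fitted content (mg/unit)")
}

#' Plot a grid-screening result
#'
#' RMSEP per configuration, colored by pretreatment; failed rows are
#' dropped.
#'
#' @param object A `grid_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_result <- function(object, ...) {
  df <- object[object$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$config_id), .data$rmsep,
                                   fill = .data$pretreatment)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "model configuration", y = "RMSEP (mg/unit)")
}

#' Prediction and residual plots for external validation
#'
#' @param pred Predicted contents.
#' @param ref Reference contents.
#' @return A ggplot object: predictions vs references (left) are shown via
#'   `plot_predictions()`; residuals vs references via `plot_residuals()`.
#' @export
plot_predictions <- function(pred, ref) {
  df <- tibble(reference = ref, predicted = pred)
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "reference content (mg/unit)",
                  y = "predicted content (mg/unit)")
}

#' @rdname plot_predictions
#' @export
plot_residuals <- function(pred, ref) {
  df <- tibble(reference = ref, residual = pred - ref)
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference content (mg/unit)", y = "residual (mg/unit)")
}
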