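#' Built-in model-screening grids
#'
#' Returns the standard screening grid for each dosage form: 13 tablet
#' configurations combining full-range and selected-interval spectra
#' (400-4000, 2700-4000, 500-1700, 2500-4000, 500-1700 + 2500-4000 cm^-1)
#' with the pretreatments {original, second derivative, area normalization,
#' area normalization + SNV, first derivative, first derivative + SNV}, and
#' 11 granule configurations over 400-3700 and 400-1700 + 2800-3700 cm^-1
#' with {original, SNV, area normalization} and SNV + first derivative at
#' polynomial orders 2-4 and windows 11/21. Each row carries the latent
#' factor count historically associated with it (`pinned_factors`), which
#' [run_grid()] can either re-derive by cross-validation (default) or reuse.
#'
#' @param form `"tablet"` or `"granule"`.
#' @return A `model_grid` tibble: `config_id`, `spectral_range`,
#'   `pretreatment`, `pinned_factors`, `max_factors`.
#' @export
builtin_grid <- function(form = c("tablet", "granule")) {
  form <- match.arg(form)
  if (form == "tablet") {
    tbl <- tibble(
      config_id = 1:13,
      spectral_range = c(
        "400-4000", "400-4000", "400-4000", "400-4000", "2700-4000",
        "400-4000", "400-4000", "500-1700", "2500-4000",
        "500-1700, 2500-4000", "500-1700", "2500-4000",
        "500-1700, 2500-4000"
      ),
      pretreatment = c(
        "original", "d2(poly=2,window=11)", "area_norm", "area_norm+snv",
        "area_norm+snv", "d1(poly=2,window=11)",
        "d1(poly=2,window=11)+snv", "d2(poly=2,window=11)",
        "d2(poly=2,window=11)", "d2(poly=2,window=11)",
        "area_norm+snv", "area_norm+snv", "area_norm+snv"
      ),
      pinned_factors = c(5L, 9L, 4L, 3L, 5L, 5L, 9L, 7L, 5L, 7L, 8L, 8L, 8L)
    )
  } else {
    tbl <- tibble(
      config_id = 1:11,
      spectral_range = c(
        "400-3700", "400-1700, 2800-3700", "400-3700",
        "400-1700, 2800-3700", "400-3700",
        rep("400-3700", 6)
      ),
      pretreatment = c(
        "original", "original", "snv", "snv", "area_norm",
        "snv+d1(poly=2,window=11)", "snv+d1(poly=2,window=21)",
        "snv+d1(poly=3,window=11)", "snv+d1(poly=3,window=21)",
        "snv+d1(poly=4,window=11)", "snv+d1(poly=4,window=21)"
      ),
      pinned_factors = c(2L, 2L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L)
    )
  }
  tbl$max_factors <- 10L
  structure(tbl, class = c("model_grid", class(tbl)), form = form)
}

#' Read / write a model grid as YAML
#'
#' Configuration files hold a list of entries `{id, intervals: [[lo, hi],
#' ...], preprocess: "snv+d1(poly=2,window=11)", max_factors}`; built-in
#' grids round-trip losslessly.
#'
#' @param grid A `model_grid` tibble.
#' @param path YAML path.
#' @return `write_grid_yaml()` returns `path` invisibly; `read_grid_yaml()`
#'   returns a `model_grid`.
#' @export
write_grid_yaml <- function(grid, path) {
  entries <- lapply(seq_len(nrow(grid)), function(i) {
    iv <- wavenumber_intervals(grid$spectral_range[i])
    list(
      id = grid$config_id[i],
      intervals = lapply(seq_len(nrow(iv)), function(j) c(iv$lo[j], iv$hi[j])),
      preprocess = grid$pretreatment[i],
      max_factors = grid$max_factors[i],
      pinned_factors = if (is.na(grid$pinned_factors[i])) NULL else
        grid$pinned_factors[i]
    )
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_grid_yaml
#' @export
read_grid_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  tbl <- purrr::map_dfr(entries, function(e) {
    iv <- wavenumber_intervals(lapply(e$intervals, as.numeric))
    tibble(
      config_id = as.integer(e$id),
      spectral_range = paste(sprintf("%g-%g", iv$lo, iv$hi), collapse = ", "),
      pretreatment = format(preprocess_spec(e$preprocess)),
      pinned_factors = if (is.null(e$pinned_factors)) NA_integer_ else
        as.integer(e$pinned_factors),
      max_factors = as.integer(e$max_factors %||% 10L)
    )
  })
  if (anyDuplicated(tbl$config_id)) {
    stop_chemocal("config ids must be unique within a grid", "format_error")
  }
  structure(tbl, class = c("model_grid", class(tbl)), form = "custom")
}

#' Run a model-screening grid
#'
#' For each configuration: restrict the spectra to its wavenumber
#' intervals, apply its pretreatment, choose the latent factor count by
#' cross-validation on the calibration subset (or reuse the pinned count),
#' fit the final model on the calibration subset, and evaluate it on the
#' validation subset. A configuration whose pretreatment fails is recorded
#' as a failed row and the grid continues.
#'
#' @param set A `spectra_set` with reference values.
#' @param split A `split_result` covering the set.
#' @param grid A `model_grid` (see [builtin_grid()], [read_grid_yaml()]).
#' @param cv_scheme,cv_seed Passed to [cross_validate()].
#' @param factor_rule Passed to [select_n_factors()].
#' @param use_pinned_factors Reuse the grid's `pinned_factors` instead of
#'   cross-validating.
#' @return A `grid_result` tibble, one metrics row per configuration
#'   (columns as in [model_metrics()], plus `config_id`, `spectral_range`,
#'   `pretreatment`, `status`). Fitted models are attached as the
#'   `"models"` attribute, keyed by config id.
#' @export
run_grid <- function(set, split, grid, cv_scheme = "auto", cv_seed = 1,
                     factor_rule = "min_rmsecv", use_pinned_factors = FALSE) {
  if (is.null(reference_values(set))) {
    stop_chemocal("spectra set has no reference values", "design_error")
  }
  cal <- split_subset(set, split, "calibration")
  val <- split_subset(set, split, "validation")
  models <- list()

  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cfg <- grid[i, ]
    base <- tibble(config_id = cfg$config_id,
                   spectral_range = cfg$spectral_range,
                   pretreatment = cfg$pretreatment)
    res <- tryCatch({
      nf <- if (use_pinned_factors && !is.na(cfg$pinned_factors)) {
        cfg$pinned_factors
      } else NULL
      model <- plsr_calibrate(
        cal, intervals = cfg$spectral_range, preprocess = cfg$pretreatment,
        n_factors = nf, max_factors = cfg$max_factors,
        cv_scheme = cv_scheme, cv_seed = cv_seed, factor_rule = factor_rule
      )
      pred <- if (n_spectra(val) > 0) predict(model, val) else NULL
      y_val <- if (n_spectra(val) > 0) reference_values(val) else NULL
      models[[as.character(cfg$config_id)]] <<- model
      dplyr::bind_cols(
        base,
        model_metrics(model$fitted, model$y, pred, y_val,
                      cv = model$cv, n_factors = model$n_factors),
        tibble(status = "ok", message = NA_character_)
      )
    }, chemocal_error = function(e) {
      dplyr::bind_cols(base, tibble(status = "failed",
                                    message = conditionMessage(e)))
    })
    res
  })
  # failed rows lack the metric columns; normalize
  metric_cols <- c("n_factors", "r2_model", "r2_cv", "r2_pearson",
                   "rmsec", "rmsecv", "rmsep", "bias", "n_cal", "n_val")
  for (col in metric_cols) if (!col %in% names(rows)) rows[[col]] <- NA
  rows <- rows[, c("config_id", "spectral_range", "pretreatment",
                   metric_cols, "status", "message")]
  structure(rows, class = c("grid_result", class(rows)), models = models)
}

#' Rank grid rows and pick the best configuration
#'
#' Composite rank-sum: descending ranks on the R-squared criteria
#' (`r2_model`, `r2_pearson`) plus ascending ranks on the error criteria
#' (`rmsep`, `abs(bias)`), each multiplied by its weight; the lowest
#' composite wins. The default doubles the `bias` weight, encoding the
#' preference for an accurate (low-bias) model among candidates of similar
#' precision; equal weights are a one-argument change. Ties go to the model
#' with fewer latent factors, then the lower config id.
#'
#' @param grid_result A `grid_result` (or any data frame with the metric
#'   columns).
#' @param weights Named weights for `r2_model`, `r2_pearson`, `rmsep`,
#'   `bias`.
#' @return The winning `config_id`.
#' @export
select_best <- function(grid_result,
                        weights = c(r2_model = 1, r2_pearson = 1,
                                    rmsep = 1, bias = 2)) {
  ok <- grid_result
  if ("status" %in% names(ok)) ok <- ok[ok$status == "ok", ]
  ok <- ok[!is.na(ok$rmsep) & !is.na(ok$bias), ]
  if (!nrow(ok)) stop_chemocal("no successful grid rows to rank", "grid_error")
  w <- c(r2_model = 1, r2_pearson = 1, rmsep = 1, bias = 2)
  w[names(weights)] <- weights
  composite <-
    w["r2_model"] * rank(-ok$r2_model) +
    w["r2_pearson"] * rank(-ok$r2_pearson) +
    w["rmsep"] * rank(ok$rmsep) +
    w["bias"] * rank(abs(ok$bias))
  ord <- order(composite, ok$n_factors, ok$config_id)
  ok$config_id[ord[1]]
}

#' Write a grid report to CSV
#'
#' Columns mirror the conventional screening-report layout: model id,
#' spectral range, pretreatment, latent factors, then the metrics.
#'
#' @param grid_result A `grid_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid_result, path) {
  write.csv(as.data.frame(grid_result[setdiff(names(grid_result), "message")]),
            path, row.names = FALSE)
  invisible(path)
}
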