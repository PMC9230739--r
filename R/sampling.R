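#' Kennard-Stone sample selection
#'
#' Deterministic max-min coverage design: the first two selections are the
#' pair at maximal Euclidean distance; every subsequent selection maximizes
#' the minimum distance to the already-selected samples. Ties are broken by
#' the lowest row index, so the result is fully deterministic without a seed.
#'
#' @param X Numeric matrix or data frame, one row per sample.
#' @param k Number of samples to select (2 <= k <= nrow(X)).
#' @return Integer vector of selected row indices, in visiting order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stop_chemocal("Kennard-Stone needs k >= 2", "parameter_error")
  if (k > n) stop_chemocal("k exceeds the number of samples", "parameter_error")
  if (!all(is.finite(X))) stop_chemocal("non-finite features", "data_error")

  D <- as.matrix(stats::dist(X))
  # farthest pair; ties -> smallest (i, j) in row-major order
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0) idx <- matrix(c(1L, 2L), 1)  # all rows identical
  ord <- order(idx[, 1], idx[, 2])
  sel <- as.integer(idx[ord[1], ])

  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)  # which.max returns the first (lowest) index on ties
    sel <- c(sel, as.integer(nxt))
    mind <- pmin(mind, D[, nxt])
  }
  unname(sel)
}

new_split_result <- function(tbl, method, seed = NA_integer_) {
  tbl <- as_tibble(tbl)
  structure(tbl, class = c("split_result", class(tbl)),
            method = method, seed = seed)
}

#' Stratified random calibration/validation split
#'
#' Draws exactly `per_stratum_calibration` samples per stratum, uniformly
#' without replacement with a seeded generator; the remainder becomes the
#' validation set.
#'
#' @param strata Vector of stratum labels, one per sample (e.g. nominal
#'   strength). Names, if present, are used as sample ids.
#' @param per_stratum_calibration Calibration samples to draw per stratum.
#' @param seed Integer seed (required for reproducibility).
#' @param ids Optional character vector of sample ids.
#' @return A `split_result` tibble with columns `sample_id`, `stratum`,
#'   `role` (`"calibration"` or `"validation"`).
#' @export
stratified_random_split <- function(strata, per_stratum_calibration, seed,
                                    ids = NULL) {
  ids <- ids %||% names(strata) %||% as.character(seq_along(strata))
  strata <- as.character(strata)
  counts <- table(strata)
  if (any(counts < per_stratum_calibration)) {
    stop_chemocal("a stratum has fewer members than the calibration quota",
                  "design_error")
  }
  role <- rep("validation", length(strata))
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      members <- which(strata == s)
      take <- sample(members, per_stratum_calibration)
      role[take] <- "calibration"
    }
  })
  new_split_result(
    tibble(sample_id = ids, stratum = strata, role = role),
    method = "stratified_random", seed = as.integer(seed)
  )
}

#' Per-stratum Kennard-Stone split of a spectra set
#'
#' Runs [kennard_stone()] independently within each stratum on the raw
#' (un-pretreated) absorbances, optionally restricted to the wavenumber
#' intervals the downstream model will use, so each strength level
#' contributes exactly the designed number of calibration samples.
#'
#' @param set A `spectra_set`.
#' @param per_stratum_calibration Calibration samples per stratum.
#' @param strata Stratum labels (defaults to the `nominal_mg` metadata
#'   column).
#' @param intervals Optional interval selection applied before distance
#'   computation (the spectra themselves are not modified).
#' @return A `split_result` tibble (see [stratified_random_split()]).
#' @export
ks_split_by_stratum <- function(set, per_stratum_calibration, strata = NULL,
                                intervals = NULL) {
  if (is.null(strata)) {
    if (!"nominal_mg" %in% names(set$samples)) {
      stop_chemocal("no strata given and no nominal_mg metadata", "design_error")
    }
    strata <- set$samples$nominal_mg
  }
  strata <- as.character(strata)
  if (length(strata) != n_spectra(set)) {
    stop_chemocal("one stratum label per spectrum required", "design_error")
  }
  X <- if (is.null(intervals)) set$absorbance else {
    select_intervals(set, intervals)$absorbance
  }
  role <- rep("validation", nrow(X))
  for (s in unique(strata)) {
    members <- which(strata == s)
    if (length(members) < per_stratum_calibration) {
      stop_chemocal("a stratum has fewer members than the calibration quota",
                    "design_error")
    }
    if (per_stratum_calibration == length(members)) {
      role[members] <- "calibration"
    } else {
      picked <- kennard_stone(X[members, , drop = FALSE],
                              per_stratum_calibration)
      role[members[picked]] <- "calibration"
    }
  }
  new_split_result(
    tibble(sample_id = set$samples$sample_id, stratum = strata, role = role),
    method = "kennard_stone"
  )
}

#' Write / read a split to CSV
#'
#' Round-trips the `sample_id, role` assignment (stratum column included
#' when writing).
#'
#' @param split A `split_result`.
#' @param path CSV path.
#' @return `write_split_csv()` returns `path` invisibly; `read_split_csv()`
#'   returns a `split_result`.
#' @export
write_split_csv <- function(split, path) {
  write.csv(as.data.frame(split), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split_csv
#' @export
read_split_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% names(df))) {
    stop_chemocal("split CSV needs sample_id and role columns", "format_error")
  }
  if (!all(df$role %in% c("calibration", "validation"))) {
    stop_chemocal("role must be calibration or validation", "format_error")
  }
  if (!"stratum" %in% names(df)) df$stratum <- NA_character_
  new_split_result(as_tibble(df)[c("sample_id", "stratum", "role")],
                   method = "file")
}

split_ids <- function(split, role) {
  as.character(split$sample_id[split$role == role])
}

#' Extract the calibration or validation subset
#'
#' @param set A `spectra_set`.
#' @param split A `split_result` covering the set's sample ids.
#' @param role `"calibration"` or `"validation"`.
#' @return The corresponding `spectra_set` subset.
#' @export
split_subset <- function(set, split, role = c("calibration", "validation")) {
  role <- match.arg(role)
  subset_samples(set, split_ids(split, role))
}
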