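#' Construct a set of aligned spectra
#'
#' A `spectra_set` holds one absorbance trace per sample on a shared
#' wavenumber grid, together with a per-sample metadata table. It is the X
#' (and, through the `reference_mg` column, the y) of all downstream
#' modelling. The grid is stored in ascending wavenumber order regardless of
#' the order the data arrived in; combining spectra measured on different
#' grids is an error, never an implicit interpolation.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing after sorting, all within \[100, 8000\].
#' @param absorbance Numeric matrix, one row per sample, one column per grid
#'   point (a.u.).
#' @param samples A data frame of per-sample metadata with at least a
#'   `sample_id` column (unique). Optional recognised columns: `form`
#'   ("tablet" or "granule"), `nominal_mg`, `truth_mg`, `reference_mg`
#'   (the analyte content used as the regression reference, mg/unit).
#'   If `NULL`, ids are taken from `rownames(absorbance)` or generated.
#' @return An object of class `spectra_set`.
#' @examples
#' wn <- seq(400, 4000, by = 100)
#' a <- matrix(runif(3 * length(wn)), nrow = 3)
#' s <- spectra_set(wn, a, tibble::tibble(sample_id = c("a", "b", "c")))
#' s
#' @export
spectra_set <- function(wavenumber, absorbance, samples = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (is.vector(absorbance)) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"

  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  absorbance <- absorbance[, ord, drop = FALSE]

  if (anyDuplicated(wavenumber) || any(diff(wavenumber) <= 0)) {
    stop_chemocal("wavenumber grid must be strictly increasing (no duplicates)",
                  "data_error")
  }
  if (any(wavenumber < 100) || any(wavenumber > 8000)) {
    stop_chemocal("wavenumbers outside the plausible 100-8000 cm^-1 range",
                  "data_error")
  }
  if (ncol(absorbance) != length(wavenumber)) {
    stop_chemocal("absorbance column count must equal grid length", "data_error")
  }
  if (!all(is.finite(absorbance))) {
    stop_chemocal("absorbance contains non-finite values", "data_error")
  }

  if (is.null(samples)) {
    ids <- rownames(absorbance) %||% paste0("s", seq_len(nrow(absorbance)))
    samples <- tibble(sample_id = ids)
  }
  samples <- as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    stop_chemocal("`samples` must contain a sample_id column", "data_error")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (nrow(samples) != nrow(absorbance)) {
    stop_chemocal("sample table row count must equal spectrum count", "data_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_chemocal("sample ids must be unique", "data_error")
  }
  if ("reference_mg" %in% names(samples) &&
      !all(is.finite(samples$reference_mg))) {
    stop_chemocal("reference values must be finite for every sample", "data_error")
  }
  dimnames(absorbance) <- list(samples$sample_id, NULL)

  structure(
    list(wavenumber = wavenumber, absorbance = absorbance, samples = samples),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d spectra x %d wavenumbers (%.0f-%.0f cm^-1)\n",
    nrow(x$absorbance), length(x$wavenumber),
    min(x$wavenumber), max(x$wavenumber)
  ))
  extras <- setdiff(names(x$samples), "sample_id")
  if (length(extras)) cat("sample metadata:", paste(extras, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count of samples.
#' @export
n_spectra <- function(set) nrow(set$absorbance)

#' Accessors for spectra_set components
#'
#' `wavenumbers()` returns the shared grid, `absorbance_matrix()` the
#' samples-by-wavenumbers intensity matrix, `sample_info()` the metadata
#' tibble, and `reference_values()` the per-sample reference analyte content
#' (mg/unit) or `NULL` when absent.
#'
#' @param set A `spectra_set`.
#' @name spectra-accessors
NULL

#' @rdname spectra-accessors
#' @export
wavenumbers <- function(set) set$wavenumber

#' @rdname spectra-accessors
#' @export
absorbance_matrix <- function(set) set$absorbance

#' @rdname spectra-accessors
#' @export
sample_info <- function(set) set$samples

#' @rdname spectra-accessors
#' @export
reference_values <- function(set) {
  if ("reference_mg" %in% names(set$samples)) set$samples$reference_mg else NULL
}

#' Attach reference analyte contents to a spectra set
#'
#' Joins a reference table (e.g. HPLC determinations) onto the sample
#' metadata by `sample_id`. Every spectrum must receive a finite value.
#'
#' @param set A `spectra_set`.
#' @param reference Data frame with columns `sample_id` and `reference_mg`
#'   (content in mg per dosage unit).
#' @return The `spectra_set` with a populated `reference_mg` column.
#' @export
attach_reference <- function(set, reference) {
  reference <- as_tibble(reference)
  if (!all(c("sample_id", "reference_mg") %in% names(reference))) {
    stop_chemocal("reference table needs sample_id and reference_mg columns",
                  "format_error")
  }
  idx <- match(set$samples$sample_id, as.character(reference$sample_id))
  if (anyNA(idx)) {
    stop_chemocal("reference table is missing values for some spectra",
                  "data_error")
  }
  set$samples$reference_mg <- as.numeric(reference$reference_mg[idx])
  if (!all(is.finite(set$samples$reference_mg))) {
    stop_chemocal("reference values must be finite", "data_error")
  }
  set
}

#' Convert a spectra set to a long tibble
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `wavenumber`, `absorbance`,
#'   plus any sample metadata columns, one row per (sample, grid point).
#' @export
as_tibble.spectra_set <- function(x, ...) {
  n <- nrow(x$absorbance)
  p <- length(x$wavenumber)
  out <- tibble(
    sample_id = rep(x$samples$sample_id, each = p),
    wavenumber = rep(x$wavenumber, times = n),
    absorbance = as.vector(t(x$absorbance))
  )
  meta <- x$samples[setdiff(names(x$samples), "sample_id")]
  if (ncol(meta)) {
    out <- dplyr::left_join(out, x$samples, by = "sample_id")
  }
  out
}

#' Build a spectra set from a long tibble
#'
#' The inverse of [as_tibble.spectra_set()]: takes per-point records and
#' pivots them onto a shared grid. All samples must cover exactly the same
#' set of wavenumbers.
#'
#' @param data Data frame with columns `sample_id`, `wavenumber`,
#'   `absorbance`; any other columns constant within a sample are kept as
#'   metadata.
#' @return A `spectra_set`.
#' @export
spectra_from_tibble <- function(data) {
  data <- as_tibble(data)
  need <- c("sample_id", "wavenumber", "absorbance")
  if (!all(need %in% names(data))) {
    stop_chemocal("need sample_id, wavenumber and absorbance columns",
                  "format_error")
  }
  wide <- tidyr::pivot_wider(
    data[need],
    names_from = "wavenumber", values_from = "absorbance"
  )
  mat <- as.matrix(wide[-1])
  if (anyNA(mat)) {
    stop_chemocal("samples do not share a common wavenumber grid", "data_error")
  }
  meta_cols <- setdiff(names(data), c("wavenumber", "absorbance"))
  meta <- dplyr::distinct(data[meta_cols])
  if (anyDuplicated(meta$sample_id)) {
    stop_chemocal("metadata columns vary within a sample", "data_error")
  }
  meta <- meta[match(wide$sample_id, meta$sample_id), ]
  spectra_set(as.numeric(colnames(wide)[-1]), mat, meta)
}

#' Define wavenumber intervals
#'
#' Builds an interval-selection table from `(lo, hi)` pairs or from compact
#' text such as `"500-1700, 2500-4000"`. Bounds are inclusive on both ends.
#'
#' @param x Either a character scalar (`"lo-hi, lo-hi"`), a numeric vector of
#'   length 2, a list of length-2 numeric vectors, or a data frame with
#'   columns `lo`, `hi`.
#' @return A tibble with columns `lo` and `hi`, sorted, non-overlapping.
#' @examples
#' wavenumber_intervals("500-1700, 2500-4000")
#' @export
wavenumber_intervals <- function(x) {
  if (is.character(x)) {
    parts <- trimws(strsplit(x, ",")[[1]])
    parts <- parts[nzchar(parts)]
    pairs <- lapply(parts, function(p) {
      nums <- suppressWarnings(as.numeric(strsplit(p, "-", fixed = TRUE)[[1]]))
      if (length(nums) != 2 || anyNA(nums)) {
        stop_chemocal(sprintf("cannot parse interval '%s'", p), "format_error")
      }
      nums
    })
    tbl <- tibble(lo = vapply(pairs, `[`, 0, 1), hi = vapply(pairs, `[`, 0, 2))
  } else if (is.numeric(x) && length(x) == 2) {
    tbl <- tibble(lo = x[1], hi = x[2])
  } else if (is.list(x) && !is.data.frame(x)) {
    tbl <- tibble(
      lo = vapply(x, `[`, 0, 1),
      hi = vapply(x, `[`, 0, 2)
    )
  } else if (is.data.frame(x)) {
    tbl <- as_tibble(x[c("lo", "hi")])
  } else {
    stop_chemocal("unrecognized interval specification", "format_error")
  }
  if (any(tbl$lo >= tbl$hi)) {
    stop_chemocal("each interval needs lo < hi", "parameter_error")
  }
  tbl <- tbl[order(tbl$lo), ]
  if (nrow(tbl) > 1 && any(tbl$lo[-1] <= tbl$hi[-nrow(tbl)])) {
    stop_chemocal("intervals overlap after sorting", "parameter_error")
  }
  tbl
}

#' Restrict a spectra set to wavenumber intervals
#'
#' Keeps the grid points falling inside any of the given intervals
#' (inclusive bounds on both ends, matching the conventional
#' "500-1700, 2500-4000 cm^-1" notation). Sample metadata, including
#' reference values, is carried through unchanged. The operation is
#' idempotent.
#'
#' @param set A `spectra_set`.
#' @param intervals Anything [wavenumber_intervals()] accepts.
#' @return The restricted `spectra_set`.
#' @export
select_intervals <- function(set, intervals) {
  iv <- wavenumber_intervals(intervals)
  keep <- rep(FALSE, length(set$wavenumber))
  for (i in seq_len(nrow(iv))) {
    keep <- keep | (set$wavenumber >= iv$lo[i] & set$wavenumber <= iv$hi[i])
  }
  if (!any(keep)) {
    stop_chemocal("no grid point falls inside the requested intervals",
                  "selection_error")
  }
  set$wavenumber <- set$wavenumber[keep]
  set$absorbance <- set$absorbance[, keep, drop = FALSE]
  set
}

#' Subset a spectra set by sample
#'
#' @param set A `spectra_set`.
#' @param ids Character vector of sample ids (or logical/integer index).
#' @return The subset `spectra_set`, in the order requested.
#' @export
subset_samples <- function(set, ids) {
  if (is.character(ids)) {
    idx <- match(ids, set$samples$sample_id)
    if (anyNA(idx)) stop_chemocal("unknown sample id(s)", "data_error")
  } else {
    idx <- seq_len(n_spectra(set))[ids]
  }
  set$absorbance <- set$absorbance[idx, , drop = FALSE]
  set$samples <- set$samples[idx, ]
  set
}

# Shared-grid guard used by prediction and set combination.
check_same_grid <- function(a, b, tol = 1e-9) {
  ga <- if (inherits(a, "spectra_set")) a$wavenumber else a
  gb <- if (inherits(b, "spectra_set")) b$wavenumber else b
  if (length(ga) != length(gb) ||
      max(abs(ga - gb)) > tol * max(1, max(abs(ga)))) {
    stop_chemocal("wavenumber grids differ; resampling is not performed",
                  "compatibility_error")
  }
  invisible(TRUE)
}
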