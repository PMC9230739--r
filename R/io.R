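#' Read spectra from CSV
#'
#' Two layouts are supported. `wide`: first column `wavenumber_cm-1`, one
#' column of absorbances per sample (header = sample id). `long`: columns
#' `sample_id, wavenumber_cm-1, absorbance`. Grids stored in descending
#' instrument order are normalized to ascending wavenumber.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` (default) or `"long"`.
#' @return A `spectra_set`.
#' @export
read_csv_spectra <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop_chemocal(sprintf("file not found: %s", path), "io_error")
  }
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1) {
    stop_chemocal("ragged rows: not all CSV lines have the same field count",
                  "format_error")
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (ncol(df) < 2) stop_chemocal("wide CSV needs at least 2 columns", "format_error")
    wn <- suppressWarnings(as.numeric(df[[1]]))
    if (anyNA(wn)) {
      stop_chemocal("wavenumber column is not fully numeric", "format_error")
    }
    mat <- t(as.matrix(df[-1]))
    if (!is.numeric(mat) || anyNA(mat)) {
      stop_chemocal("absorbance cells missing or non-numeric", "format_error")
    }
    spectra_set(wn, mat, tibble(sample_id = colnames(df)[-1]))
  } else {
    need <- c("sample_id", "wavenumber_cm-1", "absorbance")
    if (!all(need %in% names(df))) {
      stop_chemocal("long CSV needs sample_id, wavenumber_cm-1, absorbance",
                    "format_error")
    }
    if (anyNA(df[["absorbance"]]) || anyNA(df[["wavenumber_cm-1"]])) {
      stop_chemocal("missing cells in long CSV", "format_error")
    }
    spectra_from_tibble(tibble(
      sample_id = as.character(df$sample_id),
      wavenumber = as.numeric(df[["wavenumber_cm-1"]]),
      absorbance = as.numeric(df$absorbance)
    ))
  }
}

#' Write spectra to CSV
#'
#' @param set A `spectra_set`.
#' @param path Output path.
#' @param layout `"wide"` or `"long"` (see [read_csv_spectra()]).
#' @return `path`, invisibly.
#' @export
write_csv_spectra <- function(set, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(`wavenumber_cm-1` = set$wavenumber, check.names = FALSE)
    mat <- t(set$absorbance)
    colnames(mat) <- set$samples$sample_id
    df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  } else {
    long <- as_tibble(set)[c("sample_id", "wavenumber", "absorbance")]
    names(long)[2] <- "wavenumber_cm-1"
    df <- as.data.frame(long, check.names = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference-value table
#'
#' Expects columns `sample_id, form, nominal_mg, reference_mg` (the latter
#' being the per-unit analyte content determined by the reference method).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_reference_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "reference_mg")
  if (!all(need %in% names(df))) {
    stop_chemocal("reference CSV needs at least sample_id and reference_mg",
                  "format_error")
  }
  as_tibble(df)
}

#' Read a JCAMP-DX spectrum
#'
#' Minimal reader for uncompressed AFFN `##XYDATA=(X++(Y..Y))` and
#' `##XYPOINTS=(XY..XY)` records, the plain-text dialect FTIR instruments
#' export. Transmittance traces (`##YUNITS=TRANSMITTANCE`) are converted to
#' absorbance via -log10(T). Compressed dialects (SQZ/DIF/DUP/PAC) are
#' rejected.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return A one-sample `spectra_set` (grid ascending).
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) {
    stop_chemocal(sprintf("file not found: %s", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)  # strip comments

  hdr <- list(XFACTOR = 1, YFACTOR = 1, TITLE = basename(path))
  data_mode <- NULL
  data_lines <- character()
  in_data <- FALSE
  for (ln in lines) {
    if (grepl("^##", ln)) {
      if (in_data) break  # any label after the data table ends it (##END etc.)
      lab <- toupper(sub("^##([^=]*)=.*$", "\\1", ln))
      val <- trimws(sub("^##[^=]*=", "", ln))
      if (lab %in% c("XYDATA", "XYPOINTS")) {
        data_mode <- lab
        in_data <- TRUE
        if (data_mode == "XYDATA" && !grepl("X\\+\\+\\(Y\\.\\.Y\\)", val)) {
          stop_chemocal("unsupported XYDATA variable list", "format_error")
        }
      } else {
        hdr[[gsub("[ /_-]", "", lab)]] <- val
      }
    } else if (in_data && nzchar(trimws(ln))) {
      data_lines <- c(data_lines, ln)
    }
  }
  if (is.null(data_mode)) {
    stop_chemocal("no ##XYDATA or ##XYPOINTS table found", "format_error")
  }
  if (any(grepl("[^0-9.,;+\\-eE[:space:]]", data_lines))) {
    stop_chemocal("compressed JCAMP encodings (SQZ/DIF/DUP) are not supported",
                  "format_error")
  }

  xf <- as.numeric(hdr$XFACTOR %||% 1)
  yf <- as.numeric(hdr$YFACTOR %||% 1)
  if (data_mode == "XYPOINTS") {
    toks <- unlist(strsplit(paste(data_lines, collapse = ";"), "[;]"))
    toks <- toks[nzchar(trimws(toks))]
    pairs <- lapply(toks, function(t) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(t), "[,[:space:]]+")[[1]]))
      nums <- nums[!is.na(nums)]
      if (length(nums) != 2) stop_chemocal("malformed XYPOINTS pair", "format_error")
      nums
    })
    x <- vapply(pairs, `[`, 0, 1) * xf
    y <- vapply(pairs, `[`, 0, 2) * yf
  } else {
    x <- numeric(); y <- numeric()
    firstx <- as.numeric(hdr$FIRSTX)
    lastx <- as.numeric(hdr$LASTX)
    npts <- as.numeric(hdr$NPOINTS)
    deltax <- if (!is.null(hdr$DELTAX)) as.numeric(hdr$DELTAX) else {
      if (is.na(firstx) || is.na(lastx) || is.na(npts) || npts < 2) {
        stop_chemocal("XYDATA needs FIRSTX/LASTX/NPOINTS or DELTAX", "format_error")
      }
      (lastx - firstx) / (npts - 1)
    }
    for (ln in data_lines) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]]))
      nums <- nums[!is.na(nums)]
      if (length(nums) < 2) next
      xs <- nums[1] * xf + deltax * (seq_along(nums[-1]) - 1)
      x <- c(x, xs)
      y <- c(y, nums[-1] * yf)
    }
  }
  if (!length(x)) stop_chemocal("empty JCAMP data table", "format_error")

  yunits <- toupper(hdr$YUNITS %||% "ABSORBANCE")
  if (startsWith(yunits, "TRANSMITT")) {
    if (any(y <= 0)) {
      stop_chemocal("non-positive transmittance cannot be converted", "data_error")
    }
    y <- -log10(y)
  }
  spectra_set(x, matrix(y, nrow = 1),
              tibble(sample_id = as.character(hdr$TITLE)))
}
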