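test_that("spectra_set normalizes grid order and validates invariants", {
  wn <- c(2000, 400, 1000)
  X <- matrix(1:6, nrow = 2)  # columns follow wn order
  s <- spectra_set(wn, X, tibble::tibble(sample_id = c("a", "b")))
  expect_equal(wavenumbers(s), c(400, 1000, 2000))
  expect_equal(absorbance_matrix(s)[, 3], c(1, 2), ignore_attr = TRUE)

  expect_error(spectra_set(c(400, 400, 500), matrix(1:3, 1)),
               class = "chemocal_data_error")
  expect_error(spectra_set(c(50, 500), matrix(1:2, 1)),
               class = "chemocal_data_error")
  expect_error(spectra_set(c(400, 500), matrix(c(1, NA), 1)),
               class = "chemocal_data_error")
  expect_error(
    spectra_set(c(400, 500), matrix(1:4, 2),
                tibble::tibble(sample_id = c("a", "a"))),
    class = "chemocal_data_error")
  expect_error(
    spectra_set(c(400, 500), matrix(1:4, 2),
                tibble::tibble(sample_id = c("a", "b"),
                               reference_mg = c(1, NA))),
    class = "chemocal_data_error")
})

test_that("wide and long CSV round-trips preserve the matrix", {
  s <- tiny_set()
  for (layout in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_csv_spectra(s, path, layout = layout)
    back <- read_csv_spectra(path, layout = layout)
    expect_equal(wavenumbers(back), wavenumbers(s))
    expect_equal(absorbance_matrix(back), absorbance_matrix(s),
                 tolerance = 1e-9)
    expect_equal(sample_info(back)$sample_id, sample_info(s)$sample_id)
  }
})

test_that("CSV reader handles descending grids and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,s1,s2",
               "3000,0.3,0.6", "2000,0.2,0.5", "1000,0.1,0.4"), path)
  s <- read_csv_spectra(path)
  expect_equal(wavenumbers(s), c(1000, 2000, 3000))
  expect_equal(absorbance_matrix(s)["s1", ], c(0.1, 0.2, 0.3),
               ignore_attr = TRUE)

  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,s1,s2", "1000,0.1,0.2", "2000,0.3"), ragged)
  expect_error(read_csv_spectra(ragged), class = "chemocal_format_error")

  missing_cell <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,s1,s2", "1000,0.1,", "2000,0.3,0.4"),
             missing_cell)
  expect_error(read_csv_spectra(missing_cell), class = "chemocal_format_error")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,s1", "1000,0.1", "1000,0.2"), dup)
  expect_error(read_csv_spectra(dup), class = "chemocal_data_error")
})

test_that("interval selection keeps inclusive bounds, unions, and is idempotent", {
  s <- spectra_set(c(400, 1000, 2000, 3000), matrix(1:8, nrow = 2),
                   tibble::tibble(sample_id = c("a", "b"),
                                  reference_mg = c(1, 2)))
  one <- select_intervals(s, "500-1700")
  expect_equal(wavenumbers(one), 1000)

  two <- select_intervals(s, "500-1700, 2500-4000")
  expect_equal(wavenumbers(two), c(1000, 3000))
  expect_equal(reference_values(two), c(1, 2))

  # inclusive endpoints
  edge <- select_intervals(s, "1000-2000")
  expect_equal(wavenumbers(edge), c(1000, 2000))

  expect_error(select_intervals(s, "4100-4200"),
               class = "chemocal_selection_error")

  # idempotence and full-cover identity
  expect_identical(select_intervals(two, "500-1700, 2500-4000"), two)
  full <- select_intervals(s, "100-8000")
  expect_equal(absorbance_matrix(full), absorbance_matrix(s))
})

test_that("interval parsing validates structure", {
  iv <- wavenumber_intervals("2500-4000,500-1700")
  expect_equal(iv$lo, c(500, 2500))  # sorted
  expect_error(wavenumber_intervals("1700-500"),
               class = "chemocal_parameter_error")
  expect_error(wavenumber_intervals("500-1700, 1600-2000"),
               class = "chemocal_parameter_error")
})

test_that("long-tibble bridge inverts the set representation", {
  s <- tiny_set(n = 3)
  df <- tibble::as_tibble(s)
  expect_equal(nrow(df), 3 * length(wavenumbers(s)))
  back <- spectra_from_tibble(df)
  expect_equal(absorbance_matrix(back), absorbance_matrix(s))
  expect_equal(sample_info(back)$reference_mg, sample_info(s)$reference_mg)
})

test_that("JCAMP reader parses XYPOINTS, XYDATA and transmittance records", {
  xyp <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=demo", "##JCAMP-DX=4.24", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XYPOINTS=(XY..XY)",
    "400.0, 0.10; 500.0, 0.20",
    "600.0, 0.30; 700.0, 0.40",
    "##END="), xyp)
  s <- read_jcamp(xyp)
  expect_equal(wavenumbers(s), c(400, 500, 600, 700))
  expect_equal(drop(absorbance_matrix(s)), c(0.1, 0.2, 0.3, 0.4),
               ignore_attr = TRUE)

  xyd <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=trans", "##XUNITS=1/CM", "##YUNITS=TRANSMITTANCE",
    "##FIRSTX=400", "##LASTX=460", "##NPOINTS=4", "##XFACTOR=1", "##YFACTOR=0.1",
    "##XYDATA=(X++(Y..Y))",
    "400 1 1", "440 1 1",
    "##END="), xyd)
  t <- read_jcamp(xyd)  # T = 0.1 everywhere -> A = 1
  expect_equal(wavenumbers(t), c(400, 420, 440, 460))
  expect_equal(drop(absorbance_matrix(t)), rep(1, 4), ignore_attr = TRUE)

  nodata <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=x", "##END="), nodata)
  expect_error(read_jcamp(nodata), class = "chemocal_format_error")

  sqz <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=x", "##FIRSTX=400", "##LASTX=410", "##NPOINTS=2",
               "##XYDATA=(X++(Y..Y))", "400 A1B2", "##END="), sqz)
  expect_error(read_jcamp(sqz), class = "chemocal_format_error")
})
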