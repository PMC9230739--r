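test_that("builtin grids enumerate the standard configurations", {
  tab <- builtin_grid("tablet")
  expect_equal(nrow(tab), 13)
  expect_equal(tab$spectral_range[13], "500-1700, 2500-4000")
  expect_equal(tab$pretreatment[13], "area_norm+snv")
  expect_equal(tab$spectral_range[5], "2700-4000")
  expect_equal(tab$pinned_factors,
               c(5L, 9L, 4L, 3L, 5L, 5L, 9L, 7L, 5L, 7L, 8L, 8L, 8L))
  expect_setequal(unique(tab$spectral_range),
                  c("400-4000", "2700-4000", "500-1700", "2500-4000",
                    "500-1700, 2500-4000"))

  gra <- builtin_grid("granule")
  expect_equal(nrow(gra), 11)
  expect_setequal(unique(gra$spectral_range),
                  c("400-3700", "400-1700, 2800-3700"))
  d1_rows <- grep("d1", gra$pretreatment, value = TRUE)
  expect_length(d1_rows, 6)
  expect_setequal(d1_rows, paste0("snv+d1(poly=", rep(2:4, each = 2),
                                  ",window=", c(11, 21), ")"))
  expect_error(builtin_grid("capsule"))
})

test_that("grids round-trip through the YAML config format", {
  for (form in c("tablet", "granule")) {
    g <- builtin_grid(form)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_grid_yaml(g, path)
    back <- read_grid_yaml(path)
    expect_equal(back$config_id, g$config_id)
    expect_equal(back$spectral_range, g$spectral_range)
    expect_equal(back$pinned_factors, g$pinned_factors)
    # pretreatment strings normalize to the same recipe
    expect_equal(lapply(back$pretreatment, preprocess_spec),
                 lapply(g$pretreatment, preprocess_spec))
  }
})

test_that("ranking prefers dominance and weighs accuracy as documented", {
  rows <- tibble::tibble(
    config_id = 1:2, n_factors = c(3L, 3L),
    r2_model = c(0.99, 0.90), r2_pearson = c(0.99, 0.90),
    rmsep = c(1, 2), bias = c(0.1, 0.3)
  )
  expect_equal(select_best(rows), 1)  # dominates on all four criteria

  equal_r2 <- tibble::tibble(
    config_id = 1:2, n_factors = c(3L, 3L),
    r2_model = c(0.97, 0.97), r2_pearson = c(0.96, 0.96),
    rmsep = c(1.8, 1.8), bias = c(0.27, 0.05)
  )
  expect_equal(select_best(equal_r2), 2)

  single <- rows[1, ]
  expect_equal(select_best(single), 1)
  expect_error(select_best(rows[0, ]), class = "chemocal_grid_error")
})

test_that("ranking the published screening report reproduces its choice", {
  fx <- screening_report_fixture()
  equal_weights <- select_best(fx, weights = c(r2_model = 1, r2_pearson = 1,
                                               rmsep = 1, bias = 1))
  expect_true(equal_weights %in% c(11, 13))
  expect_equal(select_best(fx), 13)  # |bias|-weighted default
})

test_that("run_grid evaluates every configuration and is deterministic", {
  set <- generate_set(synthetic_design("tablet", seed = 12,
                                       replicates_per_strength = 6))
  sp <- ks_split_by_stratum(set, 4)
  grid <- builtin_grid("tablet")[c(1, 11, 13), ]
  res <- run_grid(set, sp, grid, cv_seed = 7)
  expect_equal(nrow(res), 3)
  expect_true(all(res$status == "ok"))
  metric_cols <- c("r2_model", "r2_cv", "r2_pearson", "rmsec", "rmsecv",
                   "rmsep", "bias")
  expect_true(all(is.finite(as.matrix(res[metric_cols]))))
  expect_true(all(res$n_cal == 28), all(res$n_val == 14))

  res2 <- run_grid(set, sp, grid, cv_seed = 7)
  expect_identical(as.data.frame(res), as.data.frame(res2))

  # duplicated configuration gives an identical metrics row
  twin <- grid[c(3, 3), ]
  twin$config_id <- c(13L, 99L)
  rtwin <- run_grid(set, sp, twin, cv_seed = 7)
  expect_equal(as.data.frame(rtwin[1, metric_cols]),
               as.data.frame(rtwin[2, metric_cols]))

  best <- select_best(res)
  expect_true(best %in% res$config_id)
  model <- attr(res, "models")[[as.character(best)]]
  expect_s3_class(model, "plsr_model")
})

test_that("a failing configuration is recorded and the grid continues", {
  set <- generate_set(synthetic_design("tablet", seed = 13,
                                       replicates_per_strength = 3))
  grid <- builtin_grid("tablet")[c(1, 13), ]
  grid$spectral_range[1] <- "7900-8000"  # empty selection -> failure
  sp <- ks_split_by_stratum(set, 2)
  res <- run_grid(set, sp, grid)
  expect_equal(res$status, c("failed", "ok"))
  expect_match(res$message[1], "interval")
  expect_true(is.finite(res$rmsep[2]))
})
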