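test_that("one factor recovers a rank-1 noiseless relation exactly", {
  withr::with_seed(1, {
    x <- rnorm(20)
    X <- cbind(x, 2 * x, -x)  # rank 1
    y <- 3 * x + 5
  })
  m <- fit_plsr(X, y, 1)
  expect_equal(m$fitted, y, tolerance = 1e-10)
  expect_equal(predict(m, X), y, tolerance = 1e-10)
})

test_that("full-rank PLSR equals ordinary least squares on 200 instances", {
  withr::with_seed(33, {
    for (rep in 1:200) {
      n <- sample(6:15, 1)
      p <- sample(2:5, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      m <- fit_plsr(X, y, p)
      expect_equal(m$fitted, ols_fitted(X, y),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  })
})

test_that("NIPALS factors have unit-norm weights and orthogonal scores", {
  withr::with_seed(4, {
    X <- matrix(rnorm(30 * 12), 30, 12)
    y <- rnorm(30)
  })
  m <- fit_plsr(X, y, 6)
  expect_equal(colSums(m$weights^2), rep(1, 6), tolerance = 1e-10)
  G <- crossprod(m$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("constant columns are inert and rank errors are raised", {
  withr::with_seed(5, {
    X <- matrix(rnorm(15 * 4), 15, 4)
    y <- rnorm(15)
  })
  with_const <- cbind(X, 7)
  m1 <- fit_plsr(X, y, 3)
  m2 <- fit_plsr(with_const, y, 3)
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-10)
  expect_equal(m2$coefficients[5], 0, tolerance = 1e-10)

  expect_error(fit_plsr(X, y, 20), class = "chemocal_rank_error")
  expect_error(fit_plsr(X, rep(2, 15), 2), class = "chemocal_design_error")
  # X of true rank 1 cannot support 3 informative factors
  r1 <- outer(rnorm(10), rnorm(4))
  expect_error(fit_plsr(r1, r1[, 1], 3), class = "chemocal_rank_error")
})

test_that("prediction obeys centering identities", {
  withr::with_seed(6, {
    X <- matrix(rnorm(12 * 5), 12, 5)
    y <- rnorm(12)
  })
  m <- fit_plsr(X, y, 3)
  expect_equal(drop(predict(m, matrix(m$x_mean, 1))), m$y_mean)
  dup <- predict(m, X[c(3, 3), ])
  expect_equal(dup[1], dup[2])
  expect_error(predict(m, X[, 1:3]), class = "chemocal_compatibility_error")
})

test_that("cross-validation is sane on noiseless data and is pessimistic", {
  withr::with_seed(7, {
    x <- rnorm(15)
    X <- cbind(x, 0.5 * x, -2 * x)  # noiseless rank-1 problem
    y <- 2 * x
  })
  cv <- cross_validate(X, y, 1, scheme = "loo")
  expect_equal(nrow(cv), 1)
  expect_lt(cv$rmsecv[1], 1e-6)
  expect_gt(cv$r2_cv[1], 1 - 1e-10)
  # one fit per held-out sample per factor count: segment scheme bookkeeping
  withr::with_seed(9, {
    Xn <- matrix(rnorm(30 * 4), 30, 4)
    yn <- Xn[, 1] + rnorm(30, 0, 0.2)
  })
  cvs <- cross_validate(Xn, yn, 3, scheme = "segments", n_segments = 5, seed = 2)
  expect_equal(nrow(cvs), 3)
  expect_true(all(is.finite(cvs$rmsecv)))
  expect_identical(
    as.data.frame(cross_validate(Xn, yn, 3, scheme = "segments",
                                 n_segments = 5, seed = 2)),
    as.data.frame(cvs))

  # optimism: held-out error >= calibration error at the OLS factor count
  withr::with_seed(8, {
    worse <- 0
    for (rep in 1:100) {
      n <- 12; p <- 3
      X <- matrix(rnorm(n * p), n, p)
      y <- X[, 1] + rnorm(n, 0, 0.5)
      cv <- cross_validate(X, y, p, scheme = "loo")
      m <- fit_plsr(X, y, p)
      worse <- worse + (cv$rmsecv[p] >= rmsep(m$fitted, y))
    }
    expect_equal(worse, 100)
  })

  expect_error(cross_validate(X, y, 2, scheme = "segments", n_segments = 50),
               class = "chemocal_parameter_error")
  expect_error(cross_validate(X, y, 10, scheme = "loo"),
               class = "chemocal_parameter_error")
})

test_that("factor-count selection rules follow their definitions", {
  cv <- tibble::tibble(n_factors = 1:4, rmsecv = c(5, 2, 2, 3),
                       r2_cv = NA, press = NA)
  expect_equal(select_n_factors(cv), 2)
  cv2 <- tibble::tibble(n_factors = 1:4, rmsecv = c(5, 2.05, 2, 3),
                        r2_cv = NA, press = NA)
  expect_equal(select_n_factors(cv2), 3)
  expect_equal(select_n_factors(cv2, rule = "parsimonious", tol = 0.05), 2)
  one <- cv[2, ]
  expect_equal(select_n_factors(one), 2)
})

test_that("a saved model re-predicts bit-identically after reload", {
  set <- generate_set(synthetic_design("tablet", seed = 21,
                                       replicates_per_strength = 4))
  model <- plsr_calibrate(set, intervals = "500-1700, 2500-4000",
                          preprocess = "area_norm+snv", n_factors = 4)
  path <- withr::local_tempfile(fileext = ".json")
  plsr_to_json(model, path)
  back <- plsr_from_json(path)
  p1 <- predict(model, set)
  p2 <- predict(back, set)
  expect_identical(p1, p2)
  expect_equal(format(back$preprocess), "area_norm+snv")
})

test_that("tidy and glance summarize a fit the broom way", {
  set <- generate_set(synthetic_design("tablet", seed = 2,
                                       replicates_per_strength = 3))
  m <- plsr_calibrate(set, preprocess = "snv", n_factors = 3)
  td <- tidy(m)
  expect_named(td, c("wavenumber", "estimate"))
  expect_equal(nrow(td), length(wavenumbers(set)))
  gl <- glance(m)
  expect_equal(gl$n_factors, 3L)
  expect_equal(gl$nobs, n_spectra(set))
  expect_gt(gl$r2_model, 0.9)
})

test_that("calibration on default synthetic tablets reaches the expected regime", {
  for (seed in c(31, 32)) {
    set <- generate_set(synthetic_design("tablet", seed = seed))
    sp <- ks_split_by_stratum(set, 24)
    m <- plsr_calibrate(split_subset(set, sp, "calibration"),
                        intervals = "500-1700, 2500-4000",
                        preprocess = "area_norm+snv", max_factors = 10)
    val <- split_subset(set, sp, "validation")
    expect_gt(r2_model(m$fitted, m$y), 0.95)
    expect_gt(r2_pearson(predict(m, val), reference_values(val)), 0.90)
  }
})
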