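test_that("SNV matches its closed form and is affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50)
  expect_equal(mean(snv(x)), 0, tolerance = 1e-12)
  expect_equal(sd(snv(x)), 1, tolerance = 1e-12)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
  # affine invariance: snv(a x + b) = sign(a) snv(x)
  expect_equal(snv(3.7 * x + 2), snv(x), tolerance = 1e-10)
  expect_equal(snv(-2 * x + 1), -snv(x), tolerance = 1e-10)
  expect_error(snv(c(5, 5, 5)), class = "chemocal_degenerate_error")
  expect_error(snv(5), class = "chemocal_parameter_error")
})

test_that("area normalization divides by total absolute intensity", {
  expect_equal(area_normalize(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(area_normalize(c(-1, 1, 2)), c(-0.25, 0.25, 0.5))
  x <- rnorm(30)
  expect_equal(sum(abs(area_normalize(x))), 1, tolerance = 1e-12)
  expect_error(area_normalize(c(0, 0, 0)), class = "chemocal_degenerate_error")
})

test_that("SG derivatives reproduce polynomials exactly, edges included", {
  g <- 1:15
  x2 <- g^2
  expect_equal(sg_derivative(x2, g, 1, 2, 5), 2 * g, tolerance = 1e-10)
  expect_equal(sg_derivative(x2, g, 2, 2, 5), rep(2, 15), tolerance = 1e-10)
  lin <- 3 * g + 1
  expect_equal(sg_derivative(lin, g, 2, 2, 5), rep(0, 15), tolerance = 1e-10)
  # cubic under a cubic filter, wider window
  x3 <- g^3 - 2 * g
  expect_equal(sg_derivative(x3, g, 1, 3, 7), 3 * g^2 - 2, tolerance = 1e-8)

  # grid-spacing scaling: same samples on a 2 cm^-1 grid halve the slope
  g2 <- 2 * g
  expect_equal(sg_derivative(x2, g2, 1, 2, 5), g, tolerance = 1e-10)
})

test_that("SG derivative is linear and validates its parameters", {
  g <- seq(400, 600, by = 2)
  withr::with_seed(7, {
    x <- rnorm(length(g)); y <- rnorm(length(g))
  })
  lhs <- sg_derivative(2 * x - 3 * y, g, 1, 2, 11)
  rhs <- 2 * sg_derivative(x, g, 1, 2, 11) - 3 * sg_derivative(y, g, 1, 2, 11)
  expect_equal(lhs, rhs, tolerance = 1e-10)

  expect_error(sg_derivative(x, g, 1, 2, 10), class = "chemocal_parameter_error")
  expect_error(sg_derivative(x, g, 2, 1, 11), class = "chemocal_parameter_error")
  expect_error(sg_derivative(x[1:5], g[1:5], 1, 2, 11),
               class = "chemocal_parameter_error")
  expect_error(sg_derivative(x, g^1.5, 1, 2, 11), class = "chemocal_grid_error")
})

test_that("SG interior points agree with the signal package's filter", {
  skip_if_not_installed("signal")
  g <- seq(1000, 1200, by = 2)
  x <- withr::with_seed(11, rnorm(length(g)))
  for (params in list(c(1, 2, 11), c(2, 2, 11), c(1, 3, 21))) {
    d <- params[1]; p <- params[2]; m <- params[3]
    ours <- sg_derivative(x, g, d, p, m)
    ref <- signal::sgolayfilt(x, p = p, n = m, m = d) / (2^d)
    h <- (m - 1) / 2
    interior <- (h + 1):(length(x) - h)
    expect_equal(ours[interior], ref[interior], tolerance = 1e-8)
  }
})

test_that("recipe strings parse, format and compose in listed order", {
  spec <- preprocess_spec("snv+d1(poly=2,window=21)")
  expect_length(spec$steps, 2)
  expect_equal(spec$steps[[2]]$window_points, 21)
  expect_equal(format(spec), "snv+d1(poly=2,window=21)")
  expect_equal(format(preprocess_spec("original")), "original")
  expect_equal(format(preprocess_spec("d2")), "d2(poly=2,window=11)")
  expect_error(preprocess_spec("msc"), class = "chemocal_format_error")
  expect_error(preprocess_spec("d1(poly=2,window=2)"),
               class = "chemocal_parameter_error")

  s <- spectra_set(c(400, 500, 600), matrix(c(1, 1, 2), 1),
                   tibble::tibble(sample_id = "a", reference_mg = 5))
  # identity recipe
  expect_equal(absorbance_matrix(apply_pipeline(s, "original")),
               absorbance_matrix(s))
  # hand-composed area_norm then snv on [1,1,2]
  got <- drop(absorbance_matrix(apply_pipeline(s, "area_norm+snv")))
  expect_equal(got, snv(area_normalize(c(1, 1, 2))), ignore_attr = TRUE)
  expect_equal(got, c(-1, -1, 2) / sqrt(3), ignore_attr = TRUE,
               tolerance = 1e-12)
  # order matters: snv then area_norm differs
  alt <- drop(absorbance_matrix(apply_pipeline(s, "snv+area_norm")))
  expect_false(isTRUE(all.equal(got, alt)))
})

test_that("snv followed by an SG derivative matches the affine closed form", {
  g <- 1:9
  x <- g^2
  s <- spectra_set(400 + g, matrix(x, 1), tibble::tibble(sample_id = "a"))
  got <- drop(absorbance_matrix(apply_pipeline(s, "snv+d1(poly=2,window=5)")))
  # SNV is affine: derivative of (x - mean)/sd is (2w)/sd
  expect_equal(got, 2 * g / sd(x), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pipelines preserve bookkeeping and report the failing sample", {
  set <- tiny_set(n = 4)
  out <- apply_pipeline(set, "area_norm+snv")
  expect_equal(wavenumbers(out), wavenumbers(set))
  expect_equal(sample_info(out), sample_info(set))

  bad <- spectra_set(c(400, 500, 600), rbind(c(1, 2, 3), c(7, 7, 7)),
                     tibble::tibble(sample_id = c("good", "flat")))
  err <- tryCatch(apply_pipeline(bad, "snv"), condition = identity)
  expect_s3_class(err, "chemocal_degenerate_error")
  expect_match(conditionMessage(err), "flat")
})
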