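rand_spectra <- function(n = 6, p = 20, seed = 10) {
  matrix(withr::with_seed(seed, runif(n * p)), n, p)
}

test_that("trim_bands keeps an in-range grid intact and drops the edges", {
  tbl <- spectra_tbl(rand_spectra(3, 119), seq(400, 1000, length.out = 119),
                     y = c(1, 2, 3))
  expect_equal(trim_bands(tbl)$X, tbl$X)
  # an instrument-style grid at 2.8 nm spacing over 336.2-1092.5 nm
  wl <- seq(336.2, 1092.5, by = 2.8)
  tbl2 <- spectra_tbl(rand_spectra(3, length(wl), seed = 11), wl, y = c(1, 2, 3))
  kept <- trim_bands(tbl2)
  expect_true(all(kept$wavelengths >= 400 & kept$wavelengths <= 1000))
  expect_lt(ncol(kept$X), ncol(tbl2$X))
  expect_error(trim_bands(tbl2, 450.05, 450.06), "no bands")
  expect_error(trim_bands(tbl2, 700, 600), "smaller")
})

test_that("snv matches its closed form and standardizes every row", {
  expect_equal(snv(matrix(c(1, 2, 3), 1, 3)), matrix(c(-1, 0, 1), 1, 3))
  X <- rand_spectra()
  out <- snv(X)
  expect_equal(rowMeans(out), rep(0, nrow(X)))
  expect_equal(apply(out, 1, sd), rep(1, nrow(X)))
  expect_error(snv(rbind(X, 5)), "constant")
})

test_that("minmax rescales each row onto exactly [0, 1]", {
  expect_equal(minmax_normalize(matrix(c(2, 4, 6), 1, 3)),
               matrix(c(0, 0.5, 1), 1, 3))
  out <- minmax_normalize(rand_spectra())
  expect_equal(apply(out, 1, min), rep(0, 6))
  expect_equal(apply(out, 1, max), rep(1, 6))
  expect_error(minmax_normalize(matrix(1, 2, 4)), "constant")
})

test_that("snv and minmax are invariant to per-spectrum affine distortion", {
  X <- rand_spectra()
  a <- c(2, 0.5, 3, 1.5, 7, 0.1); b <- c(-1, 5, 0, 2, -3, 0.4)
  Xd <- X * a + b  # row-wise gain and offset
  expect_equal(snv(Xd), snv(X), tolerance = 1e-12)
  expect_equal(minmax_normalize(Xd), minmax_normalize(X), tolerance = 1e-12)
})

test_that("SG derivatives reproduce polynomials exactly, edges included", {
  i <- 1:25
  quad <- matrix(3 * i^2 - 2 * i + 1, 1)
  expect_equal(sg_derivative(quad, order = 2), matrix(6, 1, 25))
  expect_equal(sg_derivative(quad, order = 1), matrix(6 * i - 2, 1))
  line <- matrix(4 * i + 2, 1)
  expect_equal(sg_derivative(line, order = 1), matrix(4, 1, 25))
  expect_equal(sg_derivative(line, order = 2), matrix(0, 1, 25))
})

test_that("SG derivative equals a brute-force windowed polyfit oracle", {
  X <- rand_spectra(4, 30, seed = 12)
  oracle <- function(x, m, window = 7, polyorder = 2) {
    n <- length(x); h <- (window - 1) / 2
    vapply(seq_len(n), function(i) {
      win <- if (i <= h) 1:window
             else if (i > n - h) (n - window + 1):n
             else (i - h):(i + h)
      t_ <- win - i
      cf <- coef(lm(x[win] ~ t_ + I(t_^2)))
      if (m == 1) cf[2] else 2 * cf[3]
    }, numeric(1))
  }
  for (m in 1:2) {
    expected <- t(apply(X, 1, oracle, m = m))
    expect_equal(sg_derivative(X, order = m), expected, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("SG derivative is linear in its input", {
  x <- rand_spectra(1, 20, seed = 13)
  z <- rand_spectra(1, 20, seed = 14)
  expect_equal(sg_derivative(2.5 * x - 4 * z, order = 2),
               2.5 * sg_derivative(x, order = 2) - 4 * sg_derivative(z, order = 2),
               tolerance = 1e-12)
  expect_error(sg_derivative(x, order = 2, window = 6), "odd")
  expect_error(sg_derivative(x, order = 2, window = 3, polyorder = 3), "polyorder")
  expect_error(sg_derivative(x[, 1:5, drop = FALSE], order = 1), "bands")
})

test_that("SNV reduces within-class variance on scatter-corrupted spectra", {
  for (seed in c(21, 22)) {
    base <- stage_spectrum(scene_params(), stage = 2)
    n <- 12
    gains <- withr::with_seed(seed, 1 + runif(n, -0.15, 0.15))
    offsets <- withr::with_seed(seed + 100, runif(n, -0.05, 0.05))
    X <- outer(gains, base) + offsets
    v_raw <- mean(apply(X, 2, var))
    v_snv <- mean(apply(snv(X), 2, var))
    expect_lt(v_snv, v_raw)
  }
})

test_that("preprocess dispatches and tags the table", {
  tbl <- quick_table(3, seed = 55)
  for (m in c("none", "snv", "normalization", "d1", "d2")) {
    out <- preprocess(tbl, m)
    expect_identical(out$preprocessing, m)
    expect_identical(dim(out$X), dim(tbl$X))
  }
  expect_error(preprocess(tbl, "msc"))
})
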