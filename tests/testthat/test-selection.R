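test_that("UVE keeps an informative band and discards pure-noise bands", {
  n <- 40
  y <- rep(c(1L, 2L), each = n / 2)
  noise <- matrix(withr::with_seed(3, rnorm(n * 50)), n, 50)
  X <- cbind(as.numeric(y == 2), noise)
  tbl <- spectra_tbl(X, 400 + 2 * seq_len(51), y = y)
  res <- uve_select(tbl, n_lv = 2, seed = 7)
  expect_true(1L %in% res$indices)
  expect_lte(sum(res$indices > 1), 0.1 * 50)  # >= 90% of noise bands gone
  expect_equal(length(res$diagnostics$stability_noise), 51)  # 51 <-> 51 bands
})

test_that("UVE on pure noise retains almost nothing", {
  n <- 40
  y <- rep(1:5, each = 8)
  X <- matrix(withr::with_seed(4, runif(n * 60)), n, 60)
  tbl <- spectra_tbl(X, 400 + 3 * seq_len(60), y = y)
  res <- uve_select(tbl, n_lv = 3, seed = 8)
  expect_lte(length(res$indices), ceiling(0.05 * 60))
})

test_that("UVE stability is invariant to positive rescaling of the spectra", {
  tbl <- quick_table(4, seed = 80)
  a <- uve_select(tbl, n_lv = 3, seed = 9)
  tbl2 <- spectra_tbl(tbl$X * 7.3, tbl$wavelengths, y = tbl$y, ids = tbl$ids,
                      split = tbl$split)
  b <- uve_select(tbl2, n_lv = 3, seed = 9)
  expect_equal(a$diagnostics$stability, b$diagnostics$stability,
               tolerance = 1e-8)
  expect_identical(a$indices, b$indices)
})

test_that("SPA picks orthogonal columns in norm order and skips duplicates", {
  # orthogonal candidate columns with norms 3 > 2 > 1 (centred)
  base <- cbind(c(1, -1, 0, 0, 0, 0), c(0, 0, 1, -1, 0, 0), c(0, 0, 0, 0, 1, -1))
  X <- cbind(base[, 3] * 1, base[, 1] * 3, base[, 2] * 2) / sqrt(2)
  tbl <- spectra_tbl(X + 10, c(500, 600, 700), y = rep(1:2, 3))
  chain <- oleaspec:::spa_chain(scale(X, scale = FALSE), start = 2, k_max = 3)
  expect_equal(chain, c(2L, 3L, 1L))  # descending residual norm
  # an exact duplicate is never selected after its twin
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  chain_d <- suppressWarnings(oleaspec:::spa_chain(scale(Xd, scale = FALSE), 1, 3))
  expect_false(all(c(1, 2) %in% chain_d))
})

test_that("SPA chain equals a brute-force Gram-Schmidt oracle", {
  X <- matrix(withr::with_seed(5, rnorm(12 * 8)), 12, 8)
  Xc <- scale(X, scale = FALSE)
  gs_oracle <- function(Xc, start, k) {
    chosen <- start
    for (step in seq_len(k - 1)) {
      basis <- qr.Q(qr(Xc[, chosen, drop = FALSE]))
      resid_norm <- vapply(seq_len(ncol(Xc)), function(j) {
        r <- Xc[, j] - basis %*% crossprod(basis, Xc[, j])
        sqrt(sum(r^2))
      }, numeric(1))
      resid_norm[chosen] <- -1
      chosen <- c(chosen, which.max(resid_norm))
    }
    chosen
  }
  for (start in c(1, 4, 8)) {
    expect_equal(oleaspec:::spa_chain(Xc, start, 6), gs_oracle(Xc, start, 6))
  }
})

test_that("SPA selection order is invariant to candidate permutation", {
  tbl <- quick_table(4, seed = 81)
  cand <- c(5, 40, 80, 100, 17, 63)
  a <- spa_select(tbl, candidates = cand, k_max = 4)
  b <- spa_select(tbl, candidates = rev(cand), k_max = 4)
  expect_identical(a$indices, b$indices)
})

test_that("the synchronous spectrum matches a direct double-loop oracle", {
  M <- matrix(withr::with_seed(6, rnorm(35)), 5, 7)
  sync <- synchronous_2dcos(M)
  ref <- colMeans(M)
  oracle <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7)
    oracle[i, j] <- sum((M[, i] - ref[i]) * (M[, j] - ref[j])) / 4
  expect_equal(sync$phi, oracle, tolerance = 1e-12)
  # symmetric PSD with per-band dynamic variance on the diagonal
  expect_equal(sync$phi, t(sync$phi))
  expect_gte(min(eigen(sync$phi, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  expect_equal(diag(sync$phi), apply(M, 2, var), tolerance = 1e-12)
})

test_that("degenerate perturbation series give degenerate synchronous spectra", {
  flat <- matrix(0.4, 5, 6)
  expect_equal(max(abs(synchronous_2dcos(flat)$phi)), 0)
  one_band <- flat; one_band[, 3] <- 1:5
  phi <- synchronous_2dcos(one_band)$phi
  expect_equal(sum(phi != 0), 1)
  expect_gt(phi[3, 3], 0)
  expect_error(synchronous_2dcos(flat[1, , drop = FALSE]), "2 perturbation")
})

test_that("autopeaks find isolated diagonal bumps and skip monotone diagonals", {
  wl <- seq(400, 1000, length.out = 41)
  two_bumps <- exp(-(wl - 550)^2 / 800) + exp(-(wl - 850)^2 / 800)
  # build a diagonal matrix whose diagonal is the bump pattern
  sync <- structure(list(phi = diag(two_bumps), wavelengths = wl, m = 5),
                    class = "sync_spectrum")
  res <- autopeaks(sync)
  expect_equal(res$wavelengths, c(550, 850))
  sync$phi <- diag(seq(0, 1, length.out = 41))
  expect_length(autopeaks(sync)$indices, 0)
})

test_that("UVE+SPA composes the two stages and stays inside the UVE set", {
  tbl <- quick_table(5, seed = 82)
  uve <- uve_select(tbl, n_lv = 3, seed = 10)
  res <- uve_spa(tbl, n_lv = 3, seed = 10, k_max = 5)
  expect_true(all(res$indices %in% uve$indices))
  expect_lte(length(res$indices), length(uve$indices))
  expect_lte(length(uve$indices), ncol(tbl$X))
  # composition identity: equals SPA run on the UVE-retained candidates
  spa <- spa_select(tbl, candidates = uve$indices, k_max = 5)
  expect_identical(res$indices, spa$indices)
})

test_that("selection results serialize to JSON", {
  tbl <- quick_table(3, seed = 83)
  res <- loading_peaks(pca_fit(tbl, k = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$method, "pc_loadings")
  expect_equal(back$wavelengths_nm, res$wavelengths)
})
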