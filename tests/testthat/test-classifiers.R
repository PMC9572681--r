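test_that("PLS1 with one latent variable equals univariate least squares", {
  x <- withr::with_seed(1, rnorm(20))
  y <- 2 * x + withr::with_seed(2, rnorm(20, 0, 0.1))
  fit <- oleaspec:::pls1_nipals(matrix(x), y, 1)
  ls <- coef(lm(y ~ x))
  expect_equal(fit$coef[1, 1], ls[["x"]], tolerance = 1e-10)
  expect_equal(fit$intercept[1], ls[["(Intercept)"]], tolerance = 1e-10)
})

test_that("a linearly separable pair is classified perfectly at LV = 1", {
  tbl <- separable_table()
  fit <- plsda_fit(tbl, max_lv = 5, cv_folds = 6)
  expect_equal(fit$n_components, 1L)
  expect_equal(predict(fit, tbl$X), tbl$y)
  # cv curve attains zero and the fitted dimension sits at its minimum
  expect_equal(min(fit$cv_errors), 0)
  expect_equal(fit$n_components, which.min(fit$cv_errors))
})

test_that("argmax ties resolve to the lowest stage", {
  tbl <- separable_table()
  fit <- plsda_fit(tbl, max_lv = 3, cv_folds = 6)
  fake <- fit
  # force identical responses for classes 1 and 2 on any input
  fake$core$coef[] <- 0
  fake$core$intercept[, ] <- c(0.9, 0.9)
  expect_equal(predict(fake, tbl$X[1:3, ]), rep(1L, 3))
})

test_that("prediction is stateless and invariant to an all-zero band", {
  tbl <- separable_table()
  fit <- plsda_fit(tbl, max_lv = 4, cv_folds = 6)
  one <- predict(fit, tbl$X[5, , drop = FALSE])
  dup <- predict(fit, tbl$X[c(5, 5, 7), ])
  expect_equal(dup[1:2], rep(one, 2))
  # refit with an extra identically-zero band: responses unchanged
  tbl0 <- spectra_tbl(cbind(tbl$X, 0), c(tbl$wavelengths, 999), y = tbl$y)
  fit0 <- plsda_fit(tbl0, max_lv = 4, cv_folds = 6)
  expect_equal(predict(fit0, cbind(tbl$X, 0), type = "response"),
               predict(fit, tbl$X, type = "response"),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fits and predictions are deterministic given row order", {
  tbl <- quick_table(4, seed = 70)
  a <- plsda_fit(tbl, max_lv = 8)
  b <- plsda_fit(tbl, max_lv = 8)
  expect_identical(a$core$coef, b$core$coef)
  expect_identical(a$cv_errors, b$cv_errors)
})

test_that("venetian folds stride the calibration table by position", {
  expect_equal(oleaspec:::venetian_folds(12, 10),
               c(1:10, 1L, 2L))
})

test_that("PCA-DA separates well-separated spherical classes and matches an
          explicit pooled-covariance LDA oracle", {
  n <- 15
  mu <- rbind(c(0, 0, 0, 0), c(6, 0, 0, 0), c(0, 6, 0, 0))
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(withr::with_seed(k, rnorm(n * 4)), n, 4) + rep(mu[k, ], each = n)))
  y <- rep(1:3, each = n)
  tbl <- spectra_tbl(X, c(400, 500, 600, 700), y = y)
  fit <- pcada_fit(tbl, max_pc = 2, cv_folds = 5)
  expect_equal(predict(fit, mu), 1:3)
  # oracle: equal-prior LDA via the explicit pooled-covariance discriminant
  p <- fit$n_components
  scores <- sweep(X, 2, fit$center) %*% fit$rotation[, seq_len(p), drop = FALSE]
  mus <- do.call(rbind, lapply(1:3, function(k)
    colMeans(scores[y == k, , drop = FALSE])))
  Sp <- Reduce(`+`, lapply(1:3, function(k) {
    Z <- sweep(scores[y == k, , drop = FALSE], 2, mus[k, ])
    crossprod(Z)
  })) / (length(y) - 3)
  Si <- solve(Sp)
  delta <- scores %*% Si %*% t(mus) - rep(0.5 * diag(mus %*% Si %*% t(mus)),
                                          each = length(y))
  oracle <- max.col(delta, ties.method = "first")
  expect_equal(predict(fit, X), oracle)
})

test_that("cv_curve is consistent with the fitted dimension and attains zero
          on separable data", {
  tbl <- separable_table()
  cc <- cv_curve(tbl, "plsda", max_components = 5, cv_folds = 6)
  expect_equal(nrow(cc), 5)
  expect_equal(attr(cc, "chosen"), which.min(cc$errors))
  expect_equal(min(cc$errors), 0)
  cc1 <- cv_curve(tbl, "plsda", max_components = 1, cv_folds = 6)
  expect_equal(nrow(cc1), 1)
})

test_that("degenerate inputs are rejected", {
  tbl <- separable_table()
  one_class <- spectra_tbl(tbl$X[1:12, ], tbl$wavelengths, y = rep(1L, 12))
  expect_error(plsda_fit(one_class), "two classes")
  expect_error(plsda_fit(tbl, cv_folds = 100), "folds")
  fit <- plsda_fit(tbl, max_lv = 3, cv_folds = 6)
  expect_error(predict(fit, tbl$X[, 1:5]), "band count")
})

test_that("PLS-DA models survive a JSON save/load round trip", {
  tbl <- separable_table()
  fit <- plsda_fit(tbl, max_lv = 3, cv_folds = 6)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit, f)
  back <- load_model(f)
  expect_equal(predict(back, tbl$X), predict(fit, tbl$X))
  expect_equal(back$n_components, fit$n_components)
})

test_that("evaluation reports cover each calibration sample once in CV", {
  tbl <- quick_table(4, seed = 71)
  tp <- preprocess(tbl, "snv")
  fit <- plsda_fit(tp, max_lv = 8)
  ev <- evaluate_splits(fit, tp)
  expect_equal(ev$cross_validation$total, sum(tbl$split == "calibration"))
  expect_equal(ev$prediction$total, sum(tbl$split == "prediction"))
})
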