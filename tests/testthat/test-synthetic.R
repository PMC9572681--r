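test_that("clean scenes have exactly zero background after calibration", {
  p <- clean_params()
  sc <- generate_scene(p)
  cal <- calibrate(sc$raw, sc$white, sc$dark)
  bg <- !sc$truth_mask
  for (b in c(1, 60, 119))
    expect_equal(max(abs(cal$data[, , b][bg])), 0)
})

test_that("identical parameters and seed give bitwise-identical scenes", {
  p <- tiny_params(seed = 77L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth_mask, b$truth_mask)
  # and a different seed does not
  c_ <- generate_scene(tiny_params(seed = 78L))
  expect_false(identical(a$raw$data, c_$raw$data))
})

test_that("stage contrast at the 672 nm band matches the analytic model", {
  p1 <- clean_params(stage = 1)
  p5 <- clean_params(stage = 5)
  b <- which.min(abs(p1$wavelengths - 672))
  extract <- function(p) {
    sc <- generate_scene(p)
    cal <- calibrate(sc$raw, sc$white, sc$dark)
    mean_spectrum(cal, sc$truth_mask)[b]
  }
  # analytic oracle: evaluate the scene model at that band for both stages
  expected <- stage_spectrum(p5, stage = 5)[b] - stage_spectrum(p1, stage = 1)[b]
  expect_equal(extract(p5) - extract(p1), expected, tolerance = 1e-12)
  # the contrast is dominated by the configured 672 nm depth difference
  d <- p1$feature_depth_by_stage
  i672 <- which.min(abs(p1$feature_centers - 672))
  g <- exp(-(p1$wavelengths[b] - 672)^2 / (2 * p1$feature_sd[i672]^2))
  expect_equal(expected, (d[1, i672] - d[5, i672]) * g, tolerance = 1e-3)
})

test_that("calibration round-trips the noise-free scene exactly", {
  p <- clean_params(background_level = 0.03, stage = 3)
  sc <- generate_scene(p)
  cal <- calibrate(sc$raw, sc$white, sc$dark)
  expect_equal(cal$data, scene_reflectance(p)$data, tolerance = 1e-12)
})

test_that("generate_dataset counts, labels and truth table are consistent", {
  ds <- generate_dataset(2, tiny_params(), seed = 5, keep_cubes = FALSE)
  expect_length(ds$scenes, 10)
  expect_equal(vapply(ds$scenes, `[[`, integer(1), "stage"),
               rep(1:5, each = 2))
  expect_equal(ds$truth$y, rep(1:5, each = 2))
  expect_error(generate_dataset(0, tiny_params()), "n_per_stage")
})

test_that("without depth jitter or noise, within-stage spectra are identical", {
  p <- clean_params()
  tbl <- simulate_spectra(3, p, seed = 9, depth_jitter_sd = 0, geom_jitter = 0)
  for (s in 1:5) {
    rows <- which(tbl$y == s)
    expect_equal(tbl$X[rows[2], ], tbl$X[rows[1], ], tolerance = 1e-12)
    expect_equal(tbl$X[rows[3], ], tbl$X[rows[1], ], tolerance = 1e-12)
  }
})

test_that("streaming extraction equals dataset-then-extract", {
  p <- tiny_params()
  a <- simulate_spectra(2, p, seed = 31)
  ds <- generate_dataset(2, p, seed = 31)
  b <- extract_spectra(ds)
  expect_equal(a$X, b$X, tolerance = 1e-12)
  expect_identical(a$y, b$y)
})

test_that("widening inter-stage depth spacing never hurts calibration CCR", {
  base <- tiny_params()
  D <- base$feature_depth_by_stage
  ctr <- colMeans(D)
  # 'weak' = depth differences halved around the stage-mean; 'strong' = default
  weak <- sweep(sweep(D, 2, ctr) * 0.5, 2, ctr, `+`)
  run_ccr <- function(depths, seed) {
    p <- tiny_params(feature_depth_by_stage = depths)
    tbl <- quick_table(6, seed = seed, params = p)
    fit <- plsda_fit(preprocess(tbl, "snv"), max_lv = 10)
    ev <- evaluate_splits(fit, preprocess(tbl, "snv"))
    ev$calibration$overall_ccr
  }
  for (seed in c(101, 202)) {
    expect_gte(run_ccr(D, seed), run_ccr(weak, seed))
  }
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(wavelengths = c(500, 400, 600)), "increasing")
  expect_error(scene_params(n_rows = 20, n_cols = 20,
                            ellipse_axes = c(15, 15)), "fit")
  expect_error(scene_params(background_level = 0.2), "background_level")
  bad <- default_depths_nonmonotone <- scene_params()$feature_depth_by_stage
  bad[, 2] <- c(0.2, 0.1, 0.15, 0.1, 0.05)
  expect_error(scene_params(feature_depth_by_stage = bad), "monotone")
})

test_that("dataset export writes cubes, masks and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(1, tiny_params(), seed = 3)
  manifest <- write_dataset(ds, dir)
  man <- read.csv(manifest)
  expect_equal(nrow(man), 5)
  cube <- read_cube(file.path(dir, man$cube[1]))
  expect_equal(cube$data, ds$scenes[[1]]$raw$data, tolerance = 1e-12)
  expect_equal(read_mask_png(file.path(dir, man$mask[1])),
               matrix(as.logical(ds$scenes[[1]]$truth_mask), 24, 24))
})
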