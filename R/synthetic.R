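#' Parameters of a synthetic fruit scene
#'
#' Describes one simulated hyperspectral acquisition: an ellipsoidal bright
#' fruit on a dark background, imaged over a visible/near-infrared wavelength
#' grid.  The fruit's true reflectance is a smooth envelope (low in the
#' visible, rising sigmoidally to a near-infrared plateau) minus Gaussian
#' absorption dips at configurable feature centres.  Defaults place dips at
#' 416 nm (Soret band), 672 nm (chlorophyll), 862 nm (first O-H overtone)
#' and 979 nm (second O-H overtone of water/carbohydrate).  Each feature
#' follows its own depth-vs-stage profile (see
#' `default_feature_depths()` in the source): the 672 nm chlorophyll dip
#' decreases strictly with maturity and dominates, while the other features
#' trace curved, partly non-monotone trajectories so that the five class
#' means span a well-conditioned simplex — the multi-constituent geometry
#' ripening fruit actually exhibits.
#'
#' @param n_rows,n_cols scene size in pixels.
#' @param wavelengths band-centre wavelengths in nm, strictly increasing;
#'   default 119 evenly spaced points on 400-1000 nm.
#' @param stage ordinal maturity stage, 1 (least mature) to 5.
#' @param ellipse_center numeric length-2 (row, col) centre of the fruit, px.
#' @param ellipse_axes numeric length-2 (row, col) semi-axes, px; the
#'   ellipse must fit inside the frame.
#' @param background_level background reflectance fraction, in \[0, 0.05\].
#' @param feature_centers absorption feature centres, nm.
#' @param feature_sd Gaussian widths (sd, nm) of the features.
#' @param feature_depth_by_stage 5 x length(feature_centers) matrix of
#'   absorption depths (reflectance fraction); the column for the 672 nm
#'   feature must be strictly monotone across stages.
#' @param noise_sd per-pixel additive Gaussian noise, reflectance units.
#' @param scatter_slope,scatter_offset multiplicative / additive scatter
#'   magnitudes.  Each distortion has a scene-level component (illumination
#'   drift between acquisitions) and a per-pixel component (surface
#'   texture), both uniform on \[-1, 1\] and scaled by the coefficient.
#' @param seed integer RNG seed for the scene's noise and scatter draws.
#' @return A `scene_params` list, validated.
#' @export
scene_params <- function(n_rows = 48, n_cols = 48,
                         wavelengths = seq(400, 1000, length.out = 119),
                         stage = 1,
                         ellipse_center = c((n_rows + 1) / 2, (n_cols + 1) / 2),
                         ellipse_axes = c(13, 16),
                         background_level = 0.02,
                         feature_centers = c(416, 672, 862, 979),
                         feature_sd = c(12, 16, 20, 22),
                         feature_depth_by_stage = default_feature_depths(),
                         noise_sd = 0.02,
                         scatter_slope = 0.10,
                         scatter_offset = 0.02,
                         seed = 1L) {
  p <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            wavelengths = as.numeric(wavelengths), stage = as.integer(stage),
            ellipse_center = as.numeric(ellipse_center),
            ellipse_axes = as.numeric(ellipse_axes),
            background_level = background_level,
            feature_centers = as.numeric(feature_centers),
            feature_sd = as.numeric(feature_sd),
            feature_depth_by_stage = feature_depth_by_stage,
            noise_sd = noise_sd, scatter_slope = scatter_slope,
            scatter_offset = scatter_offset, seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
}

# Default absorption depths: rows = stages 1..5, cols = features.
# Each feature follows its own stage profile: 672 nm strictly decreasing
# (chlorophyll breakdown), 979 nm increasing with saturating curvature
# (water/carbohydrate accumulation), 862 nm non-monotone peaking mid-season
# (pericarp moisture), 416 nm convex decreasing (pigment decay).  The four
# profiles are chosen to be affinely independent so the five class means
# span a well-conditioned simplex in feature space: ripening changes several
# constituents at different rates, and intermediate stages carry their own
# signature rather than being interpolations of the extremes — the geometry
# a linear one-vs-rest classifier needs, and the regime the instrument
# studies it emulates operate in.
default_feature_depths <- function() {
  m <- cbind(`416` = c(0.145, 0.118, 0.100, 0.108, 0.085),
             `672` = c(0.20, 0.17, 0.14, 0.11, 0.08),
             `862` = c(0.010, 0.040, 0.052, 0.038, 0.012),
             `979` = c(0.040, 0.068, 0.056, 0.080, 0.088))
  rownames(m) <- paste0("S", 1:5)
  m
}

validate_scene_params <- function(p) {
  check_wavelengths(p$wavelengths)
  if (!p$stage %in% 1:5) stop("stage must be in 1..5", call. = FALSE)
  if (p$background_level < 0 || p$background_level > 0.05)
    stop("background_level must lie in [0, 0.05]", call. = FALSE)
  ctr <- p$ellipse_center; ax <- p$ellipse_axes
  if (any(ax <= 0) ||
      ctr[1] - ax[1] < 1 || ctr[1] + ax[1] > p$n_rows ||
      ctr[2] - ax[2] < 1 || ctr[2] + ax[2] > p$n_cols)
    stop("ellipse does not fit inside the frame", call. = FALSE)
  nf <- length(p$feature_centers)
  if (length(p$feature_sd) != nf ||
      !is.matrix(p$feature_depth_by_stage) ||
      nrow(p$feature_depth_by_stage) != 5 ||
      ncol(p$feature_depth_by_stage) != nf)
    stop("feature_depth_by_stage must be a 5 x n_features matrix matching feature_centers",
         call. = FALSE)
  i672 <- which.min(abs(p$feature_centers - 672))
  d <- diff(p$feature_depth_by_stage[, i672])
  if (!(all(d > 0) || all(d < 0)))
    stop("the 672 nm feature depth must be strictly monotone across stages",
         call. = FALSE)
  peak <- reflectance_envelope(p$wavelengths)
  if (any(peak < 0) || any(peak > 1.2))
    stop("reflectance envelope outside [0, 1.2]", call. = FALSE)
  p
}

# Smooth fruit reflectance envelope: low visible, sigmoid rise to NIR plateau.
reflectance_envelope <- function(wl) 0.22 + 0.45 / (1 + exp(-(wl - 700) / 20))

#' True (noise-free) stage spectrum of the scene model
#'
#' Evaluates the analytic reflectance model — envelope minus Gaussian
#' absorption dips — for one maturity stage.  This is the ground truth that
#' calibration + segmentation + mean-spectrum extraction should recover.
#'
#' @param params a [scene_params()] object.
#' @param stage maturity stage 1-5; defaults to `params$stage`.
#' @param depths optional depth vector overriding the stage's row of
#'   `feature_depth_by_stage` (used for per-sample depth jitter).
#' @return Numeric vector of reflectance fractions, one per band.
#' @export
stage_spectrum <- function(params, stage = params$stage, depths = NULL) {
  if (is.null(depths)) depths <- params$feature_depth_by_stage[stage, ]
  wl <- params$wavelengths
  r <- reflectance_envelope(wl)
  for (f in seq_along(params$feature_centers))
    r <- r - depths[f] *
      exp(-(wl - params$feature_centers[f])^2 / (2 * params$feature_sd[f]^2))
  pmax(r, 0)
}

# Logical foreground mask of the ellipse.
ellipse_mask <- function(params) {
  r <- matrix(seq_len(params$n_rows), params$n_rows, params$n_cols)
  c_ <- matrix(seq_len(params$n_cols), params$n_rows, params$n_cols, byrow = TRUE)
  ((r - params$ellipse_center[1]) / params$ellipse_axes[1])^2 +
    ((c_ - params$ellipse_center[2]) / params$ellipse_axes[2])^2 <= 1
}

#' Noise-free true reflectance cube of a scene
#'
#' The deterministic part of the scene model: `background_level` off the
#' ellipse, the stage spectrum on it, no scatter, no noise.  Used as the
#' round-trip oracle for calibration and segmentation.
#'
#' @inheritParams stage_spectrum
#' @param depths optional per-feature depth override.
#' @return A [hypercube] of reflectance fractions.
#' @export
scene_reflectance <- function(params, depths = NULL) {
  spec <- stage_spectrum(params, depths = depths)
  mask <- ellipse_mask(params)
  nb <- length(params$wavelengths)
  data <- array(params$background_level,
                c(params$n_rows, params$n_cols, nb))
  for (b in seq_len(nb)) {
    plane <- data[, , b]
    plane[mask] <- spec[b]
    data[, , b] <- plane
  }
  hypercube(data, params$wavelengths, list(stage = params$stage))
}

# Deterministic reference frames in raw-count units (16-bit-CCD-like scale).
# White: smooth per-band illumination shape; dark: constant sensor offset.
white_counts <- function(wl) 3500 * (0.75 + 0.25 * exp(-((wl - 720) / 260)^2))
dark_counts <- function(wl) rep(118.3, length(wl))

#' Generate one synthetic raw acquisition with references and ground truth
#'
#' Builds the true reflectance scene, corrupts it with multiplicative and
#' additive scatter plus per-pixel Gaussian noise, and embeds it in raw
#' sensor counts via `raw = dark + (white - dark) * R`, together with the
#' white and dark reference frames needed to calibrate it back.  Identical
#' parameters (including `seed`) give bitwise-identical output.
#'
#' @param params a [scene_params()] object.
#' @param depths optional per-feature depth override (per-sample jitter).
#' @return A `hsi_scene` list: `raw`, `white`, `dark` (hypercubes),
#'   `truth_mask` (logical matrix marking on-ellipse pixels), and `params`.
#' @export
generate_scene <- function(params, depths = NULL) {
  params <- validate_scene_params(params)
  truth <- scene_reflectance(params, depths = depths)
  mask <- ellipse_mask(params)
  d <- dim(truth$data)
  refl <- with_seed(params$seed, {
    g_scene <- runif(1, -1, 1); o_scene <- runif(1, -1, 1)
    u_pix <- array(runif(prod(d), -1, 1), d)
    v_pix <- array(runif(prod(d), -1, 1), d)
    noise <- if (params$noise_sd > 0) array(rnorm(prod(d), 0, params$noise_sd), d)
             else 0
    gain <- 1 + params$scatter_slope * (0.6 * g_scene + 0.4 * u_pix)
    offs <- params$scatter_offset * (0.6 * o_scene + 0.4 * v_pix)
    gain * truth$data + offs + noise
  })
  wl <- params$wavelengths
  w <- aperm(array(white_counts(wl), c(d[3], d[1], d[2])), c(2, 3, 1))
  dk <- aperm(array(dark_counts(wl), c(d[3], d[1], d[2])), c(2, 3, 1))
  raw <- dk + (w - dk) * refl
  structure(list(raw = hypercube(raw, wl, list(stage = params$stage)),
                 white = hypercube(w, wl),
                 dark = hypercube(dk, wl),
                 truth_mask = mask,
                 params = params),
            class = "hsi_scene")
}

#' Generate a labelled multi-scene dataset
#'
#' Produces `5 * n_per_stage` scenes (stages 1..5, in stage order) with
#' jittered ellipse geometry and per-sample random perturbation of the
#' absorption depths, sharing one white/dark reference pair.  The returned
#' truth table holds each sample's noise-free spectrum (evaluated at its
#' perturbed depths) for oracle checks.
#'
#' @param n_per_stage number of samples per maturity stage (>= 1).
#' @param params_base a [scene_params()] template; per-scene seed, stage and
#'   geometry are derived from it.
#' @param seed master seed governing all per-sample randomness.
#' @param depth_jitter_sd sd of the additive per-sample depth perturbation
#'   (reflectance units; depths are truncated at 0).
#' @param geom_jitter max ellipse-centre jitter in px (axes jitter is half).
#' @param keep_cubes if `FALSE`, raw cubes are dropped (only truth spectra
#'   and per-scene parameters are returned) — used by the streaming pipeline.
#' @return A `hsi_dataset` list: `scenes` (each with `raw`, `truth_mask`,
#'   `stage`, `id`, `params`, `depths`), shared `white`/`dark`, and `truth`
#'   (a [spectra_tbl] of noise-free per-sample spectra).
#' @export
generate_dataset <- function(n_per_stage, params_base = scene_params(),
                             seed = 1L, depth_jitter_sd = 0.005,
                             geom_jitter = 3, keep_cubes = TRUE) {
  if (n_per_stage < 1) stop("n_per_stage must be >= 1", call. = FALSE)
  n <- 5L * as.integer(n_per_stage)
  stages <- rep(1:5, each = n_per_stage)
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) list(
      seed = sample.int(.Machine$integer.max - 1L, 1L),
      dc = runif(2, -geom_jitter, geom_jitter),
      da = runif(2, -geom_jitter / 2, geom_jitter / 2),
      ddepth = rnorm(ncol(params_base$feature_depth_by_stage), 0,
                     depth_jitter_sd)))
  })
  ids <- sprintf("S%d_%03d", stages, sequence(rep(n_per_stage, 5)))
  scenes <- vector("list", n)
  truth_X <- matrix(NA_real_, n, length(params_base$wavelengths))
  white <- dark <- NULL
  for (i in seq_len(n)) {
    p <- params_base
    p$stage <- stages[i]
    p$seed <- draws[[i]]$seed
    p$ellipse_center <- p$ellipse_center + draws[[i]]$dc
    p$ellipse_axes <- pmax(p$ellipse_axes + draws[[i]]$da, 2)
    depths <- pmax(p$feature_depth_by_stage[stages[i], ] + draws[[i]]$ddepth, 0)
    sc <- generate_scene(p, depths = depths)
    truth_X[i, ] <- stage_spectrum(p, depths = depths)
    if (is.null(white)) { white <- sc$white; dark <- sc$dark }
    scenes[[i]] <- list(raw = if (keep_cubes) sc$raw else NULL,
                        truth_mask = sc$truth_mask, stage = stages[i],
                        id = ids[i], params = p, depths = depths)
  }
  truth <- spectra_tbl(truth_X, params_base$wavelengths, y = stages, ids = ids)
  structure(list(scenes = scenes, white = white, dark = dark, truth = truth),
            class = "hsi_dataset")
}

#' Simulate, calibrate, segment and extract spectra in one streaming pass
#'
#' Convenience wrapper running the acquisition-to-spectrum pipeline scene by
#' scene without holding all cubes in memory: generate raw scene, calibrate
#' against the white/dark references, band-math segmentation, mean-spectrum
#' extraction.  Deterministic per seed and identical to running
#' [generate_dataset()] followed by [extract_spectra()].
#'
#' @inheritParams generate_dataset
#' @param wl_high,wl_low band-math wavelengths (nm) for segmentation.
#' @param threshold reflectance threshold of the binary mask.
#' @return A [spectra_tbl] of extracted mean spectra with stage labels.
#' @export
simulate_spectra <- function(n_per_stage, params_base = scene_params(),
                             seed = 1L, depth_jitter_sd = 0.005,
                             geom_jitter = 3,
                             wl_high = 862, wl_low = 416, threshold = 0.1) {
  ds <- generate_dataset(n_per_stage, params_base, seed = seed,
                         depth_jitter_sd = depth_jitter_sd,
                         geom_jitter = geom_jitter, keep_cubes = FALSE)
  n <- length(ds$scenes)
  X <- matrix(NA_real_, n, length(params_base$wavelengths))
  for (i in seq_len(n)) {
    sc <- generate_scene(ds$scenes[[i]]$params, depths = ds$scenes[[i]]$depths)
    X[i, ] <- extract_one(sc$raw, ds$white, ds$dark, wl_high, wl_low, threshold)
  }
  spectra_tbl(X, params_base$wavelengths,
              y = vapply(ds$scenes, `[[`, integer(1), "stage"),
              ids = vapply(ds$scenes, `[[`, character(1), "id"))
}

#' Extract mean spectra from a generated dataset
#'
#' Calibrates each scene's raw cube with the dataset's shared references,
#' segments it by band math + thresholding, and extracts the foreground
#' mean spectrum.
#'
#' @param dataset a `hsi_dataset` from [generate_dataset()] (with cubes).
#' @inheritParams simulate_spectra
#' @return A [spectra_tbl].
#' @export
extract_spectra <- function(dataset, wl_high = 862, wl_low = 416,
                            threshold = 0.1) {
  stopifnot(inherits(dataset, "hsi_dataset"))
  if (is.null(dataset$scenes[[1]]$raw))
    stop("dataset was generated with keep_cubes = FALSE", call. = FALSE)
  X <- t(vapply(dataset$scenes, function(sc)
    extract_one(sc$raw, dataset$white, dataset$dark, wl_high, wl_low, threshold),
    numeric(length(dataset$white$wavelengths))))
  spectra_tbl(X, dataset$white$wavelengths,
              y = vapply(dataset$scenes, `[[`, integer(1), "stage"),
              ids = vapply(dataset$scenes, `[[`, character(1), "id"))
}

# calibrate -> band math -> threshold -> mean spectrum, for one scene
extract_one <- function(raw, white, dark, wl_high, wl_low, threshold) {
  cal <- calibrate(raw, white, dark)
  mask <- threshold_mask(band_math(cal, wl_high, wl_low), threshold)
  mean_spectrum(cal, mask)
}

#' Export a generated dataset to disk
#'
#' Writes each scene as an ENVI header/binary pair, its truth mask as PNG,
#' the shared white/dark references, and a CSV manifest
#' (`sample_id, stage, cube, mask, seed`).
#'
#' @param dataset a `hsi_dataset` with cubes.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "hsi_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cube(dataset$white, file.path(dir, "white.img"))
  write_cube(dataset$dark, file.path(dir, "dark.img"))
  rows <- lapply(dataset$scenes, function(sc) {
    if (is.null(sc$raw)) stop("dataset has no cubes", call. = FALSE)
    cube_path <- file.path(dir, paste0(sc$id, ".img"))
    mask_path <- file.path(dir, paste0(sc$id, "_mask.png"))
    write_cube(sc$raw, cube_path)
    write_mask_png(sc$truth_mask, mask_path)
    data.frame(sample_id = sc$id, stage = sc$stage, cube = basename(cube_path),
               mask = basename(mask_path), seed = sc$params$seed)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
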