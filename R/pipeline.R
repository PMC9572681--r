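#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end study in one validated list:
#' synthetic-data source, split, cross-validation and model dimensions.
#'
#' @param n_per_stage samples per maturity stage.
#' @param params_base a [scene_params()] template for the generator.
#' @param seed master seed governing scene generation and the random split.
#' @param split_ratio calibration fraction (default 0.75, a 3:1 split).
#' @param cv_folds Venetian-blinds folds (default 10).
#' @param max_components dimension cap for both classifiers (default 20).
#' @param selection_preprocessing pre-treatment the wavelength selectors
#'   and simplified models run on (default `"d2"`, the 2nd derivative).
#' @param depth_jitter_sd,geom_jitter forwarded to [generate_dataset()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_stage = 40, params_base = scene_params(),
                            seed = 1L, split_ratio = 0.75, cv_folds = 10,
                            max_components = 20,
                            selection_preprocessing = "d2",
                            depth_jitter_sd = 0.005, geom_jitter = 3) {
  stopifnot(n_per_stage >= 1, split_ratio > 0, split_ratio < 1)
  selection_preprocessing <-
    match.arg(selection_preprocessing, c("none", "snv", "normalization", "d1", "d2"))
  structure(list(n_per_stage = n_per_stage, params_base = params_base,
                 seed = as.integer(seed), split_ratio = split_ratio,
                 cv_folds = cv_folds, max_components = max_components,
                 selection_preprocessing = selection_preprocessing,
                 depth_jitter_sd = depth_jitter_sd, geom_jitter = geom_jitter),
            class = "pipeline_config")
}

# simulate + trim + split: the table every comparison starts from
pipeline_table <- function(config) {
  tbl <- simulate_spectra(config$n_per_stage, config$params_base,
                          seed = config$seed,
                          depth_jitter_sd = config$depth_jitter_sd,
                          geom_jitter = config$geom_jitter)
  tbl <- trim_bands(tbl, 400, 1000)
  assign_split(tbl, ratio = config$split_ratio, seed = config$seed + 1L)
}

#' Full-spectrum model x preprocessing comparison
#'
#' Runs the 2 x 5 grid — PLS-DA and PCA-DA under each pre-treatment (none,
#' SNV, max-min normalization, 1st and 2nd Savitzky-Golay derivative) — on
#' one shared synthetic dataset and split, and tabulates calibration,
#' cross-validation and prediction CCRs with the chosen model dimension.
#' Deterministic per seed.
#'
#' @param config a [pipeline_config()].
#' @param table optional pre-built, split [spectra_tbl] to use instead of
#'   simulating one (e.g. spectra extracted from real cubes).
#' @return A [tibble::tibble] with one row per model x preprocessing:
#'   `model`, `preprocessing`, `n_components`, `ccr_calibration`, `ccr_cv`,
#'   `ccr_prediction`.
#' @export
run_full_comparison <- function(config = pipeline_config(), table = NULL) {
  if (is.null(table)) table <- pipeline_table(config)
  methods <- c("none", "snv", "normalization", "d1", "d2")
  rows <- list()
  for (model in c("plsda", "pcada")) {
    for (m in methods) {
      tp <- preprocess(table, m)
      fit <- if (model == "plsda")
        plsda_fit(tp, max_lv = config$max_components,
                  cv_folds = config$cv_folds)
      else
        pcada_fit(tp, max_pc = config$max_components,
                  cv_folds = config$cv_folds)
      ev <- evaluate_splits(fit, tp)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = model, preprocessing = m, n_components = fit$n_components,
        ccr_calibration = ev$calibration$overall_ccr,
        ccr_cv = ev$cross_validation$overall_ccr,
        ccr_prediction = ev$prediction$overall_ccr)
    }
  }
  do.call(rbind, rows)
}

#' Simplified models on selected wavelengths
#'
#' Applies each wavelength-selection method — PC loading peaks, synchronous
#' 2D-COS autopeaks, and UVE+SPA — to the (by default 2nd-derivative
#' preprocessed) calibration split, refits a PLS-DA model on the selected
#' bands only, and tabulates its CCRs next to the full-spectrum reference
#' row.  Selection never sees prediction-split rows.
#'
#' @inheritParams run_full_comparison
#' @param methods subset of `c("full", "pc_loadings", "2dcos", "uve_spa")`.
#' @return A list with `table` (a tibble: `method`, `n_wavelengths`,
#'   `n_components`, three CCR columns) and `selections` (the
#'   [selection_result] objects).
#' @export
run_selection_comparison <- function(config = pipeline_config(), table = NULL,
                                     methods = c("full", "pc_loadings",
                                                 "2dcos", "uve_spa")) {
  if (is.null(table)) table <- pipeline_table(config)
  tp <- preprocess(table, config$selection_preprocessing)
  cal <- split_rows(tp, "calibration")
  selections <- list()
  rows <- list()
  for (m in methods) {
    sel <- switch(m,
      full = selection_result("full", seq_along(tp$wavelengths),
                              tp$wavelengths),
      pc_loadings = loading_peaks(pca_fit(tp[cal, ], k = 3)),
      `2dcos` = autopeaks(synchronous_2dcos(stage_means(tp),
                                            tp$wavelengths)),
      uve_spa = uve_spa(tp, seed = config$seed + 2L,
                        cv_folds = config$cv_folds),
      stop("unknown selection method: ", m, call. = FALSE))
    selections[[m]] <- sel
    if (length(sel$indices) < 1) {
      rows[[m]] <- tibble::tibble(method = m, n_wavelengths = 0L,
                                  n_components = NA_integer_,
                                  ccr_calibration = NA_real_,
                                  ccr_cv = NA_real_, ccr_prediction = NA_real_)
      next
    }
    sub <- select_bands(tp, sel$indices)
    fit <- plsda_fit(sub, max_lv = min(config$max_components,
                                       length(sel$indices)),
                     cv_folds = config$cv_folds)
    ev <- evaluate_splits(fit, sub)
    rows[[m]] <- tibble::tibble(
      method = m, n_wavelengths = length(sel$indices),
      n_components = fit$n_components,
      ccr_calibration = ev$calibration$overall_ccr,
      ccr_cv = ev$cross_validation$overall_ccr,
      ccr_prediction = ev$prediction$overall_ccr)
  }
  list(table = do.call(rbind, rows), selections = selections)
}
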