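# Small-scene parameter sets shared across tests.  Tiny frames keep the
# per-test simulations fast while exercising the full pipeline.

tiny_params <- function(...) {
  scene_params(n_rows = 24, n_cols = 24, ellipse_axes = c(6, 8), ...)
}

# A quiet tiny scene: no noise, no scatter, black background.
clean_params <- function(background_level = 0, ...) {
  tiny_params(noise_sd = 0, scatter_slope = 0, scatter_offset = 0,
              background_level = background_level, ...)
}

# Extracted spectra from a small simulated dataset, trimmed and split.
quick_table <- function(n_per_stage = 6, seed = 42, params = tiny_params(),
                        depth_jitter_sd = 0.005, geom_jitter = 1) {
  tbl <- simulate_spectra(n_per_stage, params, seed = seed,
                          depth_jitter_sd = depth_jitter_sd,
                          geom_jitter = geom_jitter)
  assign_split(trim_bands(tbl), seed = seed + 1L)
}

# A linearly separable two-class table: class 2 offset by a large constant
# in a single band.  Deterministic.
separable_table <- function(n_per_class = 12, n_bands = 10) {
  y <- rep(c(1L, 2L), each = n_per_class)
  X <- matrix(withr::with_seed(1, rnorm(2 * n_per_class * n_bands, 0, 0.01)),
              2 * n_per_class, n_bands)
  X[y == 2L, 4] <- X[y == 2L, 4] + 5
  spectra_tbl(X, 400 + 5 * seq_len(n_bands), y = y)
}

path_published_confusion <- function() {
  system.file("extdata", "prediction_confusion_published.csv",
              package = "oleaspec", mustWork = TRUE)
}
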