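#' Principal component analysis of spectra
#'
#' Mean-centred (unscaled) PCA of the spectra matrix.  Loadings are sign-
#' canonicalized so that each component's largest-magnitude element is
#' positive, making results deterministic across platforms.
#'
#' @param table a [spectra_tbl] (all rows are used; subset beforehand to fit
#'   on a split).
#' @param k number of components to retain,
#'   `k <= min(n_samples - 1, n_bands)`.
#' @return An `hsi_pca` object: `loadings` (bands x k, orthonormal columns),
#'   `explained_pct` (per-PC % of total variance, non-increasing, summing to
#'   100 over all possible PCs), `center` (mean spectrum), `k`,
#'   `wavelengths`.
#' @export
pca_fit <- function(table, k = 3) {
  stopifnot(inherits(table, "spectra_tbl"))
  X <- table$X
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax)
    stop(sprintf("k = %d exceeds min(n - 1, bands) = %d", k, kmax), call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign canonicalization: largest-|.| element of each loading positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  structure(list(loadings = load,
                 explained_pct = 100 * ev / sum(ev),
                 center = pc$center, k = k,
                 wavelengths = table$wavelengths),
            class = "hsi_pca")
}

#' @export
print.hsi_pca <- function(x, ...) {
  cat(sprintf("<hsi_pca> %d components over %d bands\n",
              x$k, nrow(x$loadings)))
  cat("  explained %:",
      paste(sprintf("%.2f", x$explained_pct[seq_len(x$k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Project spectra onto fitted principal components
#'
#' @param model an `hsi_pca` from [pca_fit()].
#' @param X numeric matrix with the model's band count.
#' @return `n x k` score matrix (`centered X %*% loadings`).
#' @export
pca_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$loadings))
    stop("band count does not match the fitted model", call. = FALSE)
  sweep(X, 2, model$center) %*% model$loadings
}

#' Principal-component score image of a hypercube
#'
#' Projects every foreground pixel's spectrum onto one loading vector,
#' rendering background pixels as a sentinel value.
#'
#' @param model an `hsi_pca`.
#' @param cube a [hypercube] whose band count matches the model.
#' @param mask logical foreground mask.
#' @param pc_index which component, `1..k`.
#' @param sentinel value painted on background pixels (default `NA`).
#' @return Numeric matrix (rows x cols).
#' @export
score_image <- function(model, cube, mask, pc_index = 1, sentinel = NA_real_) {
  stopifnot(inherits(cube, "hypercube"))
  if (pc_index > model$k) stop("pc_index exceeds fitted components", call. = FALSE)
  d <- dim(cube$data)
  if (d[3] != nrow(model$loadings))
    stop("cube band count does not match the fitted model", call. = FALSE)
  img <- matrix(sentinel, d[1], d[2])
  idx <- which(as.logical(mask))
  if (length(idx)) {
    flat <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
    img[idx] <- pca_scores(model, flat)[, pc_index]
  }
  img
}

#' Wavelengths at the extrema of PC loading lines
#'
#' Finds the pronounced peaks and valleys of the first `n_pcs` loading
#' lines: local maxima of each line and of its negation, kept when their
#' topographic prominence reaches `min_prominence` times that line's range.
#' Wavelengths picked by several components are merged once.
#'
#' @param model an `hsi_pca`.
#' @param n_pcs how many leading components to scan (default 3).
#' @param min_prominence prominence threshold as a fraction of each loading
#'   line's range (default 0.1).
#' @return A [selection_result] with method `"pc_loadings"`.
#' @export
loading_peaks <- function(model, n_pcs = 3, min_prominence = 0.1) {
  if (n_pcs > model$k) stop("n_pcs exceeds fitted components", call. = FALSE)
  idx <- integer(0)
  for (j in seq_len(n_pcs)) {
    v <- model$loadings[, j]
    prom <- min_prominence * diff(range(v))
    idx <- c(idx, find_peaks(v, prom), find_peaks(-v, prom))
  }
  idx <- sort(unique(idx))
  selection_result("pc_loadings", idx, model$wavelengths,
                   diagnostics = list(n_pcs = n_pcs,
                                      min_prominence = min_prominence))
}
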