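#' Uninformative variable elimination (UVE)
#'
#' Appends artificial random variables (uniform noise scaled to be
#' numerically negligible, x 1e-10) to the calibration spectra — by default
#' as many as there are real bands — then fits resampled PLS1 submodels of
#' the class-indicator matrix (one model per class, Monte-Carlo subsets by
#' default) and measures each variable's reliability as the stability
#' `s = mean(b) / sd(b)` of its regression coefficient over the submodels,
#' computed per class; a variable's stability is its largest magnitude over
#' the classes.  Real variables whose stability does not exceed the cutoff
#' derived from the artificial block (its maximum |s| by default, or a
#' quantile) are eliminated.
#'
#' Stability is invariant to positive rescaling of the spectra.
#'
#' @param table a [spectra_tbl] with labels; only the calibration split is
#'   used.
#' @param n_noise number of artificial variables (default: the number of
#'   real bands).
#' @param n_lv latent variables of the PLS1 submodels; by default the
#'   dimension chosen by [plsda_fit()]'s own cross-validation on this table.
#' @param cutoff_rule `"max"` (default): cutoff = max |s| over the
#'   artificial variables; `"quantile"`: the `cutoff_quantile` quantile.
#' @param cutoff_quantile quantile used when `cutoff_rule = "quantile"`.
#' @param scheme resampling scheme for the submodels: `"mc"` (Monte-Carlo,
#'   `n_sub` random 80% subsets, default) or `"loo"` (leave-one-out).
#'   Monte-Carlo is the default because leave-one-out perturbs the fit too
#'   little on calibration sets of a few hundred samples for the stability
#'   ratio to separate real from artificial variables.
#' @param n_sub number of Monte-Carlo submodels.
#' @param seed RNG seed for the artificial variables (and MC subsets).
#' @return A [selection_result] with method `"uve"`; diagnostics hold the
#'   per-variable stability (real and artificial blocks) and the cutoff.
#' @export
uve_select <- function(table, n_noise = NULL, n_lv = NULL,
                       cutoff_rule = c("max", "quantile"),
                       cutoff_quantile = 0.99,
                       scheme = c("mc", "loo"), n_sub = 100, seed = 1L) {
  stopifnot(inherits(table, "spectra_tbl"))
  cutoff_rule <- match.arg(cutoff_rule)
  scheme <- match.arg(scheme)
  cal <- split_rows(table, "calibration")
  X <- table$X[cal, , drop = FALSE]
  y <- table$y[cal]
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 calibration samples", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("labels are constant", call. = FALSE)
  if (is.null(n_noise)) n_noise <- p
  if (is.null(n_lv))
    n_lv <- plsda_fit(table, max_lv = 10)$n_components
  noise <- with_seed(seed, matrix(runif(n * n_noise), n, n_noise)) * 1e-10
  Xa <- cbind(X, noise)
  n_lv <- min(n_lv, n - 2L, ncol(Xa))
  subsets <- switch(scheme,
    loo = lapply(seq_len(n), function(i) seq_len(n)[-i]),
    mc = with_seed(seed + 1L, lapply(seq_len(n_sub), function(i)
      sample(n, max(3, round(0.8 * n))))))
  K <- length(classes)
  B <- array(NA_real_, c(length(subsets), ncol(Xa), K))
  for (i in seq_along(subsets)) {
    ix <- subsets[[i]]
    for (k in seq_len(K)) {
      fit <- pls1_nipals(Xa[ix, , drop = FALSE],
                         as.numeric(y[ix] == classes[k]), n_lv)
      B[i, , k] <- fit$coef[, ncol(fit$coef)]
    }
  }
  s_jc <- apply(B, c(2, 3), mean) / apply(B, c(2, 3), sd)
  s_jc[!is.finite(s_jc)] <- 0
  stab <- apply(abs(s_jc), 1, max)
  stab_real <- stab[seq_len(p)]
  stab_noise <- stab[seq.int(p + 1L, p + n_noise)]
  cutoff <- switch(cutoff_rule,
    max = max(stab_noise),
    quantile = as.numeric(stats::quantile(stab_noise, cutoff_quantile)))
  keep <- which(stab_real > cutoff)
  selection_result("uve", keep, table$wavelengths,
                   diagnostics = list(stability = stab_real,
                                      stability_noise = stab_noise,
                                      cutoff = cutoff, n_lv = n_lv,
                                      scheme = scheme))
}

#' Successive projections algorithm (SPA)
#'
#' Greedy forward selection minimizing collinearity: starting from each
#' candidate band in turn, the chain repeatedly adds the candidate whose
#' (mean-centred, over calibration samples) column has the largest norm
#' after projection onto the orthogonal complement of the span of the
#' columns already chosen — ties broken toward the lowest band index.  Each
#' chain prefix of length `k <= k_max` is scored by the Venetian-blinds
#' cross-validated RMSE of a PLS-DA model restricted to those bands
#' (root-mean-square error over the class-indicator responses), and the
#' `(start, k)` pair with the smallest RMSE wins (ties: smaller `k`, then
#' lower starting band).
#'
#' @param table a [spectra_tbl] with labels; calibration split only.
#' @param candidates candidate band indices (default: all bands).
#' @param k_max longest chain tried (default `min(10, #candidates)`).
#' @param n_lv_inner latent-variable cap of the scoring PLS-DA
#'   (`min(k, n_lv_inner)` is used at chain length `k`).
#' @param cv_folds folds of the scoring cross-validation.
#' @return A [selection_result] with method `"spa"`; diagnostics hold the
#'   winning chain in selection order, its RMSE-vs-k curve, and the start.
#' @export
spa_select <- function(table, candidates = NULL, k_max = NULL,
                       n_lv_inner = 10, cv_folds = 10) {
  stopifnot(inherits(table, "spectra_tbl"))
  cal <- split_rows(table, "calibration")
  X <- table$X[cal, , drop = FALSE]
  y <- table$y[cal]
  if (is.null(candidates)) candidates <- seq_len(ncol(X))
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("no candidate bands", call. = FALSE)
  if (is.null(k_max)) k_max <- min(10L, length(candidates))
  if (k_max > length(candidates))
    stop("k_max exceeds the number of candidates", call. = FALSE)
  Xc <- scale(X[, candidates, drop = FALSE], center = TRUE, scale = FALSE)
  classes <- sort(unique(y))
  ind <- outer(y, classes, `==`) * 1
  folds <- venetian_folds(nrow(X), min(cv_folds, nrow(X)))
  best <- list(rmse = Inf, k = NA_integer_, start = NA_integer_, chain = NULL,
               curve = NULL)
  for (s in seq_along(candidates)) {
    chain <- spa_chain(Xc, start = s, k_max = k_max)
    curve <- vapply(seq_along(chain), function(k) {
      bands <- candidates[chain[seq_len(k)]]
      cv_rmse_plsda(X[, bands, drop = FALSE], y, classes, ind, folds,
                    n_lv = min(k, n_lv_inner))
    }, numeric(1))
    k_best <- which.min(curve)  # ties -> smaller k
    better <- curve[k_best] < best$rmse - 1e-12 ||
      (abs(curve[k_best] - best$rmse) <= 1e-12 &&
         (is.na(best$k) || k_best < best$k))
    if (better) {
      best <- list(rmse = curve[k_best], k = k_best, start = candidates[s],
                   chain = candidates[chain], curve = curve)
    }
  }
  sel <- best$chain[seq_len(best$k)]
  selection_result("spa", sel, table$wavelengths,
                   diagnostics = list(chain = best$chain,
                                      rmse_curve = best$curve,
                                      k = best$k, start = best$start,
                                      rmse = best$rmse))
}

# SPA projection chain: indices into the columns of Xc.
# Residual columns are updated by projecting out each newly selected column.
spa_chain <- function(Xc, start, k_max, tol = 1e-10) {
  p <- ncol(Xc)
  R <- Xc
  chain <- integer(0)
  current <- start
  scale0 <- max(sqrt(colSums(Xc^2)), 1)
  for (step in seq_len(k_max)) {
    chain <- c(chain, current)
    if (length(chain) == k_max) break
    q <- R[, current]
    nq <- sqrt(sum(q^2))
    if (nq < tol * scale0) break  # rank-deficient span reached
    q <- q / nq
    R <- R - q %*% crossprod(q, R)
    nrm <- sqrt(colSums(R^2))
    nrm[chain] <- -1
    mx <- max(nrm)
    if (mx < tol * scale0) {
      warning("candidate span exhausted before k_max; chain truncated",
              call. = FALSE)
      break
    }
    current <- which(nrm >= mx - tol * mx)[1]  # ties -> lowest index
  }
  chain
}

# CV RMSE of indicator-response PLS-DA on a fixed band subset
cv_rmse_plsda <- function(X, y, classes, ind, folds, n_lv) {
  sq <- 0
  for (f in unique(folds)) {
    tr <- folds != f; va <- !tr
    n_lv_f <- max(1L, min(n_lv, sum(tr) - 1L, ncol(X)))
    core <- plsda_core_fit(X[tr, , drop = FALSE], y[tr], classes, n_lv_f)
    resp <- plsda_core_response(core, X[va, , drop = FALSE], n_lv_f)
    sq <- sq + sum((ind[va, , drop = FALSE] - resp)^2)
  }
  sqrt(sq / length(ind))
}

#' UVE followed by SPA
#'
#' Runs [uve_select()] to discard uninformative bands, then [spa_select()]
#' with the retained bands as candidates.  The final selection is always a
#' subset of the UVE-retained set.
#'
#' @inheritParams uve_select
#' @param k_max,n_lv_inner,cv_folds passed to [spa_select()].
#' @return A [selection_result] with method `"uve_spa"`; diagnostics embed
#'   both stages' diagnostics.
#' @export
uve_spa <- function(table, n_noise = NULL, n_lv = NULL,
                    cutoff_rule = c("max", "quantile"),
                    cutoff_quantile = 0.99, scheme = c("mc", "loo"),
                    n_sub = 100, seed = 1L,
                    k_max = NULL, n_lv_inner = 10, cv_folds = 10) {
  uve <- uve_select(table, n_noise = n_noise, n_lv = n_lv,
                    cutoff_rule = cutoff_rule,
                    cutoff_quantile = cutoff_quantile,
                    scheme = scheme, n_sub = n_sub, seed = seed)
  if (length(uve$indices) < 2)
    stop("UVE retained fewer than 2 bands; relax the cutoff (try cutoff_rule = \"quantile\")",
         call. = FALSE)
  if (!is.null(k_max)) k_max <- min(k_max, length(uve$indices))
  spa <- spa_select(table, candidates = uve$indices, k_max = k_max,
                    n_lv_inner = n_lv_inner, cv_folds = cv_folds)
  selection_result("uve_spa", spa$indices, table$wavelengths,
                   diagnostics = list(uve = uve$diagnostics,
                                      spa = spa$diagnostics,
                                      uve_retained = uve$indices))
}

#' Synchronous two-dimensional correlation spectrum
#'
#' Treats the ordered stage-mean spectra as a perturbation series (maturity
#' S1 to S5 as the external perturbation), forms the dynamic spectra by
#' subtracting the perturbation-mean reference spectrum, and returns the
#' synchronous correlation matrix `t(Ytilde) %*% Ytilde / (m - 1)` —
#' symmetric, positive semidefinite, with per-band dynamic variance on the
#' diagonal.
#'
#' @param stage_means numeric matrix, one row per perturbation point
#'   (stage), ordered; columns are bands.  At least two rows.
#' @param wavelengths optional wavelength vector for the bands.
#' @return A `sync_spectrum` object: `phi` (bands x bands), `wavelengths`,
#'   `m` (number of perturbation points).
#' @export
synchronous_2dcos <- function(stage_means, wavelengths = NULL) {
  Y <- as.matrix(stage_means)
  m <- nrow(Y)
  if (m < 2) stop("need at least 2 perturbation points", call. = FALSE)
  Yt <- sweep(Y, 2, colMeans(Y))
  phi <- crossprod(Yt) / (m - 1)
  structure(list(phi = phi,
                 wavelengths = if (is.null(wavelengths))
                   seq_len(ncol(Y)) else as.numeric(wavelengths),
                 m = m),
            class = "sync_spectrum")
}

#' @export
print.sync_spectrum <- function(x, ...) {
  cat(sprintf("<sync_spectrum> %d x %d synchronous matrix over %d perturbation points\n",
              nrow(x$phi), ncol(x$phi), x$m))
  invisible(x)
}

#' Write the synchronous matrix as CSV
#'
#' @param x a `sync_spectrum`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sync_csv <- function(x, path) {
  m <- x$phi
  dimnames(m) <- list(sprintf("wl_%.1f", x$wavelengths),
                      sprintf("wl_%.1f", x$wavelengths))
  write.csv(m, path)
  invisible(path)
}

#' Autopeaks of a synchronous 2D correlation spectrum
#'
#' Local maxima of the synchronous matrix diagonal (the per-band dynamic
#' variance) passing a prominence filter, i.e. the bands most sensitive to
#' the perturbation.
#'
#' @param sync a `sync_spectrum` from [synchronous_2dcos()].
#' @param min_prominence prominence threshold as a fraction of the
#'   diagonal's range (default 0.05).
#' @return A [selection_result] with method `"2dcos"`.
#' @export
autopeaks <- function(sync, min_prominence = 0.05) {
  stopifnot(inherits(sync, "sync_spectrum"))
  d <- diag(sync$phi)
  rng <- diff(range(d))
  idx <- if (rng > 0) find_peaks(d, min_prominence * rng) else integer(0)
  selection_result("2dcos", idx, sync$wavelengths,
                   diagnostics = list(diagonal = d,
                                      min_prominence = min_prominence))
}

#' Stage-mean spectra of a labelled table
#'
#' Mean spectrum per maturity stage, rows ordered S1..S5 — the perturbation
#' series consumed by [synchronous_2dcos()].  Uses the calibration split
#' only when one is set.
#'
#' @param table a [spectra_tbl] with labels.
#' @return Numeric matrix, stages x bands, rownames `S<stage>`.
#' @export
stage_means <- function(table) {
  stopifnot(inherits(table, "spectra_tbl"))
  cal <- split_rows(table, "calibration")
  X <- table$X[cal, , drop = FALSE]
  y <- table$y[cal]
  stages <- sort(unique(y))
  M <- t(vapply(stages, function(s) colMeans(X[y == s, , drop = FALSE]),
                numeric(ncol(X))))
  rownames(M) <- paste0("S", stages)
  M
}
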