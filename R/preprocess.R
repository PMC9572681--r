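#' Trim a spectra table to a wavelength window
#'
#' Keeps bands with `lo <= wavelength <= hi`.  The defaults reproduce the
#' usual practice of discarding the noisy detector edges and retaining
#' 400-1000 nm.
#'
#' @param table a [spectra_tbl].
#' @param lo,hi window bounds in nm.
#' @return A trimmed [spectra_tbl].
#' @export
trim_bands <- function(table, lo = 400, hi = 1000) {
  stopifnot(inherits(table, "spectra_tbl"))
  if (lo >= hi) stop("lo must be smaller than hi", call. = FALSE)
  keep <- which(table$wavelengths >= lo & table$wavelengths <= hi)
  if (!length(keep)) stop("no bands inside the requested window", call. = FALSE)
  table[, keep]
}

#' Standard normal variate (SNV) scatter correction
#'
#' Centres each spectrum to mean 0 and scales it to unit standard deviation
#' (n-1 denominator), removing additive offsets and multiplicative gain.
#'
#' @param X numeric matrix, spectra in rows.
#' @return Matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 1, sd)
  if (any(s == 0))
    stop("constant spectrum (zero variance) in row(s): ",
         paste(utils::head(which(s == 0)), collapse = ", "), call. = FALSE)
  (X - rowMeans(X)) / s
}

#' Max-min normalization
#'
#' Rescales each spectrum linearly onto \[0, 1\]:
#' `(x - min(x)) / (max(x) - min(x))`.  Like SNV, invariant to per-spectrum
#' affine distortion with positive gain.
#'
#' @param X numeric matrix, spectra in rows.
#' @return Matrix of the same shape, each row spanning exactly \[0, 1\].
#' @export
minmax_normalize <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 1, min); hi <- apply(X, 1, max)
  if (any(hi == lo))
    stop("constant spectrum in row(s): ",
         paste(utils::head(which(hi == lo)), collapse = ", "), call. = FALSE)
  (X - lo) / (hi - lo)
}

#' Savitzky-Golay derivative of spectra
#'
#' Row-wise Savitzky-Golay derivative along the band axis: in each sliding
#' window a polynomial is fitted by least squares and its derivative
#' evaluated at the centre point; at the series ends the polynomial fitted
#' to the first/last window is evaluated at the edge points, so no bands are
#' lost.  The derivative is per band-index step (unit spacing), not per nm.
#'
#' @param X numeric matrix, spectra in rows.
#' @param order derivative order, 1 or 2.
#' @param window odd window length, default 7.
#' @param polyorder polynomial degree, default 2; must be `< window` and
#'   `>= order`.
#' @return Matrix of the same shape.
#' @export
sg_derivative <- function(X, order, window = 7, polyorder = 2) {
  X <- as.matrix(X)
  if (!order %in% 1:2) stop("order must be 1 or 2", call. = FALSE)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("window must exceed polyorder", call. = FALSE)
  if (order > polyorder) stop("polyorder must be >= derivative order", call. = FALSE)
  if (ncol(X) < window)
    stop("need at least `window` bands for the SG derivative", call. = FALSE)
  t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window, m = order,
          ts = 1))
}

#' Apply a named pre-treatment to a spectra table
#'
#' Dispatches on the preprocessing enum used throughout the package:
#' `"none"`, `"snv"`, `"normalization"` (max-min), `"d1"`, `"d2"`
#' (Savitzky-Golay derivatives, window 7, polynomial order 2).
#'
#' @param table a [spectra_tbl].
#' @param method preprocessing name.
#' @return A [spectra_tbl] with transformed `X` and its tag updated.
#' @export
preprocess <- function(table,
                       method = c("none", "snv", "normalization", "d1", "d2")) {
  stopifnot(inherits(table, "spectra_tbl"))
  method <- match.arg(method)
  X <- switch(method,
    none = table$X,
    snv = snv(table$X),
    normalization = minmax_normalize(table$X),
    d1 = sg_derivative(table$X, order = 1),
    d2 = sg_derivative(table$X, order = 2))
  out <- spectra_tbl(X, table$wavelengths, y = table$y, ids = table$ids,
                     split = table$split, preprocessing = method)
  out
}
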