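#' Band math: difference of two single-wavelength image planes
#'
#' Subtracts the image plane at the band nearest `wl_low` from the plane at
#' the band nearest `wl_high`, producing a greyscale image with high
#' fruit/background contrast (the fruit is bright in the near infrared and
#' dark at the violet end).  The bands actually used are recorded in the
#' `"bands_used"` attribute since the requested wavelengths need not exist
#' exactly on the grid.
#'
#' @param cube calibrated [hypercube].
#' @param wl_high,wl_low wavelengths (nm) of the minuend and subtrahend
#'   planes; defaults 862 and 416.
#' @return Numeric matrix (rows x cols) with attribute `bands_used`, a named
#'   numeric vector of the two grid wavelengths chosen.
#' @export
band_math <- function(cube, wl_high = 862, wl_low = 416) {
  stopifnot(inherits(cube, "hypercube"))
  bh <- nearest_band(cube$wavelengths, wl_high)
  bl <- nearest_band(cube$wavelengths, wl_low)
  img <- cube$data[, , bh] - cube$data[, , bl]
  attr(img, "bands_used") <- c(high = cube$wavelengths[bh],
                               low = cube$wavelengths[bl])
  img
}

#' Threshold a greyscale image into a binary mask
#'
#' Pixels strictly greater than `threshold` are foreground; the boundary
#' value itself is background.
#'
#' @param image numeric matrix, finite.
#' @param threshold reflectance threshold; default 0.1.
#' @return Logical matrix of class `hsi_mask` with attribute `n_foreground`.
#' @export
threshold_mask <- function(image, threshold = 0.1) {
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  mask <- image > threshold
  attributes(mask) <- list(dim = dim(image))
  class(mask) <- "hsi_mask"
  attr(mask, "n_foreground") <- sum(mask)
  mask
}

#' Zero the background of a hypercube
#'
#' Sets every band of each background pixel to 0, leaving foreground pixels
#' untouched.  Idempotent.
#'
#' @param cube a [hypercube].
#' @param mask logical matrix matching the cube's spatial shape.
#' @return Masked [hypercube].
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match cube spatial shape", call. = FALSE)
  keep <- array(as.logical(mask), d)  # recycled along bands
  out <- cube$data
  out[!keep] <- 0
  hypercube(out, cube$wavelengths, cube$meta)
}

#' Mean spectrum over the foreground of a mask
#'
#' Averages the spectra of foreground pixels only; background pixels (zeroed
#' or not) never enter the mean.
#'
#' @param cube a [hypercube].
#' @param mask logical matrix with at least one foreground pixel.
#' @return Numeric vector, one mean reflectance per band.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match cube spatial shape", call. = FALSE)
  idx <- which(as.logical(mask))
  if (!length(idx)) stop("empty mask: no foreground pixels to average", call. = FALSE)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}
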