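#' Hyperspectral data cube
#'
#' A hypercube couples a `rows x cols x bands` numeric array with its
#' wavelength vector (nm, strictly increasing, one entry per band) and
#' free-form metadata.  Calibrated cubes store reflectance as a fraction
#' (1.0 = 100%).
#'
#' @param data numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, `length(wavelengths) == dim(data)[3]`.
#' @param meta named list of free-form metadata (e.g. `sample_id`, `stage`).
#' @return An object of class `hypercube`.
#' @examples
#' cube <- hypercube(array(runif(4 * 5 * 3), c(4, 5, 3)), c(450, 550, 650))
#' dim(cube)
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)", call. = FALSE)
  check_wavelengths(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop(sprintf("wavelength vector length (%d) != number of bands (%d)",
                 length(wavelengths), dim(data)[3]), call. = FALSE)
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 meta = meta),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# shape + wavelength-grid compatibility check
check_same_grid <- function(a, b, what = "cubes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s have different shapes", what), call. = FALSE)
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths)))
    stop(sprintf("%s have different wavelength grids", what), call. = FALSE)
  invisible(TRUE)
}

#' Black-and-white reflectance calibration
#'
#' Converts raw sensor counts to relative reflectance using a white
#' reference (~100% reflectance) and a dark reference (~0%), element-wise:
#' `Ic = (Ir - Id) / (Iw - Id)`.  The transform cancels uneven illumination
#' and dark current: it is invariant to any common affine rescaling of the
#' three inputs.
#'
#' Elements where the white and dark references coincide (`Iw - Id <= 0`,
#' a dead pixel/band) are set to `NA` rather than infinity and reported via
#' the `"dead"` attribute (a logical array).
#'
#' @param raw,white,dark [hypercube]s of identical shape and wavelength grid;
#'   `white` may also be given as a per-band vector (flat-field collapsed to
#'   one scalar per band), as may `dark`.
#' @return A calibrated [hypercube] in reflectance fraction units, carrying
#'   `raw`'s metadata.
#' @examples
#' wl <- c(500, 600)
#' w <- hypercube(array(2, c(2, 2, 2)), wl)
#' d <- hypercube(array(0, c(2, 2, 2)), wl)
#' calibrate(w, w, d)$data[1, 1, ]  # 1.0 everywhere
#' @export
calibrate <- function(raw, white, dark) {
  expand <- function(x) {
    if (inherits(x, "hypercube")) return(x)
    # per-band reference vector -> broadcast to full frame
    if (is.numeric(x) && length(x) == dim(raw$data)[3])
      return(hypercube(aperm(array(x, dim(raw$data)[c(3, 1, 2)]), c(2, 3, 1)),
                       raw$wavelengths))
    stop("references must be hypercubes or per-band vectors", call. = FALSE)
  }
  white <- expand(white); dark <- expand(dark)
  check_same_grid(raw, white, "raw/white"); check_same_grid(raw, dark, "raw/dark")
  denom <- white$data - dark$data
  dead <- denom <= 0
  refl <- (raw$data - dark$data) / denom
  if (any(dead)) {
    refl[dead] <- NA_real_
    warning(sprintf("%d dead elements (white <= dark) set to NA", sum(dead)),
            call. = FALSE)
  }
  out <- hypercube(refl, raw$wavelengths, raw$meta)
  attr(out, "dead") <- if (any(dead)) dead else NULL
  out
}
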