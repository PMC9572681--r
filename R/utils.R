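# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Index of the grid band closest to wavelength `wl` (nm); errors outside range.
nearest_band <- function(wavelengths, wl) {
  if (wl < min(wavelengths) || wl > max(wavelengths))
    stop(sprintf("wavelength %.1f nm outside grid range [%.1f, %.1f]",
                 wl, min(wavelengths), max(wavelengths)), call. = FALSE)
  which.min(abs(wavelengths - wl))
}

check_wavelengths <- function(wavelengths) {
  if (anyNA(wavelengths) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing and free of NA", call. = FALSE)
  invisible(wavelengths)
}

# Local maxima of `x` whose topographic prominence is at least `min_prominence`.
# Prominence of a peak = height above the higher of the two lowest points one
# must descend to before reaching higher ground (or the series end) on each side.
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > x[i])
    lo_l <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1L, i - 1L)])
    right <- x[seq.int(i + 1L, n)]
    higher_r <- which(right > x[i])
    lo_r <- min(right[seq_len(if (length(higher_r)) min(higher_r) else length(right))])
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  cand[prom >= min_prominence]
}
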