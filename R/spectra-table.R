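#' Table of sample spectra with labels and split assignment
#'
#' The unit of modelling: an `n_samples x n_bands` reflectance matrix with
#' its wavelength vector, maturity stage labels (1-5), sample identifiers,
#' an optional calibration/prediction split flag, and a tag recording which
#' preprocessing has been applied.
#'
#' @param X numeric matrix, samples in rows, bands in columns ordered by
#'   increasing wavelength.
#' @param wavelengths numeric vector, nm, strictly increasing, one per column.
#' @param y integer stage labels in 1..5 (or `NA` if unknown).
#' @param ids character sample identifiers.
#' @param split optional factor/character with levels `"calibration"` and
#'   `"prediction"`, one per sample.
#' @param preprocessing tag naming the pre-treatment applied to `X`
#'   (`"none"`, `"snv"`, `"normalization"`, `"d1"`, `"d2"`).
#' @return An object of class `spectra_tbl`.
#' @export
spectra_tbl <- function(X, wavelengths, y = NULL, ids = NULL, split = NULL,
                        preprocessing = "none") {
  X <- as.matrix(X)
  check_wavelengths(wavelengths)
  if (ncol(X) != length(wavelengths))
    stop("ncol(X) must equal length(wavelengths)", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  n <- nrow(X)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_len(n))
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != n || any(!y %in% 1:5 & !is.na(y)))
      stop("y must hold one stage label in 1..5 per sample", call. = FALSE)
  }
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != n || !all(split %in% c("calibration", "prediction")))
      stop('split must be "calibration"/"prediction", one per sample', call. = FALSE)
  }
  colnames(X) <- sprintf("wl_%.1f", wavelengths)
  rownames(X) <- ids
  structure(list(X = X, wavelengths = as.numeric(wavelengths), y = y,
                 ids = as.character(ids), split = split,
                 preprocessing = preprocessing),
            class = "spectra_tbl")
}

#' @export
print.spectra_tbl <- function(x, ...) {
  cat(sprintf("<spectra_tbl> %d samples x %d bands (%.1f-%.1f nm), preprocessing: %s\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
              x$preprocessing))
  if (!is.null(x$y)) cat("  stages:", paste(table(x$y), collapse = "/"), "\n")
  if (!is.null(x$split))
    cat("  split:", sum(x$split == "calibration"), "calibration /",
        sum(x$split == "prediction"), "prediction\n")
  invisible(x)
}

#' @export
dim.spectra_tbl <- function(x) dim(x$X)

#' Subset a spectra table by sample and/or band
#'
#' @param x a [spectra_tbl].
#' @param i sample index (rows).
#' @param j band index (columns).
#' @param ... ignored.
#' @return A [spectra_tbl].
#' @export
`[.spectra_tbl` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$X))
  if (missing(j)) j <- seq_len(ncol(x$X))
  spectra_tbl(x$X[i, j, drop = FALSE], x$wavelengths[j],
              y = x$y[i], ids = x$ids[i], split = x$split[i],
              preprocessing = x$preprocessing)
}

#' Keep only selected bands of a spectra table
#'
#' @param table a [spectra_tbl].
#' @param indices band (column) indices to keep, in any order; the result is
#'   re-ordered by wavelength.
#' @return A [spectra_tbl].
#' @export
select_bands <- function(table, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices) || any(indices < 1 | indices > ncol(table$X)))
    stop("band indices out of range", call. = FALSE)
  table[, indices]
}

# rows belonging to one split (whole table when no split is set)
split_rows <- function(table, which = c("calibration", "prediction")) {
  which <- match.arg(which)
  if (is.null(table$split)) return(seq_len(nrow(table$X)))
  which(table$split == which)
}

#' Assign a random stratified calibration/prediction split
#'
#' Randomly flags each sample as calibration or prediction at the given
#' ratio (default 3:1), stratified by stage so class balance carries over
#' to both sets.
#'
#' @param table a [spectra_tbl] with labels.
#' @param ratio calibration fraction, default 0.75 (a 3:1 split).
#' @param seed integer RNG seed.
#' @param stratify stratify by stage label (default `TRUE`).
#' @return The table with its `split` field populated.
#' @export
assign_split <- function(table, ratio = 0.75, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(table, "spectra_tbl"))
  n <- nrow(table$X)
  idx_cal <- with_seed(seed, {
    if (stratify && !is.null(table$y)) {
      unlist(lapply(base::split(seq_len(n), table$y), function(ix)
        sample(ix, round(length(ix) * ratio))), use.names = FALSE)
    } else sample(n, round(n * ratio))
  })
  spl <- rep("prediction", n)
  spl[idx_cal] <- "calibration"
  table$split <- spl
  table
}

#' Convert a spectra table to a data frame / tibble
#'
#' @param x a [spectra_tbl].
#' @param ... ignored.
#' @return A [tibble::tibble] with `sample_id`, `stage`, `split` and one
#'   column per band named `wl_<nm>`.
#' @export
as.data.frame.spectra_tbl <- function(x, ...) {
  df <- data.frame(sample_id = x$ids,
                   stage = if (is.null(x$y)) NA_integer_ else x$y,
                   split = if (is.null(x$split)) NA_character_ else x$split,
                   x$X, check.names = FALSE, row.names = NULL)
  df
}

#' Write / read a spectra table as CSV
#'
#' @param table a [spectra_tbl].
#' @param path CSV path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a [spectra_tbl].
#' @export
write_spectra_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  band_cols <- grep("^wl_", names(df))
  wl <- as.numeric(sub("^wl_", "", names(df)[band_cols]))
  spectra_tbl(as.matrix(df[, band_cols]), wl,
              y = if (all(is.na(df$stage))) NULL else df$stage,
              ids = df$sample_id,
              split = if (all(is.na(df$split))) NULL else df$split)
}
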