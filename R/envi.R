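#' Read and write hypercubes as ENVI header/binary pairs
#'
#' `write_cube()` stores a [hypercube] as a flat binary file plus a text
#' header (`<path>.hdr`) carrying the dimensions, interleave, data type and
#' the wavelength list in nm.  `read_cube()` reads such a pair back;
#' write-then-read round-trips data and wavelengths losslessly (the default
#' data type is 64-bit float).  BSQ and BIL interleaves are supported.
#'
#' @param cube a [hypercube].
#' @param path path of the binary file; the header is written at
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bsq"` (band-sequential) or `"bil"` (band-interleaved
#'   by line).
#' @param data_type ENVI numeric type code: 4 (32-bit float) or 5 (64-bit
#'   float, default, lossless).
#' @return `read_cube()` returns a [hypercube]; `write_cube()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".img")
#' cube <- hypercube(array(rnorm(24), c(2, 3, 4)), c(400, 500, 600, 700))
#' write_cube(cube, f)
#' identical(read_cube(f)$data, cube$data)
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4, 5)) stop("data_type must be 4 or 5", call. = FALSE)
  d <- dim(cube$data)
  # data is rows x cols x bands; ENVI 'lines' = rows, 'samples' = cols
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),  # fastest: samples, lines, bands
    bil = aperm(cube$data, c(2, 3, 1)))  # fastest: samples, bands, lines
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.vector(arr), con, size = if (data_type == 5) 8L else 4L,
           endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           "wavelength units = nm",
           sprintf("wavelength = { %s }",
                   paste(sprintf("%.17g", cube$wavelengths), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing header file: ", hdr_path, call. = FALSE)
  hdr <- parse_envi_header(hdr_path)
  for (k in c("samples", "lines", "bands"))
    if (is.null(hdr[[k]])) stop("header lacks field: ", k, call. = FALSE)
  if (is.null(hdr[["wavelength"]]))
    stop("header lacks wavelength metadata", call. = FALSE)
  ns <- as.integer(hdr[["samples"]]); nl <- as.integer(hdr[["lines"]])
  nb <- as.integer(hdr[["bands"]])
  wl <- as.numeric(strsplit(hdr[["wavelength"]], ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("header wavelength count (%d) != bands (%d)", length(wl), nb),
         call. = FALSE)
  dt <- if (is.null(hdr[["data type"]])) 5L else as.integer(hdr[["data type"]])
  if (!dt %in% c(4L, 5L)) stop("unsupported data type: ", dt, call. = FALSE)
  size <- if (dt == 5L) 8L else 4L
  n <- ns * nl * nb
  if (file.info(path)$size != n * size)
    stop(sprintf("binary size (%d bytes) inconsistent with header (%d expected)",
                 file.info(path)$size, n * size), call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  il <- if (is.null(hdr[["interleave"]])) "bsq" else tolower(hdr[["interleave"]])
  data <- switch(il,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    stop("unsupported interleave: ", il, call. = FALSE))
  hypercube(data, wl)
}

# minimal ENVI header parser: "key = value" lines, braces may span lines
parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- sub("^ENVI\\s*", "", txt)
  out <- list()
  # fold brace-delimited values onto one line
  braces <- gregexpr("\\{[^}]*\\}", txt)
  regmatches(txt, braces) <- lapply(regmatches(txt, braces),
                                    function(v) gsub("\n", " ", v, fixed = TRUE))
  pat <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)
  for (m in regmatches(txt, pat)[[1]]) {
    key <- trimws(sub("=.*", "", m))
    val <- trimws(sub("^[^=]*=", "", m))
    val <- trimws(gsub("[{}]", "", val))
    out[[key]] <- val
  }
  out
}

#' Write a binary mask as a PNG image
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a PNG mask written by [write_mask_png()]
#'
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}
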