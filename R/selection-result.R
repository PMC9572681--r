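#' Wavelength selection result
#'
#' Common return type of the wavelength pickers ([loading_peaks()],
#' [autopeaks()], [uve_select()], [spa_select()], [uve_spa()]): the selected
#' band indices (unique, sorted) with their wavelengths, the method name,
#' and method-specific diagnostics (stability curve and cutoff for UVE,
#' RMSE-vs-k curve and chain for SPA, synchronous matrix for 2D-COS).
#'
#' @param method method name.
#' @param indices selected band indices.
#' @param wavelengths full wavelength grid of the table the selection was
#'   made on.
#' @param diagnostics named list of method diagnostics.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, indices, wavelengths,
                             diagnostics = list()) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) && (min(indices) < 1 || max(indices) > length(wavelengths)))
    stop("selected indices outside band range", call. = FALSE)
  structure(list(method = method, indices = indices,
                 wavelengths = wavelengths[indices],
                 grid = as.numeric(wavelengths),
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d band(s)\n", x$method, length(x$indices)))
  if (length(x$wavelengths))
    cat("  ", paste(sprintf("%.0f", x$wavelengths), collapse = ", "), "nm\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Writes method, indices and wavelengths (diagnostic curves included when
#' they are plain numeric vectors).
#'
#' @param x a [selection_result].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  diag_ok <- Filter(function(v) is.numeric(v) && is.null(dim(v)), x$diagnostics)
  jsonlite::write_json(list(method = x$method, indices = x$indices,
                            wavelengths_nm = x$wavelengths,
                            diagnostics = diag_ok),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
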