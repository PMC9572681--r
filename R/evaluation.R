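#' Confusion matrix with per-class classification metrics
#'
#' Cross-tabulates actual vs predicted stage labels and derives, per class
#' by one-vs-rest collapsing: correct classification rate
#' (CCR = sensitivity x 100), sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and precision `TP/(TP+FP)`.  Overall CCR is
#' `100 * trace / total`.  Precision is `NaN` (with a note) for a class
#' that is never predicted.  Raw unrounded ratios are retained; the print
#' method rounds percentages to 1 decimal and ratios to 2, the convention
#' of chemometrics reporting.
#'
#' @param actual,predicted integer label vectors of equal length, values in
#'   `1..K`.
#' @param K number of classes (default 5).
#' @return A `confusion_report`: `counts` (K x K, rows = actual),
#'   `per_class` tibble (`stage`, `n`, `ccr_pct`, `sensitivity`,
#'   `specificity`, `precision`, `note`), `overall_ccr` (%), `total`.
#' @export
confusion <- function(actual, predicted, K = 5) {
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted have different lengths", call. = FALSE)
  if (any(!actual %in% seq_len(K)) || any(!predicted %in% seq_len(K)))
    stop(sprintf("labels must lie in 1..%d", K), call. = FALSE)
  counts <- table(factor(actual, levels = seq_len(K)),
                  factor(predicted, levels = seq_len(K)))
  counts <- matrix(as.integer(counts), K, K,
                   dimnames = list(actual = paste0("S", seq_len(K)),
                                   predicted = paste0("S", seq_len(K))))
  total <- sum(counts)
  per <- lapply(seq_len(K), function(k) {
    TP <- counts[k, k]
    FN <- sum(counts[k, ]) - TP
    FP <- sum(counts[, k]) - TP
    TN <- total - TP - FN - FP
    never <- (TP + FP) == 0
    tibble::tibble(stage = k, n = TP + FN,
                   ccr_pct = 100 * TP / (TP + FN),
                   sensitivity = TP / (TP + FN),
                   specificity = TN / (TN + FP),
                   precision = if (never) NaN else TP / (TP + FP),
                   note = if (never) "class never predicted" else NA_character_)
  })
  structure(list(counts = counts,
                 per_class = do.call(rbind, per),
                 overall_ccr = 100 * sum(diag(counts)) / total,
                 total = total),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  K <- nrow(x$counts)
  hdr <- cbind(format(x$counts),
               CCR = sprintf("%.1f%%", x$per_class$ccr_pct),
               Sensitivity = sprintf("%.2f", x$per_class$sensitivity),
               Specificity = sprintf("%.2f", x$per_class$specificity),
               Precision = ifelse(is.nan(x$per_class$precision), "-",
                                  sprintf("%.2f", x$per_class$precision)))
  cat("Confusion matrix (rows = actual, cols = predicted)\n")
  print(hdr, quote = FALSE)
  cat(sprintf("Overall CCR: %.1f%% (%d/%d)\n", x$overall_ccr,
              sum(diag(x$counts)), x$total))
  invisible(x)
}

#' Macro-averaged metrics of a confusion report
#'
#' @param report a `confusion_report`.
#' @return Named numeric vector of macro-averaged sensitivity, specificity
#'   and precision (NaN precisions excluded).
#' @export
macro_metrics <- function(report) {
  pc <- report$per_class
  c(sensitivity = mean(pc$sensitivity),
    specificity = mean(pc$specificity),
    precision = mean(pc$precision[!is.nan(pc$precision)]))
}

#' Evaluate a fitted classifier on calibration, CV and prediction splits
#'
#' Produces three confusion reports: resubstitution on the calibration
#' split, the Venetian-blinds cross-validation predictions stored at fit
#' time (each calibration sample predicted exactly once by the fold that
#' held it out), and the held-out prediction split.
#'
#' @param model an `oleaspec_plsda` or `oleaspec_pcada` model carrying
#'   `cv_pred`.
#' @param table the labelled, split [spectra_tbl] the model was fitted on.
#' @return Named list of `confusion_report`s: `calibration`,
#'   `cross_validation`, `prediction`.
#' @export
evaluate_splits <- function(model, table) {
  stopifnot(inherits(table, "spectra_tbl"))
  if (is.null(table$split)) stop("table carries no split flags", call. = FALSE)
  if (is.null(model$cv_pred))
    stop("model carries no stored CV predictions; refit on this table", call. = FALSE)
  cal <- split_rows(table, "calibration")
  pred <- split_rows(table, "prediction")
  if (!length(pred)) stop("prediction split is empty", call. = FALSE)
  K <- max(table$y)
  list(calibration = confusion(table$y[cal],
                               predict(model, table$X[cal, , drop = FALSE]), K),
       cross_validation = confusion(table$y[cal], model$cv_pred, K),
       prediction = confusion(table$y[pred],
                              predict(model, table$X[pred, , drop = FALSE]), K))
}

#' Read a confusion-count matrix from CSV and score it
#'
#' Helper for evaluating an externally reported K x K count matrix (rows =
#' actual, cols = predicted), e.g. a published confusion table.
#'
#' @param path CSV with K rows and K columns of counts (row names allowed).
#' @return A `confusion_report`.
#' @export
confusion_from_counts_csv <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  confusion_from_counts(m)
}

#' @rdname confusion_from_counts_csv
#' @param counts K x K numeric count matrix.
#' @export
confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  if (ncol(counts) != K || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be a square matrix of non-negative integers", call. = FALSE)
  # row-major enumeration of cells: (actual i, predicted j)
  actual <- rep(rep(seq_len(K), each = K), as.vector(t(counts)))
  predicted <- rep(rep(seq_len(K), times = K), as.vector(t(counts)))
  confusion(actual, predicted, K)
}
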