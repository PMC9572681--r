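#' Fit a PLS-DA maturity classifier
#'
#' One PLS1 regression (NIPALS) per class against its \{0, 1\} indicator;
#' a sample is assigned to the class with the largest regression response
#' (ties to the lowest stage).  The number of latent variables is chosen by
#' ten-fold Venetian-blinds cross-validation on the calibration split: fold
#' `f` holds the calibration rows at positions `f, f + 10, f + 20, ...` in
#' table order, and the chosen dimension minimizes the cross-validated
#' misclassification count (ties to the smaller dimension).  With
#' `criterion = "press"` the prediction error sum of squares on the
#' indicator responses is minimized instead.
#'
#' @param table a [spectra_tbl] with labels; only rows flagged
#'   `"calibration"` are used (the whole table when no split is set).
#' @param max_lv largest latent-variable count tried (default 20).
#' @param cv_folds number of Venetian-blinds folds (default 10).
#' @param criterion `"misclass"` (default) or `"press"`.
#' @return An `oleaspec_plsda` model: fitted per-class coefficients for
#'   every dimension, chosen `n_components`, CV error curve, CV-predicted
#'   labels at the chosen dimension, class codes, wavelengths and the
#'   table's preprocessing tag.
#' @export
plsda_fit <- function(table, max_lv = 20, cv_folds = 10,
                      criterion = c("misclass", "press")) {
  stopifnot(inherits(table, "spectra_tbl"))
  criterion <- match.arg(criterion)
  cal <- split_rows(table, "calibration")
  X <- table$X[cal, , drop = FALSE]
  y <- table$y[cal]
  classes <- sort(unique(y))
  n <- nrow(X)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  if (n < cv_folds) stop("fewer samples than CV folds", call. = FALSE)
  A <- min(max_lv, n - 1L - ceiling(n / cv_folds), ncol(X))
  folds <- venetian_folds(n, cv_folds)
  errors <- numeric(A); press <- numeric(A)
  cv_label <- matrix(NA_integer_, n, A)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f; va <- !tr
    core_f <- plsda_core_fit(X[tr, , drop = FALSE], y[tr], classes, A)
    for (a in seq_len(A)) {
      resp <- plsda_core_response(core_f, X[va, , drop = FALSE], a)
      lab <- classes[max.col(resp, ties.method = "first")]
      cv_label[va, a] <- lab
      errors[a] <- errors[a] + sum(lab != y[va])
      ind <- outer(y[va], classes, `==`) * 1
      press[a] <- press[a] + sum((ind - resp)^2)
    }
  }
  crit <- if (criterion == "misclass") errors else press
  n_comp <- which.min(crit)  # ties -> smaller dimension
  core <- plsda_core_fit(X, y, classes, A)
  structure(list(method = "plsda", core = core, n_components = n_comp,
                 max_components = A, cv_errors = errors, cv_press = press,
                 criterion = criterion,
                 cv_pred = cv_label[, n_comp],
                 cal_ids = table$ids[cal], classes = classes,
                 wavelengths = table$wavelengths,
                 preprocessing = table$preprocessing),
            class = "oleaspec_plsda")
}

#' @export
print.oleaspec_plsda <- function(x, ...) {
  cat(sprintf("<PLS-DA> %d classes, %d latent variable(s) (CV over 1..%d), preprocessing: %s\n",
              length(x$classes), x$n_components, x$max_components,
              x$preprocessing))
  invisible(x)
}

#' Predict maturity stages with a fitted PLS-DA model
#'
#' @param object an `oleaspec_plsda` model.
#' @param newdata numeric matrix (samples x bands) or a [spectra_tbl] with
#'   the model's band count; a table must carry the model's preprocessing
#'   tag.
#' @param type `"class"` for labels, `"response"` for the per-class
#'   regression responses (a `class` attribute carries the labels too).
#' @param components latent-variable count, default the fitted
#'   `n_components`.
#' @param ... ignored.
#' @return Integer labels, or a response matrix when `type = "response"`.
#' @export
predict.oleaspec_plsda <- function(object, newdata,
                                   type = c("class", "response"),
                                   components = object$n_components, ...) {
  type <- match.arg(type)
  X <- model_matrix_for(object, newdata)
  resp <- plsda_core_response(object$core, X, components)
  lab <- object$classes[max.col(resp, ties.method = "first")]
  if (type == "class") return(lab)
  attr(resp, "class_labels") <- lab
  resp
}

# common newdata validation for both classifiers
model_matrix_for <- function(object, newdata) {
  if (inherits(newdata, "spectra_tbl")) {
    if (!identical(newdata$preprocessing, object$preprocessing))
      stop(sprintf("table preprocessing '%s' does not match model '%s'",
                   newdata$preprocessing, object$preprocessing), call. = FALSE)
    newdata <- newdata$X
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$wavelengths))
    stop("band count does not match the fitted model", call. = FALSE)
  X
}

#' Fit a PCA-DA maturity classifier
#'
#' Principal component analysis on the calibration spectra followed by
#' linear discriminant analysis (pooled within-class covariance, equal
#' priors) on the first `p` un-rotated PC scores.  `p` is chosen by the
#' same Venetian-blinds cross-validated misclassification criterion as
#' [plsda_fit()], with PCA and LDA refitted inside every fold.  If the
#' within-class covariance is singular at the requested dimension, `p` is
#' reduced with a warning.
#'
#' @inheritParams plsda_fit
#' @param max_pc largest score dimension tried (default 20).
#' @return An `oleaspec_pcada` model.
#' @export
pcada_fit <- function(table, max_pc = 20, cv_folds = 10) {
  stopifnot(inherits(table, "spectra_tbl"))
  cal <- split_rows(table, "calibration")
  X <- table$X[cal, , drop = FALSE]
  y <- table$y[cal]
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X)
  if (K < 2) stop("need at least two classes", call. = FALSE)
  if (n < cv_folds) stop("fewer samples than CV folds", call. = FALSE)
  A <- min(max_pc, n - 1L - ceiling(n / cv_folds), ncol(X))
  folds <- venetian_folds(n, cv_folds)
  errors <- rep(0, A)
  cv_label <- matrix(NA_integer_, n, A)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f; va <- !tr
    pc <- prcomp(X[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    str_ <- pc$x
    sva <- sweep(X[va, , drop = FALSE], 2, pc$center) %*% pc$rotation
    for (a in seq_len(A)) {
      lab <- tryCatch({
        ld <- MASS::lda(str_[, seq_len(a), drop = FALSE], grouping = factor(y[tr]),
                        prior = rep(1 / K, K))
        as.integer(as.character(
          stats::predict(ld, sva[, seq_len(a), drop = FALSE])$class))
      }, error = function(e) NULL)
      if (is.null(lab)) { errors[a] <- errors[a] + Inf; next }
      cv_label[va, a] <- lab
      errors[a] <- errors[a] + sum(lab != y[va])
    }
  }
  n_comp <- which.min(errors)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  fit_lda <- function(p) MASS::lda(pc$x[, seq_len(p), drop = FALSE],
                                   grouping = factor(y),
                                   prior = rep(1 / K, K))
  lda_fit <- NULL; p_used <- n_comp
  while (is.null(lda_fit) && p_used >= 1) {
    lda_fit <- tryCatch(fit_lda(p_used), error = function(e) NULL)
    if (is.null(lda_fit)) {
      warning(sprintf("within-class covariance singular at p = %d; reducing", p_used),
              call. = FALSE)
      p_used <- p_used - 1L
    }
  }
  if (is.null(lda_fit)) stop("LDA failed at every dimension", call. = FALSE)
  structure(list(method = "pcada", center = pc$center, rotation = pc$rotation,
                 lda = lda_fit, n_components = p_used, max_components = A,
                 cv_errors = errors, cv_pred = cv_label[, n_comp],
                 cal_ids = table$ids[cal], classes = classes,
                 wavelengths = table$wavelengths,
                 preprocessing = table$preprocessing),
            class = "oleaspec_pcada")
}

#' @export
print.oleaspec_pcada <- function(x, ...) {
  cat(sprintf("<PCA-DA> %d classes, %d PC(s) (CV over 1..%d), preprocessing: %s\n",
              length(x$classes), x$n_components, x$max_components,
              x$preprocessing))
  invisible(x)
}

#' Predict maturity stages with a fitted PCA-DA model
#'
#' @param object an `oleaspec_pcada` model.
#' @param newdata matrix or [spectra_tbl] matching the model's bands.
#' @param ... ignored.
#' @return Integer stage labels.
#' @export
predict.oleaspec_pcada <- function(object, newdata, ...) {
  X <- model_matrix_for(object, newdata)
  scores <- sweep(X, 2, object$center) %*%
    object$rotation[, seq_len(object$n_components), drop = FALSE]
  as.integer(as.character(stats::predict(object$lda, scores)$class))
}

#' Cross-validation error curve over model dimension
#'
#' Recomputes the Venetian-blinds cross-validated misclassification counts
#' for every dimension 1..`max_components`, for either classifier.
#' Deterministic given the table's row order.
#'
#' @inheritParams plsda_fit
#' @param method `"plsda"` or `"pcada"`.
#' @param max_components largest dimension tried.
#' @return A [tibble::tibble] with columns `components` and `errors`, and
#'   attribute `chosen` (the error-minimizing dimension, ties to the
#'   smallest).
#' @export
cv_curve <- function(table, method = c("plsda", "pcada"),
                     max_components = 20, cv_folds = 10) {
  method <- match.arg(method)
  fit <- switch(method,
    plsda = plsda_fit(table, max_lv = max_components, cv_folds = cv_folds),
    pcada = pcada_fit(table, max_pc = max_components, cv_folds = cv_folds))
  out <- tibble::tibble(components = seq_along(fit$cv_errors),
                        errors = fit$cv_errors)
  attr(out, "chosen") <- which.min(fit$cv_errors)
  out
}

#' Save / load a fitted classifier as a JSON archive
#'
#' A self-describing plain-text serialization: method, class codes, chosen
#' dimension, wavelengths, preprocessing tag and all numeric model state.
#'
#' @param model an `oleaspec_plsda` model.
#' @param path file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "oleaspec_plsda"))
    stop("only PLS-DA models are serialized to JSON", call. = FALSE)
  payload <- list(method = model$method, classes = model$classes,
                  n_components = model$n_components,
                  max_components = model$max_components,
                  wavelengths = model$wavelengths,
                  preprocessing = model$preprocessing,
                  coef = model$core$coef, intercept = model$core$intercept,
                  cv_errors = model$cv_errors)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- length(p$classes)
  A <- p$max_components
  coef <- array(as.numeric(p$coef), c(length(p$wavelengths), A, K))
  structure(list(method = "plsda",
                 core = list(coef = coef,
                             intercept = matrix(as.numeric(p$intercept), A, K),
                             classes = as.integer(p$classes)),
                 n_components = p$n_components, max_components = A,
                 cv_errors = as.numeric(p$cv_errors),
                 classes = as.integer(p$classes),
                 wavelengths = as.numeric(p$wavelengths),
                 preprocessing = p$preprocessing),
            class = "oleaspec_plsda")
}
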