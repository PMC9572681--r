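# PLS1 (univariate-response partial least squares) via NIPALS.
# Returns regression coefficients on the original (uncentred) scale for
# every component count 1..A, so cross-validation curves come from one fit.
pls1_nipals <- function(X, y, A, tol = 1e-12) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  A <- min(A, n - 1L, p)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx); yc <- y - my
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < tol) break
    pl <- crossprod(Xc, t_) / tt
    qa <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, pl)
    yc <- yc - qa * t_
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
    a_eff <- a
  }
  if (a_eff == 0L)
    return(list(coef = matrix(0, p, max(A, 1L)),
                intercept = rep(my, max(A, 1L)), a_eff = 0L))
  coef <- matrix(0, p, A)
  for (a in seq_len(a_eff)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    coef[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  if (a_eff < A) coef[, seq.int(a_eff + 1L, A)] <- coef[, a_eff]
  intercept <- my - as.numeric(mx %*% coef)
  list(coef = coef, intercept = intercept, a_eff = a_eff)
}

# One PLS1 model per class against its {0,1} indicator.
# Returns coef array [p, A, K] and intercept matrix [A, K].
plsda_core_fit <- function(X, y, classes, A) {
  p <- ncol(X); K <- length(classes)
  coef <- array(0, c(p, A, K))
  intercept <- matrix(0, A, K)
  for (k in seq_len(K)) {
    fit <- pls1_nipals(X, as.numeric(y == classes[k]), A)
    a_have <- ncol(fit$coef)
    use <- seq_len(min(A, a_have))
    coef[, use, k] <- fit$coef[, use]
    intercept[use, k] <- fit$intercept[use]
    if (a_have < A) {
      coef[, seq.int(a_have + 1L, A), k] <- fit$coef[, a_have]
      intercept[seq.int(a_have + 1L, A), k] <- fit$intercept[a_have]
    }
  }
  list(coef = coef, intercept = intercept, classes = classes)
}

# Per-class regression responses at `a` components: n x K matrix.
plsda_core_response <- function(core, X, a) {
  K <- length(core$classes)
  resp <- X %*% matrix(core$coef[, a, ], ncol = K)
  sweep(resp, 2, core$intercept[a, ], `+`)
}

# argmax class assignment; ties -> lowest stage index
plsda_core_labels <- function(core, X, a) {
  core$classes[max.col(plsda_core_response(core, X, a), ties.method = "first")]
}

# Venetian-blinds fold assignment: fold f holds rows f, f + k, f + 2k, ...
venetian_folds <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L
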