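# Maximum-likelihood multinomial logit on aggregated count data.
#
# X: n x p design (unique covariate patterns); Y: n x J counts with the
# REFERENCE destination in column 1. Coefficients are a p x (J-1) matrix for
# the non-reference destinations. Newton-Raphson on the full stacked Hessian;
# step halving keeps the log-likelihood monotone; on separation (diverging
# coefficients or a singular Hessian) the fit restarts with a small ridge
# penalty and is flagged.
multinom_newton <- function(X, Y, ridge = 0, maxit = 500, tol = 1e-8,
                            compute_se = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  p <- ncol(X)
  J <- ncol(Y)
  stopifnot(J >= 2, nrow(X) == nrow(Y))
  N <- rowSums(Y)
  keep <- N > 0
  Xk <- X[keep, , drop = FALSE]
  Yk <- Y[keep, , drop = FALSE]
  Nk <- N[keep]
  Ynr <- Yk[, -1, drop = FALSE]
  Jm <- J - 1
  total <- sum(Nk)

  # columns with no variation among observed patterns cannot be identified;
  # their coefficients are pinned at 0
  active <- apply(Xk, 2, function(col) {
    length(unique(col)) > 1 || col[1] != 0
  })
  active[1] <- TRUE # intercept
  Xa <- Xk[, active, drop = FALSE]
  pa <- ncol(Xa)

  row_max0 <- function(m) {
    a <- m[, 1]
    for (j in seq_len(ncol(m))[-1]) a <- pmax(a, m[, j])
    pmax(a, 0)
  }

  loglik_parts <- function(beta) {
    eta <- Xa %*% beta
    a <- row_max0(eta)
    ex <- exp(eta - a)
    denom <- exp(-a) + rowSums(ex)
    P <- ex / denom # non-reference probabilities
    ll <- sum(Ynr * eta) - sum(Nk * (a + log(denom))) -
      0.5 * ridge * sum(beta^2)
    list(ll = ll, P = P)
  }

  beta <- matrix(0, pa, Jm)
  parts <- loglik_parts(beta)
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(maxit)) {
    P <- parts$P
    G <- crossprod(Xa, Ynr - Nk * P) - ridge * beta
    if (max(abs(G)) < tol * max(1, total)) {
      converged <- TRUE
      break
    }
    H <- matrix(0, pa * Jm, pa * Jm)
    for (j in seq_len(Jm)) {
      for (k in j:Jm) {
        w <- if (j == k) Nk * P[, j] * (1 - P[, j]) else -Nk * P[, j] * P[, k]
        blk <- crossprod(Xa * w, Xa)
        ri <- (j - 1) * pa + seq_len(pa)
        ci <- (k - 1) * pa + seq_len(pa)
        H[ri, ci] <- blk
        if (j != k) H[ci, ri] <- t(blk)
      }
    }
    diag(H) <- diag(H) + ridge
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      if (ridge == 0) {
        return(multinom_newton(X, Y, ridge = 1e-6, maxit = maxit, tol = tol,
                               compute_se = compute_se))
      }
      separated <- TRUE
      break
    }
    step <- matrix(step, pa, Jm)
    # step halving
    lam <- 1
    repeat {
      cand <- beta + lam * step
      cparts <- loglik_parts(cand)
      if (is.finite(cparts$ll) && cparts$ll >= parts$ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    beta <- beta + lam * step
    parts <- cparts
    if (ridge == 0 && max(abs(beta)) > 30) {
      # (quasi-)separation: some linear predictor is running off to +-Inf
      return(multinom_newton(X, Y, ridge = 1e-6, maxit = maxit, tol = tol,
                             compute_se = compute_se))
    }
  }

  coef <- matrix(0, p, Jm, dimnames = list(colnames(X), colnames(Y)[-1]))
  coef[active, ] <- beta
  se <- NULL
  if (compute_se) {
    P <- parts$P
    H <- matrix(0, pa * Jm, pa * Jm)
    for (j in seq_len(Jm)) {
      for (k in j:Jm) {
        w <- if (j == k) Nk * P[, j] * (1 - P[, j]) else -Nk * P[, j] * P[, k]
        blk <- crossprod(Xa * w, Xa)
        ri <- (j - 1) * pa + seq_len(pa)
        ci <- (k - 1) * pa + seq_len(pa)
        H[ri, ci] <- blk
        if (j != k) H[ci, ri] <- t(blk)
      }
    }
    diag(H) <- diag(H) + max(ridge, 0)
    v <- tryCatch(diag(solve(H)), error = function(e) rep(NA_real_, pa * Jm))
    se <- matrix(NA_real_, p, Jm, dimnames = dimnames(coef))
    se[active, ] <- matrix(sqrt(pmax(v, 0)), pa, Jm)
  }
  list(
    coefficients = coef,
    loglik = parts$ll,
    converged = converged && !separated,
    ridge = ridge,
    iterations = it,
    active = active,
    se = se
  )
}

# softmax transition probabilities from design rows; coef has reference
# destination (column of zeros) implicit in position `ref_index` of `labels`
softmax_probs <- function(X, coef, labels, ref_index = 1) {
  eta <- X %*% coef
  full <- matrix(0, nrow(X), length(labels))
  full[, -ref_index] <- eta
  a <- full[, 1]
  for (j in seq_len(ncol(full))[-1]) a <- pmax(a, full[, j])
  ex <- exp(full - a)
  P <- ex / rowSums(ex)
  colnames(P) <- labels
  P
}
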