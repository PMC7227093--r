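# Independent oracle implementations used only to cross-check the package.
# Written deliberately in a naive, loop-heavy style straight from the
# published formulas so they share no code path with the implementation.

# Parametric empirical-Bayes batch adjustment, gene-by-gene loops
# (Johnson, Li & Rabinovic 2007).  X: samples x genes.
oracle_combat <- function(X, batch, conv = 1e-4) {
  batch <- as.integer(as.factor(batch))
  B <- max(batch)
  n <- nrow(X)
  G <- ncol(X)
  nb <- sapply(1:B, function(j) sum(batch == j))

  grand <- numeric(G)
  varp <- numeric(G)
  for (g in 1:G) {
    bm <- sapply(1:B, function(j) mean(X[batch == j, g]))
    grand[g] <- sum(bm * nb / n)
    varp[g] <- sum((X[, g] - bm[batch])^2) / n
  }
  S <- matrix(0, n, G)
  for (g in 1:G) S[, g] <- (X[, g] - grand[g]) / sqrt(varp[g])

  gamma_hat <- matrix(0, B, G)
  delta_hat <- matrix(0, B, G)
  for (j in 1:B) for (g in 1:G) {
    v <- S[batch == j, g]
    gamma_hat[j, g] <- mean(v)
    delta_hat[j, g] <- var(v)
  }

  out <- S
  for (j in 1:B) {
    gbar <- mean(gamma_hat[j, ])
    t2 <- var(gamma_hat[j, ])
    dm <- mean(delta_hat[j, ])
    ds2 <- var(delta_hat[j, ])
    ap <- (2 * ds2 + dm^2) / ds2
    bp <- (dm * ds2 + dm^3) / ds2
    nj <- nb[j]
    g_old <- gamma_hat[j, ]
    d_old <- delta_hat[j, ]
    repeat {
      g_new <- (t2 * nj * gamma_hat[j, ] + d_old * gbar) / (t2 * nj + d_old)
      sum2 <- numeric(G)
      for (g in 1:G) sum2[g] <- sum((S[batch == j, g] - g_new[g])^2)
      d_new <- (0.5 * sum2 + bp) / (nj / 2 + ap - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change <= conv) break
    }
    for (g in 1:G)
      out[batch == j, g] <- (S[batch == j, g] - g_old[g]) / sqrt(d_old[g])
  }
  for (g in 1:G) out[, g] <- out[, g] * sqrt(varp[g]) + grand[g]
  out
}

# Lasso solved by plain coordinate descent at a given penalty sequence,
# matching the conventions of the path implementation it cross-checks:
# predictors standardized to mean 0 and unit population SD, outcome
# centered, objective 1/(2n) * RSS + lambda * sum(|b|), coefficients
# reported on the input scale.  Returns coefficient matrix p x nlambda
# and intercepts.
oracle_lasso_path <- function(X, y, lambda, tol = 1e-9, max_sweeps = 10000) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(X^2) - xm^2)
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  soft <- function(z, t) sign(z) * max(abs(z) - t, 0)

  beta <- numeric(p)
  r <- yc
  B <- matrix(0, p, length(lambda))
  b0 <- numeric(length(lambda))
  sweep_once <- function(coords, lam) {
    delta_max <- 0
    for (j in coords) {
      bj <- beta[j]
      z <- sum(Xs[, j] * r) / n + bj
      bn <- soft(z, lam)
      if (bn != bj) {
        r <<- r - Xs[, j] * (bn - bj)
        beta[j] <<- bn
        delta_max <- max(delta_max, abs(bn - bj))
      }
    }
    delta_max
  }
  for (k in seq_along(lambda)) {
    lam <- lambda[k]
    repeat {
      # one complete pass (lets coordinates enter the active set) ...
      d_full <- sweep_once(1:p, lam)
      if (d_full < tol) break
      # ... then iterate the active set to convergence
      for (s in seq_len(max_sweeps)) {
        active <- which(beta != 0)
        if (length(active) == 0) break
        if (sweep_once(active, lam) < tol) break
      }
    }
    B[, k] <- beta / xs
    b0[k] <- ym - sum(B[, k] * xm)
  }
  list(beta = B, intercept = b0)
}

# K-fold CV curve at a fixed penalty sequence and fixed fold assignment,
# grouped-fold convention: per-fold mean squared error, curve = fold-size
# weighted mean, SE over folds with divisor sqrt(K); the 1-SE choice is the
# largest penalty with curve <= min + SE[min].
oracle_cv_lasso <- function(X, y, foldid, lambda) {
  K <- max(foldid)
  nl <- length(lambda)
  fold_mse <- matrix(NA_real_, K, nl)
  w <- numeric(K)
  for (f in 1:K) {
    test <- foldid == f
    w[f] <- sum(test)
    fit <- oracle_lasso_path(X[!test, , drop = FALSE], y[!test], lambda)
    pred <- sweep(X[test, , drop = FALSE] %*% fit$beta, 2, fit$intercept, "+")
    fold_mse[f, ] <- colMeans((pred - y[test])^2)
  }
  cvm <- apply(fold_mse, 2, function(col) sum(col * w) / sum(w))
  cvsd <- sqrt(apply((fold_mse - matrix(cvm, K, nl, byrow = TRUE))^2, 2,
                     function(col) sum(col * w) / sum(w)) / (K - 1))
  imin <- which.min(cvm)
  lambda_1se <- max(lambda[cvm <= cvm[imin] + cvsd[imin]])
  full <- oracle_lasso_path(X, y, lambda)
  k1 <- which(lambda == lambda_1se)
  list(cvm = cvm, cvsd = cvsd, lambda_min = lambda[imin],
       lambda_1se = lambda_1se,
       beta_1se = full$beta[, k1], intercept_1se = full$intercept[k1])
}
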