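# Independent proximal-gradient (FISTA) minimizer of the elastic-net
# penalized logistic objective. Deliberately shares no code path with the
# package's coordinate-descent solver; used as an optimization oracle.
prox_grad_enet <- function(X, y, lambda, alpha, max_iter = 200000, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  Xa <- cbind(1, X)
  lip <- (svd(Xa, nu = 0, nv = 0)$d[1]^2) / (4 * n) + lambda * (1 - alpha)
  step <- 1 / lip
  b <- rep(0, p + 1)
  bz <- b
  tk <- 1
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% bz)
    grad <- drop(crossprod(Xa, plogis(eta) - y)) / n
    grad[-1] <- grad[-1] + lambda * (1 - alpha) * bz[-1]
    bn <- bz - step * grad
    bn[-1] <- sign(bn[-1]) * pmax(abs(bn[-1]) - step * lambda * alpha, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    done <- max(abs(bn - b)) < tol
    bz <- bn + ((tk - 1) / tn) * (bn - b)
    b <- bn
    tk <- tn
    if (done) break
  }
  list(beta0 = b[1], beta = b[-1])
}

# Small logistic test problem with a few informative features.
make_logistic_data <- function(n, p, n_signal = 3, coef = 1.2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  eta <- drop(X[, seq_len(n_signal), drop = FALSE] %*% rep(coef, n_signal))
  y <- rbinom(n, 1, plogis(eta))
  # guard against degenerate draws
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}

# Subgradient residual of the penalized logistic objective at (beta0, beta):
# returns the largest KKT violation across coordinates (0 at an optimum).
kkt_violation <- function(beta0, beta, X, y, lambda, alpha) {
  n <- nrow(X)
  pr <- plogis(drop(beta0 + X %*% beta))
  grad <- drop(crossprod(X, pr - y)) / n + lambda * (1 - alpha) * beta
  viol <- ifelse(beta == 0,
                 pmax(abs(grad) - lambda * alpha, 0),
                 abs(grad + lambda * alpha * sign(beta)))
  c(max(viol), abs(mean(pr - y)))
}
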