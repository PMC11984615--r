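# Independent numerical oracles used across the suite. These deliberately
# avoid the package's quadrature/variational code paths.

# univariate PLN log-pmf by adaptive deterministic integration
pln_logpmf_oracle <- function(y, mu, sigma2, offset = 0) {
  vapply(y, function(yi) {
    f <- function(x) {
      exp(yi * (x + offset) - exp(x + offset) - lgamma(yi + 1) -
            (x - mu)^2 / (2 * sigma2))
    }
    lo <- mu - 15 * sqrt(sigma2); hi <- mu + 15 * sqrt(sigma2)
    v <- stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
    log(v) - 0.5 * log(2 * pi * sigma2)
  }, numeric(1))
}

# exact bivariate MPLN log-likelihood by mode-centred product Gauss-Hermite
# quadrature (independent of the variational machinery)
mpln_loglik_2d_oracle <- function(Y, mu, Sigma, nodes = 40L) {
  gh <- pracma::gaussHermite(nodes)
  Sinv <- solve(Sigma)
  ldetS <- determinant(Sigma, logarithm = TRUE)$modulus
  grid <- as.matrix(expand.grid(k = seq_len(nodes), l = seq_len(nodes)))
  Tmat <- cbind(gh$x[grid[, 1]], gh$x[grid[, 2]])
  lw <- log(gh$w[grid[, 1]]) + gh$x[grid[, 1]]^2 +
        log(gh$w[grid[, 2]]) + gh$x[grid[, 2]]^2
  g <- function(X, y) {
    rowSums(sweep(X, 2L, y, "*") - exp(X) - matrix(lgamma(y + 1), nrow(X), 2, byrow = TRUE)) -
      0.5 * rowSums((sweep(X, 2L, mu) %*% Sinv) * sweep(X, 2L, mu))
  }
  ll <- vapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]
    x <- log(y + 0.5)
    for (it in 1:60) {                       # Newton to the joint mode
      gr <- y - exp(x) - Sinv %*% (x - mu)
      H <- -diag(exp(x)) - Sinv
      step <- solve(H, -gr)
      step <- pmin(pmax(step, -2), 2)
      x <- x + as.numeric(step)
      if (max(abs(step)) < 1e-12) break
    }
    H <- diag(exp(x)) + Sinv
    L <- t(chol(solve(H)))
    X <- matrix(x, nrow(Tmat), 2, byrow = TRUE) + sqrt(2) * Tmat %*% t(L)
    m <- max(lw + g(X, y))
    log(sum(exp(lw + g(X, y) - m))) + m +
      log(2) + sum(log(diag(L))) - log(2 * pi) - 0.5 * ldetS
  }, numeric(1))
  sum(ll)
}

# adjusted Rand index between two partitions
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# two well-separated MPLN components for clustering tests
make_two_cluster_data <- function(n_per = 200L, seed = 1L) {
  p1 <- mpln_params(log(c(100, 400, 50)), diag(0.2, 3))
  p2 <- mpln_params(log(c(1000, 30, 600)), diag(0.2, 3))
  Y <- rbind(mpln_sample(p1, n_per, seed = derive_seed(seed, 1L)),
             mpln_sample(p2, n_per, seed = derive_seed(seed, 2L)))
  list(Y = Y, truth = rep(1:2, each = n_per), p1 = p1, p2 = p2)
}
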