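## Parameter bundles ---------------------------------------------------------

#' Poisson parameters
#' @param rate positive expected count.
#' @return an object of class `poisson_params`.
#' @export
poisson_params <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate), rate > 0)
  structure(list(rate = rate), class = "poisson_params")
}

#' Negative binomial parameters (shape--scale form)
#'
#' The hierarchical Poisson-Gamma form: the Poisson rate is Gamma(alpha, beta)
#' so the marginal mean is `alpha * beta` and the marginal variance is
#' `mean + mean^2 / alpha`. `1/alpha` is the over-dispersion parameter.
#'
#' @param shape Gamma shape alpha (> 0).
#' @param scale Gamma scale beta (> 0).
#' @return an object of class `nb_params`.
#' @export
nb_params <- function(shape, scale) {
  stopifnot(is.finite(shape), shape > 0, is.finite(scale), scale > 0)
  structure(list(shape = shape, scale = scale), class = "nb_params")
}

#' Poisson lognormal parameters
#'
#' The observed count is Poisson with rate `exp(X)` where the latent
#' `X ~ N(mu, sigma2)`. `sigma2 = 0` gives back a Poisson with rate `exp(mu)`.
#'
#' @param mu latent Gaussian mean.
#' @param sigma2 latent Gaussian variance (>= 0).
#' @return an object of class `pln_params`.
#' @export
pln_params <- function(mu, sigma2) {
  stopifnot(is.finite(mu), is.finite(sigma2), sigma2 >= 0)
  structure(list(mu = mu, sigma2 = sigma2), class = "pln_params")
}

#' Multivariate Poisson lognormal parameters
#'
#' Counts in each coordinate are conditionally Poisson with rate `exp(X_j)`
#' where the latent vector `X ~ N(mu, Sigma)`; `Sigma` must be symmetric
#' positive-definite.
#'
#' @param mu latent mean vector (length d).
#' @param Sigma d x d symmetric positive-definite latent covariance.
#' @return an object of class `mpln_params`.
#' @export
mpln_params <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  d <- length(mu)
  stopifnot(d >= 1L, nrow(Sigma) == d, ncol(Sigma) == d, all(is.finite(Sigma)))
  if (!is_spd(Sigma)) stop("Sigma must be symmetric positive-definite")
  structure(list(mu = mu, Sigma = (Sigma + t(Sigma)) / 2), class = "mpln_params")
}

## Moments and moment matching -----------------------------------------------

#' Mean and variance of a Poisson lognormal distribution
#'
#' Closed forms: `E(Y) = exp(mu + sigma2/2)` and
#' `V(Y) = E(Y) + E(Y)^2 (exp(sigma2) - 1)`. The factor `exp(sigma2) - 1`
#' controls the over-dispersion; it vanishes in the Poisson limit.
#'
#' @param params a [pln_params()] object.
#' @return list with elements `mean` and `variance`.
#' @export
pln_moments <- function(params) {
  stopifnot(inherits(params, "pln_params"))
  m <- exp(params$mu + params$sigma2 / 2)
  list(mean = m, variance = m + m^2 * (exp(params$sigma2) - 1))
}

#' Poisson lognormal parameters matching a target mean and variance
#'
#' Inverts the PLN moment formulas: `sigma2 = log(1 + (v - m)/m^2)` and
#' `mu = log(m) - sigma2/2`. Requires `v >= m` (the PLN family cannot be
#' under-dispersed).
#'
#' @param mean target mean (> 0).
#' @param variance target variance (>= mean).
#' @return a [pln_params()] object.
#' @export
pln_match_moments <- function(mean, variance) {
  stopifnot(is.finite(mean), mean > 0, is.finite(variance))
  if (variance < mean) {
    stop("under-dispersed target: the PLN family requires variance >= mean")
  }
  sigma2 <- log1p((variance - mean) / mean^2)
  pln_params(mu = log(mean) - sigma2 / 2, sigma2 = sigma2)
}

#' Mean and variance of a negative binomial distribution
#' @param params an [nb_params()] object.
#' @return list with elements `mean` and `variance`.
#' @export
nb_moments <- function(params) {
  stopifnot(inherits(params, "nb_params"))
  m <- params$shape * params$scale
  list(mean = m, variance = m + m^2 / params$shape)
}

#' Negative binomial parameters matching a target mean and variance
#'
#' `alpha = m^2 / (v - m)`, `beta = (v - m) / m`; requires strict
#' over-dispersion (`v > m`, otherwise alpha diverges).
#'
#' @inheritParams pln_match_moments
#' @return an [nb_params()] object.
#' @export
nb_match_moments <- function(mean, variance) {
  stopifnot(is.finite(mean), mean > 0, is.finite(variance))
  if (variance <= mean) {
    stop("target variance must exceed the mean: the NB shape diverges at equality")
  }
  nb_params(shape = mean^2 / (variance - mean), scale = (variance - mean) / mean)
}

## PLN log pmf by adaptive Gauss-Hermite quadrature --------------------------

## cache of Gauss-Hermite rules (physicists' convention)
.gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  .gh_cache[[key]]
}

## Newton solve for the per-observation posterior mode of the latent x:
## maximize y*(x+o) - exp(x+o) - (x-mu)^2/(2 sigma2).  Concave, vectorized.
pln_latent_mode <- function(y, mu, sigma2, offset) {
  x <- ifelse(y > 0, log(y + 0.5) - offset, mu)
  for (it in 1:50) {
    ex <- exp(x + offset)
    g <- y - ex - (x - mu) / sigma2
    h <- ex + 1 / sigma2
    step <- g / h
    step <- pmax(pmin(step, 2), -2)  # damped: exp() must not overflow
    x <- x + step
    if (max(abs(step)) < 1e-12) break
  }
  x
}

#' Log probability mass function of the Poisson lognormal distribution
#'
#' Evaluates `log P(Y = y)` where `Y | X ~ Poisson(exp(X + offset))` and
#' `X ~ N(mu, sigma2)`. The marginal has no closed form; the integral over the
#' latent variable is computed by Gauss-Hermite quadrature recentred at the
#' posterior mode of `X` given `y` and rescaled by the local curvature, which
#' keeps the rule accurate when the conditional posterior is much narrower
#' than the prior (large counts). At `sigma2 = 0` the exact Poisson branch is
#' used.
#'
#' @param y vector of nonnegative integer counts.
#' @param params a [pln_params()] object.
#' @param offset log-scale additive constant(s) in the latent exponent
#'   (scalar or one per element of `y`); default 0.
#' @param nodes number of quadrature nodes (default 50).
#' @return vector of log probabilities, one per element of `y`.
#' @export
pln_logpmf <- function(y, params, offset = 0, nodes = 50L) {
  stopifnot(inherits(params, "pln_params"))
  check_counts(y)
  stopifnot(all(is.finite(offset)))
  if (length(offset) == 1L) offset <- rep(offset, length(y))
  stopifnot(length(offset) == length(y))
  mu <- params$mu; sigma2 <- params$sigma2
  if (sigma2 < 1e-10) {
    return(dpois(round(y), lambda = exp(mu + offset), log = TRUE))
  }
  gh <- gh_rule(nodes)
  xhat <- pln_latent_mode(y, mu, sigma2, offset)
  scl <- 1 / sqrt(exp(xhat + offset) + 1 / sigma2)
  ## integral of exp(g(x)) dx with nodes x = xhat + sqrt(2)*scl*t
  tk <- gh$x
  lw <- log(gh$w) + tk^2
  xk <- matrix(xhat, length(y), nodes) + sqrt(2) * outer(scl, tk)
  ek <- xk + offset
  g <- y * ek - exp(ek) - lgamma(y + 1) - (xk - mu)^2 / (2 * sigma2)
  lint <- row_logsumexp(sweep(g, 2L, lw, "+")) + 0.5 * log(2) + log(scl)
  lint - 0.5 * log(2 * pi * sigma2)
}

## Samplers ------------------------------------------------------------------

#' Sample from the Poisson, negative binomial, or Poisson lognormal family
#'
#' All three samplers draw hierarchically where applicable (latent draw, then
#' conditional Poisson) and are reproducible given `seed`.
#'
#' @param params family parameter object.
#' @param n number of draws.
#' @param offset log-scale additive constant(s) in the latent exponent.
#' @param seed optional integer seed; if `NULL`, the current RNG state is used.
#' @return integer vector of counts.
#' @export
pln_sample <- function(params, n, offset = 0, seed = NULL) {
  stopifnot(inherits(params, "pln_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n, params$mu, sqrt(params$sigma2))
  rpois(n, exp(x + offset))
}

#' @rdname pln_sample
#' @export
nb_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "nb_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lambda <- rgamma(n, shape = params$shape, scale = params$scale)
  rpois(n, lambda)
}

#' @rdname pln_sample
#' @export
poisson_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "poisson_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rpois(n, params$rate)
}

## MPLN moments and sampling -------------------------------------------------

#' Closed-form moments of the multivariate Poisson lognormal distribution
#'
#' `E(Y_j) = exp(mu_j + Sigma_jj/2)`;
#' `V(Y_j) = E(Y_j) + E(Y_j)^2 (exp(Sigma_jj) - 1)`;
#' `Cov(Y_j, Y_k) = E(Y_j) E(Y_k) (exp(Sigma_jk) - 1)` for `j != k`;
#' `Cor(Y_j, Y_k) = (exp(Sigma_jk) - 1) /
#'   sqrt((exp(Sigma_jj) - 1 + 1/E(Y_j)) (exp(Sigma_kk) - 1 + 1/E(Y_k)))`.
#' The observed covariance keeps the sign of the latent covariance, maps
#' latent zero to observed zero exactly, and is attenuated in magnitude.
#'
#' @param params an [mpln_params()] object.
#' @return list with `mean` (length d), `covariance` and `correlation`
#'   (both d x d).
#' @export
mpln_moments <- function(params) {
  stopifnot(inherits(params, "mpln_params"))
  mu <- params$mu; Sigma <- params$Sigma
  d <- length(mu)
  m <- exp(mu + diag(Sigma) / 2)
  C <- outer(m, m) * (exp(Sigma) - 1)
  diag(C) <- m + m^2 * (exp(diag(Sigma)) - 1)
  denom <- sqrt(exp(diag(Sigma)) - 1 + 1 / m)
  R <- (exp(Sigma) - 1) / outer(denom, denom)
  diag(R) <- 1
  list(mean = m, covariance = C, correlation = R)
}

#' Latent covariance entry from a latent correlation and two latent variances
#'
#' `Sigma_jk = Cor(X_j, X_k) * sqrt(Sigma_jj * Sigma_kk)`. The implied 2x2
#' latent covariance must be positive-definite (`|cor_x| < 1`).
#'
#' @param cor_x latent Pearson correlation in (-1, 1).
#' @param sjj,skk latent variances (> 0).
#' @return the off-diagonal latent covariance entry.
#' @export
latent_cov_entry <- function(cor_x, sjj, skk) {
  stopifnot(is.finite(cor_x), sjj > 0, skk > 0)
  if (abs(cor_x) >= 1) {
    stop("latent correlation must lie strictly inside (-1, 1) for a positive-definite covariance")
  }
  cor_x * sqrt(sjj * skk)
}

#' Sample a count matrix from the multivariate Poisson lognormal distribution
#'
#' Each row draws a latent vector from `N(mu, Sigma)`, then conditionally
#' independent Poisson counts with rates `exp(X_ij + o_ij)`.
#'
#' @param params an [mpln_params()] object.
#' @param n number of rows (observations).
#' @param offsets scalar, per-row vector, or n x d matrix of log offsets.
#' @param seed optional integer seed.
#' @param latent if `TRUE`, also return the latent matrix `X`.
#' @return integer matrix (n x d), or a list `(Y, X)` when `latent = TRUE`.
#' @export
mpln_sample <- function(params, n, offsets = NULL, seed = NULL, latent = FALSE) {
  stopifnot(inherits(params, "mpln_params"), n >= 1)
  d <- length(params$mu)
  O <- expand_offsets(offsets, n, d)
  if (!is.null(seed)) set.seed(seed)
  X <- MASS::mvrnorm(n, mu = params$mu, Sigma = params$Sigma)
  X <- matrix(X, nrow = n, ncol = d)
  Y <- matrix(rpois(n * d, exp(X + O)), n, d)
  if (latent) list(Y = Y, X = X) else Y
}
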