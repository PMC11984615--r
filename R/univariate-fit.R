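## Maximum-likelihood fitting of Poisson, NB, and PLN to count vectors.
## NB and PLN are maximized over unconstrained (log mean, log shape) /
## (mu, log sigma2) parameterizations by quasi-Newton; both are initialized
## at the moment-matching inversion of the sample moments.

new_univariate_fit <- function(family, params, moments, loglik, converged, n_iter) {
  structure(
    list(family = family, params = params,
         fitted_moments = moments, loglik = loglik,
         converged = converged, n_iter = n_iter),
    class = "univariate_fit"
  )
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("Univariate %s fit: mean = %.4g, variance = %.4g, loglik = %.4f (%s)\n",
              x$family, x$fitted_moments$mean, x$fitted_moments$variance,
              x$loglik, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

## collapse a count vector to (unique value, multiplicity) for fast likelihoods
count_table <- function(y) {
  u <- sort(unique(y))
  list(u = u, w = tabulate(match(y, u), nbins = length(u)))
}

#' Fit a Poisson distribution by maximum likelihood
#'
#' The MLE of the rate is the sample mean (closed form); the fitted variance
#' equals the fitted mean by construction.
#'
#' @param y nonempty vector of nonnegative integer counts.
#' @return a `univariate_fit` object.
#' @export
fit_poisson <- function(y) {
  check_counts(y)
  rate <- mean(y)
  if (rate <= 0) {
    warning("all counts are zero; Poisson rate floored at 1e-8")
    rate <- 1e-8
  }
  ll <- sum(dpois(y, rate, log = TRUE))
  new_univariate_fit("poisson", poisson_params(rate),
                     list(mean = rate, variance = rate), ll,
                     converged = TRUE, n_iter = 0L)
}

## sample moments with the variance floored just above the mean, used to
## initialize the over-dispersed families
overdispersed_start <- function(y) {
  m <- max(mean(y), 1e-8)
  v <- max(var(y), m * (1 + 1e-6))
  list(mean = m, variance = v)
}

#' Fit a negative binomial distribution by maximum likelihood
#'
#' Maximizes the NB log-likelihood over (log mean, log shape) by BFGS,
#' starting from the moment-matching inversion. On effectively Poisson data
#' the shape is capped at 1e8 and the fitted variance collapses to the mean.
#'
#' @inheritParams fit_poisson
#' @param max_iter iteration cap for the optimizer.
#' @return a `univariate_fit` object.
#' @export
fit_nb <- function(y, max_iter = 500L) {
  check_counts(y)
  tab <- count_table(y)
  start <- overdispersed_start(y)
  alpha0 <- min(start$mean^2 / (start$variance - start$mean), 1e8)
  theta0 <- c(log(start$mean), log(alpha0))
  nll <- function(th) {
    mu <- exp(th[1]); size <- min(exp(th[2]), 1e8)
    -sum(tab$w * dnbinom(tab$u, size = size, mu = mu, log = TRUE))
  }
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  mu <- exp(opt$par[1]); alpha <- min(exp(opt$par[2]), 1e8)
  params <- nb_params(shape = alpha, scale = mu / alpha)
  new_univariate_fit("nb", params, nb_moments(params), -opt$value,
                     converged = opt$convergence == 0L,
                     n_iter = as.integer(opt$counts[["function"]]))
}

#' Fit a Poisson lognormal distribution by maximum likelihood
#'
#' Direct quadrature MLE: the marginal log-likelihood, evaluated with
#' [pln_logpmf()], is maximized over (mu, log sigma2) by BFGS from the
#' moment-matching start. sigma2 is bounded below at 1e-10; at that boundary
#' the fit is effectively the Poisson limit.
#'
#' @inheritParams fit_nb
#' @param offset log-scale offset(s) as in [pln_logpmf()].
#' @param nodes quadrature nodes.
#' @return a `univariate_fit` object.
#' @export
fit_pln <- function(y, offset = 0, max_iter = 500L, nodes = 50L) {
  check_counts(y)
  single_offset <- length(unique(offset)) == 1L
  tab <- if (single_offset) count_table(y) else list(u = y, w = rep(1, length(y)))
  off <- if (single_offset) offset[1] else offset
  start <- overdispersed_start(y)
  p0 <- pln_match_moments(start$mean, start$variance)
  theta0 <- c(p0$mu - mean(off), log(max(p0$sigma2, 1e-8)))
  nll <- function(th) {
    s2 <- max(exp(th[2]), 1e-10)
    -sum(tab$w * pln_logpmf(tab$u, pln_params(th[1], s2), offset = off, nodes = nodes))
  }
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  params <- pln_params(opt$par[1], max(exp(opt$par[2]), 1e-10))
  new_univariate_fit("pln", params, pln_moments(params), -opt$value,
                     converged = opt$convergence == 0L,
                     n_iter = as.integer(opt$counts[["function"]]))
}

#' Percentage relative bias of an estimate
#'
#' `(estimate - truth) / truth * 100`.
#'
#' @param estimate estimated value(s).
#' @param truth nonzero true value.
#' @return relative bias in percent.
#' @export
relative_bias_pct <- function(estimate, truth) {
  stopifnot(is.finite(truth))
  if (truth == 0) stop("relative bias is undefined for truth = 0")
  (estimate - truth) / truth * 100
}

#' Summarize per-replicate relative biases
#'
#' @param estimates vector of per-replicate estimates (>= 2).
#' @param truth nonzero generating value.
#' @return list with `mean_relative_bias_pct`, `sd_relative_bias_pct`,
#'   `n_replicates`.
#' @export
summarize_bias <- function(estimates, truth) {
  if (length(estimates) < 2L) stop("at least 2 replicates are required")
  rb <- relative_bias_pct(estimates, truth)
  list(mean_relative_bias_pct = mean(rb),
       sd_relative_bias_pct = sd(rb),
       n_replicates = length(estimates))
}
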