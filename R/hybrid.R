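## Two-step hybrid refinement of a fitted MPLN mixture.
##
## The variational clustering is treated as final: the MAP partition is
## frozen, and within each cluster the component parameters are re-estimated
## by MCMC on the exact posterior. Latent rows X_i move by random-walk
## Metropolis (scale adapted toward a 0.3 acceptance rate during burn-in);
## (mu_g, Sigma_g) are drawn from their conjugate normal-inverse-Wishart
## conditional given the current latent rows, under a weak prior
## (kappa0 = 0.01, nu0 = d + 2, Psi0 = I, prior mean = the variational
## estimate). The chain starts at the variational estimates.

## unnormalized log posterior of the latent rows, vectorized over rows
latent_logpost_rows <- function(X, Y, O, mu, Sinv) {
  E <- X + O
  Xc <- sweep(X, 2L, mu)
  rowSums(Y * E - exp(E)) - 0.5 * rowSums((Xc %*% Sinv) * Xc)
}

## conjugate NIW draw of (mu, Sigma) given latent rows X
niw_draw <- function(X, m0, kappa0 = 0.01, nu0 = ncol(X) + 2, Psi0 = diag(ncol(X))) {
  m <- nrow(X); d <- ncol(X)
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2L, xbar))
  kn <- kappa0 + m
  nun <- nu0 + m
  mn <- (kappa0 * m0 + m * xbar) / kn
  dev <- xbar - m0
  Psin <- Psi0 + S + (kappa0 * m / kn) * tcrossprod(dev)
  W <- rWishart(1L, df = nun, Sigma = chol2inv(chol(Psin)))[, , 1L]
  Sigma <- chol2inv(chol(W))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- MASS::mvrnorm(1L, mn, Sigma / kn)
  list(mu = as.numeric(mu), Sigma = Sigma)
}

refine_cluster <- function(Y, O, comp, M_init, n_mcmc, burnin) {
  m <- nrow(Y); d <- ncol(Y)
  X <- M_init
  mu <- comp$mu; Sigma <- comp$Sigma
  scale <- 2.4 / sqrt(d) * 0.1
  n_total <- burnin + n_mcmc
  mu_draws <- matrix(NA_real_, n_mcmc, d)
  Sigma_sum <- matrix(0, d, d)
  acc <- 0; acc_n <- 0
  batch_acc <- 0; batch_n <- 0
  for (it in seq_len(n_total)) {
    Sinv <- chol2inv(chol(Sigma))
    lp0 <- latent_logpost_rows(X, Y, O, mu, Sinv)
    Xp <- X + matrix(rnorm(m * d, sd = scale), m, d)
    lp1 <- latent_logpost_rows(Xp, Y, O, mu, Sinv)
    accept <- log(runif(m)) < (lp1 - lp0)
    X[accept, ] <- Xp[accept, , drop = FALSE]
    batch_acc <- batch_acc + sum(accept); batch_n <- batch_n + m
    if (it <= burnin && it %% 20L == 0L) {
      rate <- batch_acc / batch_n
      scale <- scale * exp(rate - 0.3)   # adapt toward 0.3 acceptance
      batch_acc <- 0; batch_n <- 0
    }
    draw <- niw_draw(X, m0 = comp$mu)
    mu <- draw$mu; Sigma <- draw$Sigma
    if (it > burnin) {
      acc <- acc + sum(accept); acc_n <- acc_n + m
      mu_draws[it - burnin, ] <- mu
      Sigma_sum <- Sigma_sum + Sigma
    }
  }
  rate <- acc / max(acc_n, 1L)
  if (rate < 0.05 || rate > 0.7) {
    warning(sprintf("post-adaptation acceptance rate %.2f outside [0.05, 0.7]", rate))
  }
  Sigma_mean <- Sigma_sum / n_mcmc
  list(mu_mean = colMeans(mu_draws),
       mu_ci = apply(mu_draws, 2L, quantile, probs = c(0.025, 0.975)),
       Sigma_mean = (Sigma_mean + t(Sigma_mean)) / 2,
       acceptance_rate = rate,
       mu_draws = mu_draws)
}

#' Hybrid Bayesian refinement of a variational mixture fit
#'
#' Step two of the two-step hybrid procedure: keeps the variational MAP
#' partition fixed and re-estimates each component's `(mu, Sigma)` by MCMC on
#' the exact within-cluster posterior, initialized at the variational
#' estimates. With `n_mcmc = 0` the variational estimates are returned
#' unchanged.
#'
#' @param Y n x d count matrix used in the original fit.
#' @param offsets log offsets used in the original fit.
#' @param fit a converged `mpln_mixture` object.
#' @param n_mcmc number of post-burn-in MCMC iterations (default 500).
#' @param burnin burn-in iterations (default `n_mcmc / 2`).
#' @param seed integer seed.
#' @return an object of class `mpln_hybrid`: `components` (posterior-mean
#'   [mpln_params()] per cluster), `posterior` (per-cluster summaries:
#'   posterior mean and 95% credible intervals for `mu`, posterior mean
#'   `Sigma`, acceptance rate), and the unchanged `labels`.
#' @export
hybrid_refine <- function(Y, offsets = NULL, fit, n_mcmc = 500L,
                          burnin = max(100L, n_mcmc %/% 2L), seed = 1L) {
  stopifnot(inherits(fit, "mpln_mixture"))
  Y <- as.matrix(Y)
  n <- nrow(Y); d <- ncol(Y)
  O <- expand_offsets(offsets, n, d)
  labels <- fit$labels
  if (n_mcmc == 0L) {
    return(structure(list(components = fit$components, posterior = NULL,
                          labels = labels, n_mcmc = 0L),
                     class = "mpln_hybrid"))
  }
  set.seed(derive_seed(seed, 911L))
  components <- vector("list", fit$G)
  posterior <- vector("list", fit$G)
  for (g in seq_len(fit$G)) {
    idx <- which(labels == g)
    if (length(idx) < 2L) {
      warning("cluster ", g, " has fewer than 2 members; kept at variational estimates")
      components[[g]] <- fit$components[[g]]
      next
    }
    res <- refine_cluster(Y[idx, , drop = FALSE], O[idx, , drop = FALSE],
                          fit$components[[g]], fit$vstates[[g]]$M[idx, , drop = FALSE],
                          n_mcmc, burnin)
    components[[g]] <- mpln_params(res$mu_mean, res$Sigma_mean)
    posterior[[g]] <- res
  }
  structure(list(components = components, posterior = posterior,
                 labels = labels, n_mcmc = n_mcmc),
            class = "mpln_hybrid")
}
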