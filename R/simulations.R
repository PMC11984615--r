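## Simulation drivers: univariate mean/variance recovery across generating
## families, NB-vs-PLN quantile comparison, latent-vs-observed Spearman
## correlation mapping, and correlation recovery for uncorrelated and
## correlated multivariate scenarios.

#' The nine univariate simulation scenarios
#'
#' One Poisson scenario (mean = variance = 1000), four negative binomial and
#' four Poisson lognormal scenarios, all with mean 1000 and variances 5000,
#' 10000, 20000, 50000.
#'
#' @return data.frame with columns `scenario`, `distribution`, `mean`,
#'   `variance`.
#' @export
table1_scenarios <- function() {
  data.frame(
    scenario = 1:9,
    distribution = c("poisson", rep("nb", 4), rep("pln", 4)),
    mean = rep(1000, 9),
    variance = c(1000, 5000, 10000, 20000, 50000, 5000, 10000, 20000, 50000)
  )
}

sample_family <- function(distribution, mean, variance, n, seed) {
  switch(distribution,
    poisson = poisson_sample(poisson_params(mean), n, seed = seed),
    nb = nb_sample(nb_match_moments(mean, variance), n, seed = seed),
    pln = pln_sample(pln_match_moments(mean, variance), n, seed = seed),
    stop("unknown generating distribution: ", distribution))
}

#' Univariate mean/variance recovery experiment
#'
#' For each scenario and replicate, generates `n_per_dataset` counts from the
#' stated family, fits the Poisson, NB, and PLN distributions by maximum
#' likelihood, and records the fitted moments and their percentage relative
#' biases. Each replicate uses a seed derived from the master seed, so any
#' subset of the experiment is reproducible in isolation.
#'
#' @param scenarios scenario table as from [table1_scenarios()] (a subset is
#'   allowed).
#' @param n_per_dataset counts per dataset (default 1000).
#' @param n_replicates datasets per scenario (default 100).
#' @param seed master integer seed.
#' @param models families to fit.
#' @return list with `estimates` (tidy per-replicate table) and `summary`
#'   (per scenario x model x quantity: mean and sd of the percentage relative
#'   bias, average estimate, and its standard error across replicates).
#' @export
run_table1 <- function(scenarios = table1_scenarios(), n_per_dataset = 1000L,
                       n_replicates = 100L, seed = 1L,
                       models = c("poisson", "nb", "pln")) {
  fitters <- list(poisson = fit_poisson, nb = fit_nb, pln = fit_pln)[models]
  rows <- vector("list", nrow(scenarios) * n_replicates * length(models))
  k <- 0L
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    for (r in seq_len(n_replicates)) {
      y <- sample_family(sc$distribution, sc$mean, sc$variance, n_per_dataset,
                         seed = derive_seed(seed, sc$scenario, r))
      for (m in names(fitters)) {
        fit <- fitters[[m]](y)
        k <- k + 1L
        rows[[k]] <- data.frame(
          scenario = sc$scenario, distribution = sc$distribution,
          true_mean = sc$mean, true_variance = sc$variance,
          replicate = r, model = m,
          fitted_mean = fit$fitted_moments$mean,
          fitted_variance = fit$fitted_moments$variance,
          converged = fit$converged)
      }
    }
  }
  estimates <- do.call(rbind, rows)
  estimates$bias_mean_pct <- (estimates$fitted_mean - estimates$true_mean) /
    estimates$true_mean * 100
  estimates$bias_variance_pct <- (estimates$fitted_variance - estimates$true_variance) /
    estimates$true_variance * 100
  cells <- unique(estimates[, c("scenario", "model")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    sub <- estimates[estimates$scenario == cells$scenario[j] &
                     estimates$model == cells$model[j], ]
    do.call(rbind, lapply(c("mean", "variance"), function(q) {
      est <- sub[[paste0("fitted_", q)]]
      bias <- sub[[paste0("bias_", q, "_pct")]]
      data.frame(
        scenario = cells$scenario[j], model = cells$model[j], quantity = q,
        true_value = sub[[paste0("true_", q)]][1],
        avg_estimate = mean(est), se_estimate = sd(est) / sqrt(length(est)),
        mean_bias_pct = mean(bias), sd_bias_pct = sd(bias),
        n_replicates = length(est))
    }))
  }))
  rownames(summ) <- NULL
  list(estimates = estimates, summary = summ)
}

#' Empirical quantile comparison of moment-matched NB and PLN samples
#'
#' Draws `n_draws` counts from the NB and the PLN distribution matched to the
#' same target mean and variance and returns paired empirical quantiles. The
#' two distributions agree closely in the body at modest over-dispersion and
#' diverge in the tails as the variance grows.
#'
#' @param mean,variance shared target moments (variance > mean).
#' @param n_draws draws per family.
#' @param probs quantile probabilities.
#' @param seed integer seed.
#' @return data.frame with `prob`, `q_nb`, `q_pln`.
#' @export
qq_compare <- function(mean, variance, n_draws = 1e5,
                       probs = seq(0.001, 0.999, by = 0.001), seed = 1L) {
  y_nb <- nb_sample(nb_match_moments(mean, variance), n_draws,
                    seed = derive_seed(seed, 1L))
  y_pln <- pln_sample(pln_match_moments(mean, variance), n_draws,
                      seed = derive_seed(seed, 2L))
  data.frame(prob = probs,
             q_nb = unname(quantile(y_nb, probs)),
             q_pln = unname(quantile(y_pln, probs)))
}

#' Latent-versus-observed Spearman correlation mapping
#'
#' For a grid of latent correlations, draws bivariate MPLN data with equal
#' margins matched to `(mean, ratio * mean)` and records the Spearman
#' correlation of the latent Gaussian pair and of the observed count pair.
#' The mapping is monotone, preserves zero exactly, and attenuates less as
#' the marginal mean grows.
#'
#' @param mean marginal mean of both coordinates.
#' @param ratio variance/mean ratio of both coordinates.
#' @param rho_grid latent correlations, each in (-1, 1).
#' @param n draws per grid point.
#' @param seed integer seed.
#' @return data.frame with `rho`, `spearman_latent`, `spearman_observed`.
#' @export
correlation_mapping <- function(mean = 50, ratio = 5,
                                rho_grid = seq(-0.99, 0.99, length.out = 41),
                                n = 5000L, seed = 1L) {
  stopifnot(all(abs(rho_grid) <= 0.99))
  marg <- pln_match_moments(mean, ratio * mean)
  out <- lapply(seq_along(rho_grid), function(k) {
    rho <- rho_grid[k]
    sjk <- latent_cov_entry(rho, marg$sigma2, marg$sigma2)
    Sigma <- matrix(c(marg$sigma2, sjk, sjk, marg$sigma2), 2, 2)
    draw <- mpln_sample(mpln_params(rep(marg$mu, 2), Sigma), n,
                        seed = derive_seed(seed, k), latent = TRUE)
    data.frame(rho = rho,
               spearman_latent = cor(draw$X[, 1], draw$X[, 2], method = "spearman"),
               spearman_observed = cor(draw$Y[, 1], draw$Y[, 2], method = "spearman"))
  })
  do.call(rbind, out)
}

#' Generating parameters for the multivariate correlation scenarios
#'
#' Scenarios A-C are uncorrelated: independent Poisson, independent NB, and
#' independent PLN margins. Scenarios D-F are MPLN with all-positive
#' (latent correlation 0.5), all-negative (-0.2), and mixed-sign (+0.5 within
#' two blocks, -0.3 across) latent correlation structures; positive
#' definiteness is verified at construction. All margins have mean `mean`
#' and variance `ratio * mean`.
#'
#' @param scenario one of "A".."F".
#' @param d dimension (default 5).
#' @param mean,ratio marginal mean and variance/mean ratio.
#' @return list with `scenario`, `family`, and either per-margin parameters
#'   (A-C) or an [mpln_params()] object plus the observed-space correlation
#'   truth (D-F; the truth is 0 off-diagonal for A-C).
#' @export
scenario_af_params <- function(scenario, d = 5L, mean = 500, ratio = 10) {
  scenario <- match.arg(scenario, LETTERS[1:6])
  variance <- ratio * mean
  marg <- pln_match_moments(mean, variance)
  if (scenario %in% c("A", "B", "C")) {
    family <- c(A = "poisson", B = "nb", C = "pln")[[scenario]]
    return(list(scenario = scenario, family = family, d = d,
                mean = mean, variance = variance,
                true_cor = diag(d)))
  }
  R <- switch(scenario,
    D = matrix(0.5, d, d),
    E = matrix(-0.2, d, d),
    F = {
      b1 <- seq_len(ceiling(d / 2)); b2 <- setdiff(seq_len(d), b1)
      R <- matrix(-0.3, d, d)
      R[b1, b1] <- 0.5; R[b2, b2] <- 0.5
      R
    })
  diag(R) <- 1
  Sigma <- R * marg$sigma2
  params <- mpln_params(rep(marg$mu, d), Sigma)  # PD verified here
  list(scenario = scenario, family = "mpln", d = d,
       mean = mean, variance = variance, params = params,
       true_cor = mpln_moments(params)$correlation)
}

sample_scenario_af <- function(spec, n, seed) {
  if (spec$family == "mpln") return(mpln_sample(spec$params, n, seed = seed))
  set.seed(seed)
  vapply(seq_len(spec$d), function(j) {
    switch(spec$family,
      poisson = poisson_sample(poisson_params(spec$mean), n),
      nb = nb_sample(nb_match_moments(spec$mean, spec$variance), n),
      pln = pln_sample(pln_match_moments(spec$mean, spec$variance), n))
  }, numeric(n))
}

#' Correlation recovery experiment over the A-F scenarios
#'
#' For each scenario and replicate, generates a count matrix, fits an MPLN
#' distribution by variational EM, and records every estimated off-diagonal
#' observed-space correlation along with its generating truth.
#'
#' @param scenarios subset of "A".."F".
#' @param d dimension.
#' @param n observations per dataset.
#' @param n_replicates datasets per scenario.
#' @param seed master integer seed.
#' @param mean,ratio marginal mean and variance/mean ratio.
#' @return tidy data.frame: `scenario`, `replicate`, `j`, `k`, `est_cor`,
#'   `true_cor`.
#' @export
run_scenarios_AF <- function(scenarios = LETTERS[1:6], d = 5L, n = 1000L,
                             n_replicates = 100L, seed = 1L,
                             mean = 500, ratio = 10) {
  out <- list()
  for (sc in scenarios) {
    spec <- scenario_af_params(sc, d = d, mean = mean, ratio = ratio)
    ut <- which(upper.tri(diag(d)), arr.ind = TRUE)
    for (r in seq_len(n_replicates)) {
      Y <- sample_scenario_af(spec, n, seed = derive_seed(seed, match(sc, LETTERS), r))
      fit <- fit_mpln(Y)
      R <- mpln_moments(fit$params)$correlation
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, replicate = r, j = ut[, 1], k = ut[, 2],
        est_cor = R[ut], true_cor = spec$true_cor[ut])
    }
  }
  do.call(rbind, out)
}
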