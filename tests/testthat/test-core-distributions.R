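test_that("PLN moments: Poisson limit, direct substitution, and sampling agreement", {
  m0 <- pln_moments(pln_params(log(1000), 0))
  expect_equal(m0$mean, 1000)
  expect_equal(m0$variance, 1000)

  m1 <- pln_moments(pln_params(0, 2))
  expect_equal(m1$mean, exp(1))
  expect_equal(m1$variance, exp(1) + exp(2) * (exp(2) - 1))

  p <- pln_match_moments(200, 2000)
  y <- pln_sample(p, 2e5, seed = 42)
  mm <- pln_moments(p)
  se_mean <- sqrt(mm$variance / length(y))
  se_var <- sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(mean(y) - mm$mean), 3 * se_mean)
  expect_lt(abs(var(y) - mm$variance), 3 * se_var)
})

test_that("moment matching inverts the moment formulas for PLN and NB", {
  p <- pln_match_moments(1000, 1000)
  expect_equal(p$mu, log(1000))
  expect_equal(p$sigma2, 0)
  expect_equal(pln_match_moments(1000, 50000)$sigma2, log(1.049))
  expect_error(pln_match_moments(100, 50), "under-dispersed")

  nb <- nb_match_moments(1000, 5000)
  expect_equal(nb$shape, 250)
  expect_equal(nb$scale, 4)
  expect_equal(nb_moments(nb), list(mean = 1000, variance = 5000))
  expect_error(nb_match_moments(10, 10), "variance must exceed")

  # round trips on a grid, to 1e-10 relative error
  for (m in c(0.5, 10, 1000, 5e4)) {
    for (r in c(1.0001, 2, 10, 60)) {
      pp <- pln_moments(pln_match_moments(m, r * m))
      expect_equal(pp$mean, m, tolerance = 1e-10)
      expect_equal(pp$variance, r * m, tolerance = 1e-10)
      nn <- nb_moments(nb_match_moments(m, r * m))
      expect_equal(nn$mean, m, tolerance = 1e-10)
      expect_equal(nn$variance, r * m, tolerance = 1e-10)
    }
  }
})

test_that("PLN log-pmf matches brute-force integration, normalizes, and hits the Poisson branch", {
  # sigma2 = 0 degenerates to the exact Poisson pmf
  expect_equal(pln_logpmf(0:20, pln_params(log(7), 0)),
               dpois(0:20, 7, log = TRUE), tolerance = 1e-14)

  expect_equal(pln_logpmf(0, pln_params(0, 1)),
               pln_logpmf_oracle(0, 0, 1), tolerance = 1e-8)

  ys <- c(0, 1, 5, 20, 80, 200)
  expect_equal(pln_logpmf(ys, pln_params(log(30), 0.4)),
               pln_logpmf_oracle(ys, log(30), 0.4), tolerance = 1e-8)

  # offsets shift the latent exponent
  expect_equal(pln_logpmf(ys, pln_params(log(30), 0.4), offset = 0.7),
               pln_logpmf_oracle(ys, log(30), 0.4, offset = 0.7),
               tolerance = 1e-8)

  # pmf sums to 1; the support bound follows the lognormal mixing tail
  # (heavier than Gaussian, so a quantile-based cutoff is used)
  p <- pln_params(log(50), 0.5)
  ymax <- ceiling(2 * qlnorm(1 - 1e-9, p$mu, sqrt(p$sigma2))) + 100
  expect_equal(sum(exp(pln_logpmf(0:ymax, p))), 1, tolerance = 1e-6)

  # self-check: 10x the node count changes nothing material
  p2 <- pln_match_moments(1000, 20000)
  ys2 <- c(200, 600, 1000, 1500, 3000)
  expect_equal(pln_logpmf(ys2, p2), pln_logpmf(ys2, p2, nodes = 500L),
               tolerance = 1e-9)

  expect_error(pln_logpmf(-1, p), "negative")
  expect_error(pln_logpmf(2.5, p), "non-integer")
})

test_that("hierarchical samplers are seed-reproducible and hit the Poisson limit", {
  p <- pln_match_moments(100, 500)
  expect_identical(pln_sample(p, 100, seed = 9), pln_sample(p, 100, seed = 9))
  nb <- nb_match_moments(100, 500)
  expect_identical(nb_sample(nb, 100, seed = 9), nb_sample(nb, 100, seed = 9))

  # sigma2 = 0 draws are distributionally Poisson(e^mu)
  y <- pln_sample(pln_params(log(20), 0), 1e5, seed = 11)
  brk <- c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), 20), Inf)
  obs <- table(cut(y, brk))
  expp <- diff(ppois(c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), 20), Inf), 20)) * 1e5
  pval <- pchisq(sum((obs - expp)^2 / expp), df = length(obs) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("MPLN moments: closed forms, univariate reduction, zero mapping, sampling", {
  # diagonal latent covariance gives exactly zero observed covariance
  pd <- mpln_params(c(1, 2, 3), diag(c(0.3, 0.2, 0.1)))
  md <- mpln_moments(pd)
  expect_true(all(md$covariance[upper.tri(md$covariance)] == 0))

  # d = 1 reduces to the univariate moments
  p1 <- mpln_params(2, matrix(0.5, 1, 1))
  u <- pln_moments(pln_params(2, 0.5))
  m1 <- mpln_moments(p1)
  expect_equal(as.numeric(m1$mean), u$mean)
  expect_equal(as.numeric(m1$covariance), u$variance)

  # empirical agreement for a d = 3 mixed-sign covariance
  S <- matrix(c(0.3, 0.1, -0.08,
                0.1, 0.25, 0.05,
                -0.08, 0.05, 0.2), 3, 3)
  p <- mpln_params(log(c(50, 120, 80)), S)
  Y <- mpln_sample(p, 2e5, seed = 5)
  mm <- mpln_moments(p)
  expect_equal(colMeans(Y), mm$mean, tolerance = 0.02)
  emp <- cov(Y)
  for (j in 1:2) for (k in (j + 1):3) {
    se <- sd((Y[, j] - mean(Y[, j])) * (Y[, k] - mean(Y[, k]))) / sqrt(nrow(Y))
    expect_lt(abs(emp[j, k] - mm$covariance[j, k]), 3 * se)
  }

  expect_identical(mpln_sample(p, 50, seed = 3), mpln_sample(p, 50, seed = 3))
})

test_that("latent covariance entries invert and reproduce the observed correlation form", {
  expect_equal(latent_cov_entry(0, 2, 2), 0)
  expect_equal(latent_cov_entry(0.5, 4, 1), 1)
  expect_error(latent_cov_entry(1, 1, 1), "strictly inside")

  # round-trip recovery of the latent correlation
  sjj <- 0.7; skk <- 1.3
  for (rho in c(-0.9, -0.2, 0.33, 0.8)) {
    sjk <- latent_cov_entry(rho, sjj, skk)
    expect_equal(sjk / sqrt(sjj * skk), rho, tolerance = 1e-12)
  }

  # induced observed correlation obeys the closed form
  sjk <- latent_cov_entry(0.9, 0.683, 0.683)
  expect_equal(sjk, 0.9 * 0.683)
  mu <- c(3, 3.5)
  Sg <- matrix(c(0.683, sjk, sjk, 0.683), 2, 2)
  mm <- mpln_moments(mpln_params(mu, Sg))
  expected <- (exp(sjk) - 1) /
    sqrt((exp(0.683) - 1 + 1 / mm$mean[1]) * (exp(0.683) - 1 + 1 / mm$mean[2]))
  expect_equal(mm$correlation[1, 2], expected, tolerance = 1e-12)
})

test_that("over-dispersion identity, attenuation, and sign preservation hold on a random grid", {
  set.seed(202)
  for (rep in 1:25) {
    mu <- runif(1, -1, 7); s2 <- runif(1, 0, 2.5)
    mm <- pln_moments(pln_params(mu, s2))
    expect_equal(mm$variance - mm$mean, mm$mean^2 * (exp(s2) - 1), tolerance = 1e-12)
  }
  for (rep in 1:25) {
    d <- sample(2:5, 1)
    A <- matrix(rnorm(d * d, sd = 0.4), d, d)
    Sigma <- crossprod(A) + diag(0.05, d)
    mu <- runif(d, 0, 6)
    mm <- mpln_moments(mpln_params(mu, Sigma))
    off <- upper.tri(Sigma)
    # attenuation: the observed correlation is strictly smaller in magnitude
    # than the latent correlation (the observed-space range is narrower)
    Rx <- cov2cor(Sigma)
    expect_true(all(abs(mm$correlation[off]) < abs(Rx[off]) | Rx[off] == 0))
    # sign preservation, with exact zero mapped to exact zero
    expect_identical(sign(mm$covariance[off]), sign(Sigma[off]))
  }
})
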