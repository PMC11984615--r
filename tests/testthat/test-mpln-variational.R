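test_that("ELBO degenerates to the Poisson log-likelihood in the zero-variance limit", {
  set.seed(61)
  mu <- log(40)
  y <- matrix(rpois(30, exp(mu)), ncol = 1)
  eps <- 1e-9
  vs <- variational_state(matrix(mu, 30, 1), matrix(eps, 30, 1))
  e <- elbo(y, mpln_params(mu, matrix(eps, 1, 1)), vs)
  expect_equal(e, sum(dpois(y, exp(mu), log = TRUE)), tolerance = 1e-4)
})

test_that("ELBO is a true lower bound on the quadrature log-likelihood (d = 1)", {
  set.seed(62)
  for (rep in 1:8) {
    mu <- runif(1, 0, 4); s2 <- runif(1, 0.1, 1.5)
    y <- matrix(pln_sample(pln_params(mu, s2), 25), ncol = 1)
    ll <- sum(pln_logpmf(as.numeric(y), pln_params(mu, s2)))
    params <- mpln_params(mu, matrix(s2, 1, 1))
    vs0 <- variational_state(log(y + 0.5), matrix(0.1, 25, 1))
    expect_lte(elbo(y, params, vs0), ll + 1e-8)
    vs1 <- update_variational(y, params, vs0)
    expect_lte(elbo(y, params, vs1), ll + 1e-8)
    expect_gte(elbo(y, params, vs1), elbo(y, params, vs0) - 1e-8)
  }
})

test_that("ELBO gradients in the variational parameters match central differences", {
  set.seed(63)
  n <- 6; d <- 3
  Sigma <- crossprod(matrix(rnorm(9, sd = 0.4), 3)) + diag(0.1, 3)
  params <- mpln_params(c(2, 3, 2.5), Sigma)
  Y <- mpln_sample(params, n, seed = 64)
  M <- log(Y + 0.5); S2 <- matrix(0.2, n, d)
  Sinv <- solve(Sigma)
  A <- exp(M + S2 / 2)
  gM <- Y - A - sweep(M, 2L, params$mu) %*% Sinv
  gS2 <- -A / 2 - matrix(diag(Sinv), n, d, byrow = TRUE) / 2 + 1 / (2 * S2)
  h <- 1e-5
  for (idx in list(c(2, 1), c(5, 3), c(1, 2))) {
    i <- idx[1]; j <- idx[2]
    Mp <- M; Mp[i, j] <- M[i, j] + h
    Mm <- M; Mm[i, j] <- M[i, j] - h
    num <- (elbo(Y, params, variational_state(Mp, S2)) -
            elbo(Y, params, variational_state(Mm, S2))) / (2 * h)
    expect_equal(num, gM[i, j], tolerance = 1e-5)
    Sp <- S2; Sp[i, j] <- S2[i, j] + h
    Sm <- S2; Sm[i, j] <- S2[i, j] - h
    num2 <- (elbo(Y, params, variational_state(M, Sp)) -
             elbo(Y, params, variational_state(M, Sm))) / (2 * h)
    expect_equal(num2, gS2[i, j], tolerance = 1e-4)
  }
})

test_that("variational update is stationary at an optimum and ascends from a perturbation", {
  set.seed(65)
  params <- mpln_params(c(3, 4), matrix(c(0.3, 0.1, 0.1, 0.4), 2))
  Y <- mpln_sample(params, 40, seed = 66)
  vs <- update_variational(Y, params, variational_state(log(Y + 0.5), matrix(0.1, 40, 2)))
  for (k in 1:5) vs <- update_variational(Y, params, vs)
  e_opt <- elbo(Y, params, vs)
  # stationary: a further update changes essentially nothing
  vs2 <- update_variational(Y, params, vs)
  expect_equal(elbo(Y, params, vs2), e_opt, tolerance = 1e-9)
  expect_equal(vs2$M, vs$M, tolerance = 1e-4)
  # perturbed state strictly improves in one pass
  vsp <- variational_state(vs$M + 0.3, vs$S2 * 2)
  e_pert <- elbo(Y, params, vsp)
  vsr <- update_variational(Y, params, vsp)
  expect_gt(elbo(Y, params, vsr), e_pert)
})

test_that("the model update is the exact maximizer given the variational state", {
  # identical rows: mu = m, Sigma = c I (+ridge)
  M <- matrix(rep(c(1, 2), each = 5), 5, 2)
  vs <- variational_state(M, matrix(0.3, 5, 2))
  p <- update_model(vs)
  expect_equal(p$mu, c(1, 2))
  expect_equal(p$Sigma, diag(0.3, 2), tolerance = 1e-6)

  # one-hot weights reproduce that row's statistics
  set.seed(67)
  M2 <- matrix(rnorm(10), 5, 2); S22 <- matrix(runif(10, 0.1, 0.5), 5, 2)
  w <- c(0, 0, 1, 0, 0)
  p2 <- update_model(variational_state(M2, S22), w)
  expect_equal(p2$mu, M2[3, ])
  expect_equal(diag(p2$Sigma), S22[3, ] * (1 + 1e-8) + 1e-8 * mean(S22[3, ]),
               tolerance = 1e-6)

  # no perturbation of (mu, Sigma) improves the ELBO
  params <- mpln_params(c(2.5, 3.5), diag(c(0.4, 0.3)))
  Y <- mpln_sample(params, 60, seed = 68)
  vs3 <- update_variational(Y, params, variational_state(log(Y + 0.5), matrix(0.1, 60, 2)))
  opt <- update_model(vs3)
  e_opt <- elbo(Y, opt, vs3)
  for (k in 1:6) {
    dmu <- rnorm(2, sd = 0.02)
    dS <- crossprod(matrix(rnorm(4, sd = 0.02), 2))
    cand <- mpln_params(opt$mu + dmu, opt$Sigma + dS)
    expect_lte(elbo(Y, cand, vs3), e_opt + 1e-10)
  }
})

test_that("the ELBO at convergence is tight for well-concentrated bivariate data", {
  set.seed(69)
  Sigma <- matrix(c(0.08, 0.03, 0.03, 0.08), 2)
  params <- mpln_params(log(c(1000, 1200)), Sigma)
  Y <- mpln_sample(params, 50, seed = 70)
  fit <- fit_mpln(Y)
  ll <- mpln_loglik_2d_oracle(Y, fit$params$mu, fit$params$Sigma)
  gap <- ll - fit$elbo
  expect_gte(gap, -1e-6)        # a genuine lower bound
  expect_lt(gap, 0.5)           # and a tight one at high counts
})

test_that("variational EM recovers MPLN parameters and is ELBO-monotone", {
  mu <- log(c(500, 300, 800, 200))
  S <- diag(c(0.3, 0.2, 0.25, 0.35))
  S[1, 2] <- S[2, 1] <- 0.15; S[3, 4] <- S[4, 3] <- -0.12; S[1, 3] <- S[3, 1] <- 0.1
  params <- mpln_params(mu, S)
  Y <- mpln_sample(params, 2000, seed = 71)
  fit <- fit_mpln(Y)
  expect_true(fit$converged)
  tr <- fit$elbo_trace
  expect_true(all(diff(tr) > -1e-8 * (abs(tr[-1]) + 1)))
  est <- mpln_moments(fit$params)$correlation
  tru <- mpln_moments(params)$correlation
  expect_lt(max(abs(est - tru)), 0.1)
  expect_lt(max(abs(fit$params$mu - mu)), 0.1)
})

test_that("offsets act as equivariant shifts of the latent mean", {
  params <- mpln_params(log(c(100, 250)), matrix(c(0.3, 0.08, 0.08, 0.2), 2))
  Y <- mpln_sample(params, 600, seed = 72)
  f0 <- fit_mpln(Y, offsets = 0)
  f1 <- fit_mpln(Y, offsets = 1.3)
  expect_equal(f1$params$mu, f0$params$mu - 1.3, tolerance = 1e-3)
  expect_equal(f1$params$Sigma, f0$params$Sigma, tolerance = 1e-3)
})

test_that("a univariate variational fit agrees with the quadrature MLE", {
  p <- pln_match_moments(1000, 10000)
  y <- pln_sample(p, 1e4, seed = 73)
  fv <- fit_mpln(matrix(y, ncol = 1))
  fq <- fit_pln(y)
  mv <- pln_moments(pln_params(fv$params$mu, fv$params$Sigma[1, 1]))
  expect_equal(mv$mean, fq$fitted_moments$mean, tolerance = 0.02)
  expect_equal(mv$variance, fq$fitted_moments$variance, tolerance = 0.02)
})
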