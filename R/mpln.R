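## Variational Gaussian fitting of a single MPLN distribution.
##
## The latent posterior of each row X_i | Y_i is approximated by
## N(m_i, diag(s_i^2)) (a diagonal approximating covariance: the objective
## then separates over rows and entries, and the fit scales as n * d).
## Model parameters and variational parameters are updated in alternation;
## each step does not decrease the evidence lower bound (ELBO).

#' Construct a variational state
#'
#' Per-observation approximating-Gaussian means `M` and variances `S2`,
#' both n x d with `S2 > 0`.
#'
#' @param M n x d matrix of variational means.
#' @param S2 n x d matrix of positive variational variances.
#' @return an object of class `variational_state`.
#' @export
variational_state <- function(M, S2) {
  M <- as.matrix(M); S2 <- as.matrix(S2)
  stopifnot(all(dim(M) == dim(S2)), all(is.finite(M)), all(S2 > 0))
  structure(list(M = M, S2 = S2), class = "variational_state")
}

## per-row ELBO contributions J_i (length n):
##   J_i = sum_j [ y_ij (o_ij + m_ij) - e^{o_ij + m_ij + s_ij^2/2} - log y_ij! ]
##         - KL( N(m_i, diag(s_i^2)) || N(mu, Sigma) )
elbo_rows <- function(Y, O, params, M, S2, Sinv = NULL, ldet = NULL) {
  mu <- params$mu; Sigma <- params$Sigma
  d <- length(mu)
  if (is.null(Sinv)) Sinv <- chol2inv(chol(Sigma))
  if (is.null(ldet)) ldet <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  A <- exp(O + M + S2 / 2)
  pois <- rowSums(Y * (O + M) - A - lgamma(Y + 1))
  Mc <- sweep(M, 2L, mu)
  quad <- rowSums((Mc %*% Sinv) * Mc)
  trc <- S2 %*% diag(Sinv)
  kl <- 0.5 * (as.numeric(trc) + quad - d + ldet - rowSums(log(S2)))
  pois - kl
}

#' Evidence lower bound for an MPLN model and variational state
#'
#' The variational objective: expected complete-data log-likelihood under the
#' row-wise Gaussian approximating densities minus their KL divergence from
#' the latent prior. Always a lower bound on the marginal log-likelihood.
#'
#' @param Y n x d count matrix.
#' @param params an [mpln_params()] object.
#' @param vstate a [variational_state()].
#' @param offsets log offsets (scalar, per-row, or n x d).
#' @return scalar ELBO value.
#' @export
elbo <- function(Y, params, vstate, offsets = NULL) {
  Y <- as.matrix(Y)
  stopifnot(inherits(params, "mpln_params"), inherits(vstate, "variational_state"))
  O <- expand_offsets(offsets, nrow(Y), ncol(Y))
  sum(elbo_rows(Y, O, params, vstate$M, vstate$S2))
}

#' Optimize the variational parameters for fixed model parameters
#'
#' Ascends the ELBO over all rows' `(m_i, log s_i^2)` jointly (the objective
#' separates over rows) with analytic gradients and a bounded number of
#' quasi-Newton iterations. Rows whose bound would decrease (a failed line
#' search in the shared optimizer) retain their previous state.
#'
#' @inheritParams elbo
#' @param max_iter inner iteration cap (default 50).
#' @return an updated [variational_state()].
#' @export
update_variational <- function(Y, params, vstate, offsets = NULL, max_iter = 50L) {
  Y <- as.matrix(Y)
  n <- nrow(Y); d <- ncol(Y)
  O <- expand_offsets(offsets, n, d)
  Sinv <- chol2inv(chol(params$Sigma))
  ldet <- as.numeric(determinant(params$Sigma, logarithm = TRUE)$modulus)
  mu <- params$mu
  dSinv <- diag(Sinv)

  obj <- function(th) {
    M <- matrix(th[seq_len(n * d)], n, d)
    S2 <- exp(matrix(th[n * d + seq_len(n * d)], n, d))
    -sum(elbo_rows(Y, O, params, M, S2, Sinv, ldet))
  }
  grad <- function(th) {
    M <- matrix(th[seq_len(n * d)], n, d)
    S2 <- exp(matrix(th[n * d + seq_len(n * d)], n, d))
    A <- exp(O + M + S2 / 2)
    gM <- Y - A - sweep(M, 2L, mu) %*% Sinv
    gS2 <- -A / 2 - matrix(dSinv, n, d, byrow = TRUE) / 2 + 1 / (2 * S2)
    -c(gM, gS2 * S2)  # chain rule for log s^2
  }
  th0 <- c(vstate$M, log(vstate$S2))
  opt <- optim(th0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  M1 <- matrix(opt$par[seq_len(n * d)], n, d)
  S21 <- exp(matrix(opt$par[n * d + seq_len(n * d)], n, d))
  ## per-row monotonicity guard
  j0 <- elbo_rows(Y, O, params, vstate$M, vstate$S2, Sinv, ldet)
  j1 <- elbo_rows(Y, O, params, M1, S21, Sinv, ldet)
  worse <- j1 < j0
  if (any(worse)) {
    M1[worse, ] <- vstate$M[worse, , drop = FALSE]
    S21[worse, ] <- vstate$S2[worse, , drop = FALSE]
  }
  variational_state(M1, S21)
}

#' Closed-form model update from a variational state
#'
#' Weighted M-step: `mu` is the weighted mean of the variational means and
#' `Sigma` the weighted mean of `(m_i - mu)(m_i - mu)' + diag(s_i^2)`, with a
#' small ridge (`1e-8 * trace/d` on the diagonal) guaranteeing positive
#' definiteness. Weights are 1 for single-distribution fitting and
#' responsibilities inside mixtures.
#'
#' @param vstate a [variational_state()].
#' @param weights per-row nonnegative weights with positive sum.
#' @return an [mpln_params()] object.
#' @export
update_model <- function(vstate, weights = NULL) {
  M <- vstate$M; S2 <- vstate$S2
  n <- nrow(M); d <- ncol(M)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  W <- sum(weights)
  if (W <= 0) stop("weights must have a positive sum")
  mu <- as.numeric(colSums(M * weights) / W)
  Mc <- sweep(M, 2L, mu)
  Sigma <- crossprod(Mc * weights, Mc) / W + diag(colSums(S2 * weights) / W, d)
  Sigma <- (Sigma + t(Sigma)) / 2
  diag(Sigma) <- diag(Sigma) + 1e-8 * sum(diag(Sigma)) / d
  mpln_params(mu, Sigma)
}

#' Fit an MPLN distribution by variational EM
#'
#' Alternates [update_variational()] and [update_model()] until the relative
#' ELBO change falls below `tol` or `max_iter` sweeps. Variational means are
#' initialized at `log(y + 0.5) - offset` and variances at 0.1.
#'
#' @param Y n x d nonnegative integer count matrix.
#' @param offsets log offsets (scalar, per-row vector, or n x d matrix).
#' @param init optional [mpln_params()] starting value.
#' @param tol relative ELBO convergence tolerance (default 1e-6).
#' @param max_iter maximum outer sweeps (default 1000).
#' @return an object of class `mpln_fit`: `params`, `vstate`, `elbo_trace`,
#'   `elbo`, `converged`, `n_iter`.
#' @export
fit_mpln <- function(Y, offsets = NULL, init = NULL, tol = 1e-6, max_iter = 1000L) {
  Y <- as.matrix(Y)
  check_counts(Y, "Y")
  n <- nrow(Y); d <- ncol(Y)
  if (n <= d) warning("fewer observations than dimensions + 1; covariance estimate may be unstable")
  O <- expand_offsets(offsets, n, d)
  vs <- variational_state(log(Y + 0.5) - O, matrix(0.1, n, d))
  params <- if (is.null(init)) update_model(vs) else init
  trace <- -Inf
  for (it in seq_len(max_iter)) {
    vs <- update_variational(Y, params, vs, O)
    params <- update_model(vs)
    e <- sum(elbo_rows(Y, O, params, vs$M, vs$S2))
    trace <- c(trace, e)
    if (abs(e - trace[length(trace) - 1L]) <
        tol * (abs(e) + 1e-3)) break
  }
  converged <- it < max_iter ||
    abs(diff(utils::tail(trace, 2L))) < tol * (abs(trace[length(trace)]) + 1e-3)
  if (!converged) warning("fit_mpln did not converge in ", max_iter, " sweeps")
  structure(list(params = params, vstate = vs,
                 elbo_trace = trace[-1L], elbo = trace[length(trace)],
                 converged = converged, n_iter = it),
            class = "mpln_fit")
}

#' @export
print.mpln_fit <- function(x, ...) {
  d <- length(x$params$mu)
  cat(sprintf("MPLN variational fit: d = %d, ELBO = %.4f, %d sweeps (%s)\n",
              d, x$elbo, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
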