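## Finite mixtures of MPLN distributions fitted by variational EM.
##
## Each component carries its own variational state; responsibilities are
## computed from the per-observation, per-component ELBO contributions J_ig
## (the standard variational surrogate for the intractable component
## densities). The mixture bound sum_i log sum_g pi_g exp(J_ig) is
## nondecreasing across sweeps and doubles as the likelihood surrogate in BIC.

## n x G matrix of per-component row bounds J_ig
mixture_J <- function(Y, O, components, vstates) {
  G <- length(components)
  J <- matrix(0, nrow(Y), G)
  for (g in seq_len(G)) {
    J[, g] <- elbo_rows(Y, O, components[[g]], vstates[[g]]$M, vstates[[g]]$S2)
  }
  J
}

#' E-step: responsibilities from mixture weights and per-component bounds
#'
#' `z_ig` is proportional to `pi_g exp(J_ig)` where `J_ig` is the row's ELBO
#' contribution under component `g`; rows are normalized with log-sum-exp
#' stabilization. A row whose bounds are all `-Inf` gets uniform
#' responsibilities with a warning.
#'
#' @param Y n x d count matrix.
#' @param offsets log offsets.
#' @param pi mixture weights (simplex).
#' @param components list of [mpln_params()].
#' @param vstates list of per-component [variational_state()].
#' @return n x G responsibility matrix with unit row sums.
#' @export
e_step <- function(Y, offsets, pi, components, vstates) {
  Y <- as.matrix(Y)
  O <- expand_offsets(offsets, nrow(Y), ncol(Y))
  J <- mixture_J(Y, O, components, vstates)
  lz <- sweep(J, 2L, log(pi), "+")
  bad <- !is.finite(apply(lz, 1L, max))
  if (any(bad)) {
    warning(sum(bad), " observation(s) had degenerate bounds; uniform responsibilities assigned")
    lz[bad, ] <- 0
  }
  z <- exp(lz - apply(lz, 1L, max))
  z / rowSums(z)
}

#' M-step: mixture weights and component parameters from responsibilities
#'
#' `pi_g = sum_i z_ig / n`; each component is refit by [update_model()] with
#' weights `z_ig`. A component with fewer than `d + 1` effective observations
#' gets an inflated diagonal ridge to keep its covariance well-conditioned.
#'
#' @param Y n x d count matrix (used only for dimension checks).
#' @param resp n x G responsibility matrix.
#' @param vstates list of per-component [variational_state()].
#' @return list with elements `pi` and `components`.
#' @export
m_step <- function(Y, resp, vstates) {
  n <- nrow(resp); G <- ncol(resp)
  d <- ncol(vstates[[1L]]$M)
  pi <- colSums(resp) / n
  components <- vector("list", G)
  for (g in seq_len(G)) {
    w <- resp[, g]
    comp <- update_model(vstates[[g]], w)
    if (sum(w) < d + 1) {
      warning("component ", g, " has fewer than d + 1 effective observations; ridge inflated")
      Sg <- comp$Sigma
      diag(Sg) <- diag(Sg) + 1e-2 * sum(diag(Sg)) / d
      comp <- mpln_params(comp$mu, Sg)
    }
    components[[g]] <- comp
  }
  list(pi = pi, components = components)
}

#' BIC of a fitted MPLN mixture
#'
#' `-2 * l + p * log(n)` where `l` is the ELBO-based surrogate
#' `sum_i log sum_g pi_g exp(J_ig)` and
#' `p = (G - 1) + G d + G d (d + 1) / 2`. Smaller is better.
#'
#' @param fit an `mpln_mixture` fit.
#' @param n number of observations (defaults to the fitted data size).
#' @return scalar BIC value.
#' @export
bic <- function(fit, n = nrow(fit$resp)) {
  stopifnot(inherits(fit, "mpln_mixture"))
  d <- length(fit$components[[1L]]$mu)
  p <- (fit$G - 1) + fit$G * d + fit$G * d * (d + 1) / 2
  -2 * fit$loglik_surrogate + p * log(n)
}

#' MAP cluster assignment from responsibilities
#'
#' Row-wise argmax; ties resolve to the lowest component index.
#'
#' @param resp n x G responsibility matrix.
#' @return integer label vector in 1..G.
#' @export
map_assign <- function(resp) {
  apply(as.matrix(resp), 1L, which.max)
}

## one EM run from an initial hard assignment
mixture_em <- function(Y, O, init_labels, G, tol, max_iter, inner_iter = 50L) {
  n <- nrow(Y); d <- ncol(Y)
  M0 <- log(Y + 0.5) - O
  vstates <- lapply(seq_len(G), function(g) variational_state(M0, matrix(0.1, n, d)))
  resp <- matrix(0, n, G)
  resp[cbind(seq_len(n), init_labels)] <- 1
  resp <- pmax(resp, 1e-3)          # soften: every component sees every row
  resp <- resp / rowSums(resp)
  ms <- m_step(Y, resp, vstates)
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    for (g in seq_len(G)) {
      vstates[[g]] <- update_variational(Y, ms$components[[g]], vstates[[g]], O,
                                         max_iter = inner_iter)
    }
    resp <- e_step(Y, O, ms$pi, ms$components, vstates)
    ms <- m_step(Y, resp, vstates)
    J <- mixture_J(Y, O, ms$components, vstates)
    ll <- sum(row_logsumexp(sweep(J, 2L, log(ms$pi), "+")))
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(ll) + 1e-3)) break
    prev <- ll
  }
  list(pi = ms$pi, components = ms$components, vstates = vstates,
       resp = resp, trace = trace, loglik_surrogate = trace[length(trace)],
       converged = it < max_iter, n_iter = it)
}

#' Fit a G-component mixture of MPLN distributions
#'
#' Runs variational EM from `n_starts` k-means initializations on
#' `log(Y + 0.5) - offsets` (per-start seeds derived from `seed`) and keeps
#' the run with the best mixture bound. Components are reported in order of
#' decreasing mixing weight.
#'
#' @param Y n x d nonnegative integer count matrix.
#' @param offsets log offsets (scalar, per-row, or n x d).
#' @param G number of components.
#' @param n_starts number of random initializations (default 10).
#' @param seed master integer seed.
#' @param tol relative convergence tolerance on the mixture bound.
#' @param max_iter maximum EM sweeps per start.
#' @return an object of class `mpln_mixture`: `G`, `pi`, `components`,
#'   `vstates`, `resp`, `labels`, `elbo` (the mixture bound),
#'   `loglik_surrogate`, `bic`, `elbo_trace`, `converged`.
#' @export
fit_mixture <- function(Y, offsets = NULL, G, n_starts = 10L, seed = 1L,
                        tol = 1e-6, max_iter = 200L) {
  Y <- as.matrix(Y)
  check_counts(Y, "Y")
  n <- nrow(Y); d <- ncol(Y)
  stopifnot(G >= 1L, G < n)
  O <- expand_offsets(offsets, n, d)
  L <- log(Y + 0.5) - O
  best <- NULL
  failures <- character(0)
  for (s in seq_len(n_starts)) {
    init <- tryCatch({
      set.seed(derive_seed(seed, G, s))
      if (G == 1L) rep(1L, n) else kmeans(L, centers = G, nstart = 1L)$cluster
    }, error = function(e) sample(seq_len(G), n, replace = TRUE))
    run <- tryCatch(
      mixture_em(Y, O, init, G, tol, max_iter),
      error = function(e) e
    )
    if (inherits(run, "error")) {
      failures <- c(failures, sprintf("start %d: %s", s, conditionMessage(run)))
      next
    }
    if (is.null(best) || run$loglik_surrogate > best$loglik_surrogate) best <- run
  }
  if (is.null(best)) {
    stop("all starts failed:\n", paste(failures, collapse = "\n"))
  }
  ord <- order(best$pi, decreasing = TRUE)
  fit <- structure(
    list(G = G, pi = best$pi[ord], components = best$components[ord],
         vstates = best$vstates[ord], resp = best$resp[, ord, drop = FALSE],
         elbo_trace = best$trace, elbo = best$loglik_surrogate,
         loglik_surrogate = best$loglik_surrogate,
         converged = best$converged, seed = seed),
    class = "mpln_mixture")
  fit$labels <- map_assign(fit$resp)
  fit$bic <- bic(fit, n)
  fit
}

#' @export
print.mpln_mixture <- function(x, ...) {
  cat(sprintf("MPLN mixture: G = %d, pi = (%s), BIC = %.2f\n",
              x$G, paste(sprintf("%.3f", x$pi), collapse = ", "), x$bic))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits a mixture for every G in `G_range` and keeps the BIC minimizer among
#' fits that succeeded; ties break toward the smaller G.
#'
#' @inheritParams fit_mixture
#' @param G_range integer vector of component counts to try.
#' @return an object of class `mpln_model_selection`: `fits` (one per G,
#'   `NULL` on failure), `bic_table`, `chosen_G`, `best`.
#' @export
select_model <- function(Y, offsets = NULL, G_range = 1:5, n_starts = 10L,
                         seed = 1L, tol = 1e-6, max_iter = 200L) {
  G_range <- sort(unique(as.integer(G_range)))
  fits <- setNames(vector("list", length(G_range)), paste0("G", G_range))
  bics <- rep(NA_real_, length(G_range))
  for (k in seq_along(G_range)) {
    fits[[k]] <- tryCatch(
      fit_mixture(Y, offsets, G = G_range[k], n_starts = n_starts,
                  seed = seed, tol = tol, max_iter = max_iter),
      error = function(e) {
        warning("G = ", G_range[k], " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fits[[k]])) bics[k] <- fits[[k]]$bic
  }
  if (all(is.na(bics))) stop("no mixture fit succeeded over G_range")
  k_best <- which(bics == min(bics, na.rm = TRUE))[1L]  # ties -> smaller G
  structure(
    list(fits = fits,
         bic_table = data.frame(G = G_range, bic = bics),
         chosen_G = G_range[k_best], best = fits[[k_best]]),
    class = "mpln_model_selection")
}

#' @export
print.mpln_model_selection <- function(x, ...) {
  cat("MPLN mixture model selection (BIC):\n")
  print(x$bic_table, row.names = FALSE)
  cat("chosen G =", x$chosen_G, "\n")
  invisible(x)
}
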