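## Between-sample normalization factors and their conversion to log offsets
## for the latent exponent of the (M)PLN models. Orientation throughout:
## rows = samples, columns = features.

#' Trimmed-mean-of-M-values (TMM) effective normalization factors
#'
#' The canonical TMM recipe: the reference sample is the one whose
#' upper-quartile of library-size-scaled counts is closest to the mean upper
#' quartile; each sample's composition factor is the exponential of the
#' precision-weighted mean of the log-ratios (M-values) against the
#' reference, after two-sided trimming of 30% of the M-values and 5% of the
#' A-values, over features positive in both samples. Precision weights come
#' from the binomial (delta-method) variance of M.
#'
#' Convention: the returned factor combines the composition factor with the
#' library size (`factor_s` is proportional to `libsize_s * TMM_s`) and the
#' vector is rescaled to geometric mean 1, so `log(factors)` can be used
#' directly as per-sample offsets jointly identifiable with the latent mean.
#' A sample with doubled counts therefore gets (about) twice the factor.
#'
#' @param Y samples x features nonnegative integer count matrix (>= 2 rows).
#' @param trim_M,trim_A two-sided trim fractions for M- and A-values.
#' @return per-sample positive factors with geometric mean 1.
#' @export
tmm_factors <- function(Y, trim_M = 0.30, trim_A = 0.05) {
  Y <- as.matrix(Y)
  check_counts(Y, "Y")
  n <- nrow(Y)
  if (n < 2L) stop("TMM requires at least 2 samples")
  lib <- rowSums(Y)
  if (any(lib == 0)) stop("every sample must contain at least one positive count")
  uq <- apply(sweep(Y, 1L, lib, "/"), 1L, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  yr <- Y[ref, ]; Nr <- lib[ref]
  comp <- vapply(seq_len(n), function(s) {
    if (s == ref) return(1)
    ys <- Y[s, ]; Ns <- lib[s]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) stop("sample ", s, " shares no positive feature with the reference")
    ps <- ys[ok] / Ns; pr <- yr[ok] / Nr
    M <- log(ps / pr)
    A <- 0.5 * log(ps * pr)
    w <- 1 / ((Ns - ys[ok]) / (Ns * ys[ok]) + (Nr - yr[ok]) / (Nr * yr[ok]))
    nf <- length(M)
    loM <- floor(nf * trim_M) + 1; hiM <- nf - floor(nf * trim_M)
    loA <- floor(nf * trim_A) + 1; hiA <- nf - floor(nf * trim_A)
    keep <- rank(M, ties.method = "first") >= loM & rank(M, ties.method = "first") <= hiM &
            rank(A, ties.method = "first") >= loA & rank(A, ties.method = "first") <= hiA
    if (!any(keep)) return(1)
    exp(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- lib * comp
  f <- f / exp(mean(log(f)))
  unname(f)
}

#' Median-of-ratios size factors
#'
#' For every feature positive in all samples, the feature's geometric mean
#' across samples is computed; a sample's size factor is the median over
#' those features of `count / geometric mean` (the DESeq2-style estimator).
#'
#' @param Y samples x features nonnegative integer count matrix.
#' @param pseudo_count optional constant added to all counts before the
#'   ratios are formed; the default 0 errors when no feature is positive in
#'   every sample, in which case a small pseudo-count (e.g. 0.5) is the
#'   documented fallback.
#' @return per-sample positive size factors.
#' @export
median_ratio_size_factors <- function(Y, pseudo_count = 0) {
  Y <- as.matrix(Y)
  check_counts(Y, "Y")
  Yp <- Y + pseudo_count
  ok <- apply(Yp > 0, 2L, all)
  if (!any(ok)) {
    stop("no feature is positive in every sample; rerun with a pseudo_count (e.g. 0.5)")
  }
  lg <- colMeans(log(Yp[, ok, drop = FALSE]))
  f <- apply(Yp[, ok, drop = FALSE], 1L, function(y) median(exp(log(y) - lg)))
  unname(f)
}

#' Convert normalization factors to log offsets
#'
#' @param factors per-sample positive factors.
#' @return per-sample log offsets (`log(factors)`).
#' @export
to_offsets <- function(factors) {
  stopifnot(all(is.finite(factors)), all(factors > 0))
  log(factors)
}

#' Build an offset specification for a count matrix
#'
#' Bundles a normalization method, its per-sample factors, and the implied
#' log offsets.
#'
#' @param Y samples x features count matrix.
#' @param method one of `"tmm"`, `"median_ratio"`, `"none"`, `"user"`.
#' @param factors user-supplied per-sample factors (required for
#'   `method = "user"`).
#' @return an object of class `offset_spec` with `method`, `factors`,
#'   `offsets`.
#' @export
offset_spec <- function(Y, method = c("tmm", "median_ratio", "none", "user"),
                        factors = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  factors <- switch(method,
    tmm = tmm_factors(Y),
    median_ratio = median_ratio_size_factors(Y),
    none = rep(1, nrow(Y)),
    user = {
      if (is.null(factors)) stop("method = 'user' requires factors")
      stopifnot(length(factors) == nrow(Y), all(factors > 0))
      as.numeric(factors)
    })
  structure(list(method = method, factors = factors,
                 offsets = to_offsets(factors)),
            class = "offset_spec")
}
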