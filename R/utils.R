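#' @keywords internal
"_PACKAGE"

#' @importFrom stats dpois dnbinom rpois rnbinom rnorm rgamma runif optim
#'   nlminb kmeans quantile cor sd var median rWishart setNames
#' @importFrom utils read.table write.table write.csv packageVersion
NULL

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## row-wise logsumexp for a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

#' Derive a reproducible substream seed from a master seed
#'
#' Expands one master integer seed into per-scenario, per-replicate seeds so
#' that every simulation replicate is independently reproducible. The mapping
#' is a small multiplicative hash kept below 2^31.
#'
#' @param seed master integer seed.
#' @param ... further integer indices (scenario number, replicate number, ...).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (k in idx) {
    h <- (h * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483629L + 1L)
}

## checks for count vectors/matrices
check_counts <- function(y, arg = "y") {
  if (length(y) == 0L) stop(sprintf("'%s' must be nonempty", arg))
  if (any(!is.finite(y))) stop(sprintf("'%s' contains non-finite values", arg))
  if (any(y < 0)) stop(sprintf("'%s' contains negative values", arg))
  if (any(abs(y - round(y)) > 1e-8)) {
    stop(sprintf("'%s' contains non-integer values; counts must be integers", arg))
  }
  invisible(TRUE)
}

## recycle offsets to an n x d matrix; accepts scalar, per-sample vector, or matrix
expand_offsets <- function(offsets, n, d) {
  if (is.null(offsets)) return(matrix(0, n, d))
  if (is.matrix(offsets)) {
    if (nrow(offsets) != n || ncol(offsets) != d) {
      stop("offset matrix dimensions do not match the data")
    }
    return(offsets)
  }
  if (length(offsets) == 1L) return(matrix(offsets, n, d))
  if (length(offsets) == n) return(matrix(offsets, n, d))
  stop("offsets must be a scalar, a per-sample vector of length n, or an n x d matrix")
}

is_spd <- function(S, tol = 1e-10) {
  if (!isSymmetric(S, tol = 1e-8)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}
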