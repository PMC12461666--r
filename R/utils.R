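# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Thin wrapper around [withr::with_seed()] so that every stochastic
#' operation in the package is reproducible from an explicit seed without
#' disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Euclidean projection of a vector onto the probability simplex
#'
#' Duchi et al. (2008) O(K log K) algorithm.  Used for the ancestry
#' factorization's Q-updates.
#' @noRd
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Row-wise simplex projection of a matrix.
project_simplex_rows <- function(M) {
  t(apply(M, 1, project_simplex))
}

# Spectral norm of a small symmetric PSD matrix (Lipschitz constants for
# the projected-gradient ancestry updates).
spec_norm <- function(S) {
  if (length(S) == 1L) return(abs(S[1]))
  max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
}

#' Stop unless a condition holds, with a sprintf-style message
#' @noRd
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

# Column-standardize a matrix (unit SD); errors on zero-variance columns
# naming the offenders.
standardize_cols <- function(X, what = "predictor") {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  bad <- colnames(X)[!is.finite(sds) | sds == 0]
  check_that(length(bad) == 0L, "constant %s column(s): %s",
             what, paste(bad, collapse = ", "))
  scale(X, center = TRUE, scale = sds)
}

# Lower-triangle (off-diagonal) values of a square matrix.
lower_tri <- function(M) M[lower.tri(M)]

# Informative per-stage logging; suppressible via options(geaoffset.quiet=TRUE).
go_log <- function(fmt, ...) {
  if (!isTRUE(getOption("geaoffset.quiet", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
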