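# Constrained ordination: RDA and partial RDA built from first principles
# (QR projection + SVD), permutation tests, Ezekiel-adjusted R2, forward
# variable selection, Spearman variable clustering, variance partitioning.

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param p number of predictor degrees of freedom.
#' @return adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  check_that(n > p + 1, "adjusted R2 needs n > p + 1 (n = %d, p = %d)", n, p)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# Residualize the columns of M on [1, Z] by least squares.
residualize <- function(M, Z) {
  M <- as.matrix(M)
  if (is.null(Z)) return(sweep(M, 2, colMeans(M)))
  Qz <- qr.Q(qr(cbind(1, as.matrix(Z))))
  M - Qz %*% crossprod(Qz, M)
}

#' Fit a redundancy analysis, optionally partial
#'
#' The multivariate response `Y` is column-centered; predictors `X` are
#' standardized to unit SD.  With conditioners `Z`, both `Y` and `X` are
#' first replaced by their residuals on `[1, Z]` (partial RDA).  The
#' fitted response is the least-squares projection of `Y` onto the column
#' space of `X`; canonical axes come from its SVD.  Site scores are the
#' projections of (residualized) `Y` onto the canonical axes,
#' `variable_loadings` the correlations of the predictors with those
#' scores, and `R2` the fraction `tr(Yhat' Yhat) / tr(Y' Y)` of
#' (conditioned) response variance explained.
#'
#' @param Y numeric response matrix (rows = sites or individuals).
#' @param X predictor table (data.frame or matrix), rows aligned with `Y`.
#' @param Z optional conditioner table.
#' @return An object of class `rda_model`: `canonical_eigenvalues`
#'   (descending, divisor n-1), `site_scores`, `locus_loadings`,
#'   `variable_loadings`, `r_squared`, `adj_r_squared`, `rank`, plus the
#'   internal matrices needed by [permutation_test()].
#' @export
rda_fit <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_that(nrow(Y) == nrow(X), "Y and X row counts differ")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    check_that(nrow(Z) == nrow(Y), "Y and Z row counts differ")
  }
  check_that(!anyNA(Y) && !anyNA(X) && (is.null(Z) || !anyNA(Z)),
             "missing values not allowed; impute upstream")
  n <- nrow(Y)
  Xs <- standardize_cols(X)
  Yc <- residualize(Y, Z)
  Xr <- residualize(Xs, Z)
  if (max(abs(Xr)) < 1e-8) {
    # every predictor lies in the conditioner space: nothing left to fit
    rank_x <- 0L
    Qx <- matrix(0, n, 0)
    Yhat <- matrix(0, n, ncol(Yc))
    keep <- integer(0)
    V <- matrix(0, ncol(Yc), 0)
    eig <- numeric(0)
  } else {
    qx <- qr(Xr)
    rank_x <- qx$rank
    if (rank_x < ncol(Xr)) {
      aliased <- colnames(X)[qx$pivot[(rank_x + 1):ncol(Xr)]]
      stop(sprintf("predictor(s) aliased after conditioning: %s",
                   paste(aliased, collapse = ", ")), call. = FALSE)
    }
    Qx <- qr.Q(qx)[, seq_len(rank_x), drop = FALSE]
    Yhat <- Qx %*% crossprod(Qx, Yc)
    sv <- svd(Yhat)
    keep <- which(sv$d > max(sv$d[1], 0) * 1e-9 &
                    seq_along(sv$d) <= rank_x)
    V <- sv$v[, keep, drop = FALSE]
    eig <- sv$d[keep]^2 / (n - 1)
  }
  site_scores <- Yc %*% V
  if (length(keep)) {
    colnames(site_scores) <- paste0("RDA", seq_along(keep))
    colnames(V) <- paste0("RDA", seq_along(keep))
    if (!is.null(colnames(Y))) rownames(V) <- colnames(Y)
  }
  vl <- if (length(keep)) suppressWarnings(stats::cor(Xs, site_scores)) else
    matrix(0, ncol(Xs), 0, dimnames = list(colnames(X), NULL))
  tot <- sum(Yc^2)
  fit_ss <- sum(Yhat^2)
  rank_z <- if (is.null(Z)) 0L else qr(cbind(1, Z))$rank - 1L
  structure(list(canonical_eigenvalues = eig,
                 site_scores = site_scores,
                 locus_loadings = V,
                 variable_loadings = vl,
                 r_squared = fit_ss / tot,
                 adj_r_squared = adjusted_r2(fit_ss / tot, n - rank_z, rank_x),
                 rank = rank_x, rank_z = rank_z, n = n,
                 tot_chi = tot / (n - 1),
                 Y_res = Yc, Qx = Qx,
                 predictors = colnames(X)),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("rda_model: %d obs, %d predictors%s; R2 = %.4f (adj %.4f); %d canonical axes\n",
              x$n, x$rank,
              if (x$rank_z > 0) sprintf(" | %d conditioning df", x$rank_z) else "",
              x$r_squared, x$adj_r_squared,
              length(x$canonical_eigenvalues)))
  invisible(x)
}

#' Permutation test of a fitted (partial) RDA
#'
#' Pseudo-F is `(canonical SS / df_model) / (residual SS / df_resid)`.
#' Rows of the conditioned predictor space are permuted (reduced-model
#' permutation); the p-value uses the add-one estimator.
#'
#' @param model an `rda_model`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `pseudo_f` and `p`.
#' @export
permutation_test <- function(model, n_perm = 999L, seed = 1L) {
  check_that(n_perm >= 99, "use at least 99 permutations")
  Y <- model$Y_res
  Qx <- model$Qx
  n <- model$n
  df_mod <- model$rank
  df_res <- n - 1 - model$rank_z - model$rank
  tot <- sum(Y^2)
  fstat <- function(Qperm) {
    fit <- sum(crossprod(Qperm, Y)^2)
    (fit / df_mod) / ((tot - fit) / df_res)
  }
  f_obs <- fstat(Qx)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b)
      fstat(Qx[sample(n), , drop = FALSE]) >= f_obs, logical(1)))
  })
  list(pseudo_f = f_obs, p = (exceed + 1) / (n_perm + 1))
}

#' Forward selection of predictor variables for an RDA
#'
#' Greedy forward selection: at each step the candidate maximizing the
#' augmented model's adjusted R-squared is evaluated (ties broken by
#' candidate order); it is added only if its conditional permutation test
#' is significant (`p <= alpha`) and it increases the adjusted R-squared.
#' Selection stops when the best candidate fails either check, when the
#' pool is exhausted, or — after adding — when the model's adjusted
#' R-squared surpasses that of the all-candidates model (the usual triple
#' stopping rule; the variable crossing the scope is a genuine driver and
#' is retained).
#'
#' @param Y response matrix.
#' @param candidates data.frame/matrix of candidate predictors.
#' @param alpha significance level for the conditional test.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return list with `selected` (character vector, in selection order) and
#'   `trace` (data.frame: step, variable, adj_r2, p, action).
#' @export
forward_select <- function(Y, candidates, alpha = 0.01, n_perm = 1000L,
                           seed = 1L) {
  candidates <- as.data.frame(candidates)
  check_that(ncol(candidates) >= 1, "need at least one candidate")
  vars <- colnames(candidates)
  full_adj <- rda_fit(Y, candidates)$adj_r_squared
  selected <- character(0)
  cur_adj <- 0
  trace <- list()
  step <- 0L
  repeat {
    remaining <- setdiff(vars, selected)
    if (!length(remaining)) break
    step <- step + 1L
    adj <- vapply(remaining, function(v) {
      rda_fit(Y, candidates[, c(selected, v), drop = FALSE])$adj_r_squared
    }, numeric(1))
    best <- remaining[which.max(adj)]   # which.max: first on ties
    best_adj <- adj[[which.max(adj)]]
    Zsel <- if (length(selected)) candidates[, selected, drop = FALSE] else NULL
    pt <- permutation_test(
      rda_fit(Y, candidates[, best, drop = FALSE], Z = Zsel),
      n_perm = n_perm, seed = seed + step)
    action <-
      if (pt$p > alpha) "stop: p > alpha"
      else if (best_adj <= cur_adj) "stop: adjusted R2 decreased"
      else if (best_adj > full_adj) "added; stop: surpassed full-model adjusted R2"
      else "added"
    trace[[step]] <- data.frame(step = step, variable = best,
                                adj_r2 = best_adj, p = pt$p,
                                action = action,
                                stringsAsFactors = FALSE)
    if (!startsWith(action, "added")) break
    selected <- c(selected, best)
    cur_adj <- best_adj
    if (action != "added") break   # scope reached after adding
  }
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), variable = character(0),
                    adj_r2 = numeric(0), p = numeric(0),
                    action = character(0)),
       full_adj_r2 = full_adj)
}

#' Cluster environmental variables by Spearman correlation
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - |Spearman rho|`; the tree is cut at distance `1 - cut`, grouping
#' variables whose rank correlation exceeds `cut` in magnitude.  Choosing
#' the representative variable per branch is left to the caller.
#'
#' @param env_table data.frame/matrix of variables (columns).
#' @param cut absolute Spearman correlation defining a branch (default 0.7).
#' @return list with `membership` (named integer vector), `tree` (hclust),
#'   `rho` (Spearman correlation matrix).
#' @export
varclus_spearman <- function(env_table, cut = 0.7) {
  X <- as.matrix(env_table)
  check_that(ncol(X) >= 2, "need >= 2 variables")
  sds <- apply(X, 2, stats::sd)
  check_that(all(sds > 0), "constant variable(s): %s",
             paste(colnames(X)[sds == 0], collapse = ", "))
  rho <- stats::cor(X, method = "spearman")
  d <- stats::as.dist(1 - abs(rho))
  tree <- stats::hclust(d, method = "average")
  membership <- stats::cutree(tree, h = 1 - cut)
  list(membership = membership, tree = tree, rho = rho)
}

#' Partition response variance among three predictor blocks
#'
#' Variance partitioning in the classic pRDA sense: the full model uses
#' all three blocks; each block's pure fraction is the gain in adjusted
#' R-squared of the full model over the model without that block
#' (equivalently, the conditioned model's contribution); the confounded
#' fraction is the remainder of the full adjusted R-squared.  Each pure
#' model and the full model get reduced-model permutation p-values.
#'
#' @param Y response matrix.
#' @param env,geo,struct the three predictor blocks (non-empty).
#' @param n_perm,seed permutation settings.
#' @return data.frame of class `partition_table` with rows full /
#'   pure_env / pure_structure / pure_geography / confounded and columns
#'   `prop_explained`, `prop_total`, `p`.
#' @export
variance_partition <- function(Y, env, geo, struct, n_perm = 999L, seed = 1L) {
  env <- as.data.frame(env); geo <- as.data.frame(geo)
  struct <- as.data.frame(struct)
  check_that(ncol(env) > 0 && ncol(geo) > 0 && ncol(struct) > 0,
             "all three predictor blocks must be non-empty")
  adj <- function(...) rda_fit(Y, do.call(cbind, list(...)))$adj_r_squared
  full_fit <- rda_fit(Y, cbind(env, geo, struct))
  a_full <- full_fit$adj_r_squared
  pure_env <- a_full - adj(geo, struct)
  pure_str <- a_full - adj(env, geo)
  pure_geo <- a_full - adj(env, struct)
  confounded <- a_full - (pure_env + pure_str + pure_geo)
  p_full <- permutation_test(full_fit, n_perm, seed)$p
  p_env <- permutation_test(rda_fit(Y, env, Z = cbind(geo, struct)),
                            n_perm, seed + 1L)$p
  p_str <- permutation_test(rda_fit(Y, struct, Z = cbind(env, geo)),
                            n_perm, seed + 2L)$p
  p_geo <- permutation_test(rda_fit(Y, geo, Z = cbind(env, struct)),
                            n_perm, seed + 3L)$p
  out <- data.frame(
    component = c("full", "pure_env", "pure_structure", "pure_geography",
                  "confounded"),
    prop_explained = c(1, pure_env, pure_str, pure_geo, confounded) /
      c(1, rep(a_full, 4)),
    prop_total = c(a_full, pure_env, pure_str, pure_geo, confounded),
    p = c(p_full, p_env, p_str, p_geo, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("partition_table", "data.frame")
  out
}
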