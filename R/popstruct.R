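# Population structure and differentiation: PCA, ancestry estimation,
# choice of K, genotype imputation, Q-matrix interpolation, AMOVA,
# F_ST, and isolation by distance.

# ---------------------------------------------------------------------------
# PCA

#' Principal component analysis of a genotype matrix
#'
#' Loci are centered on their mean dosage; missing entries are mean-imputed
#' for the decomposition only.  Scores come from the SVD of the centered
#' matrix; eigenvalues (variances along PCs, divisor n-1) are sorted
#' descending.
#'
#' @param g a [genotype_matrix()].
#' @param n_axes number of axes to return (default all).
#' @return list with `scores` (individuals x axes), `loadings`
#'   (loci x axes), `eigenvalues`.
#' @export
pca_genotypes <- function(g, n_axes = NULL) {
  X <- g$values
  check_that(nrow(X) >= 2 && ncol(X) >= 2, "need >= 2 individuals and loci")
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, mu)
  Xc[is.na(Xc)] <- 0
  check_that(sum(Xc^2) > 0, "zero-variance genotype matrix")
  sv <- svd(Xc)
  ev <- sv$d^2 / (nrow(X) - 1)
  k <- if (is.null(n_axes)) length(ev) else min(n_axes, length(ev))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(g$individual_ids, paste0("PC", seq_len(k)))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(g$locus_meta$id, paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings, eigenvalues = ev)
}

# ---------------------------------------------------------------------------
# Ancestry estimation (masked least-squares matrix factorization)

# Objective 0.5 * || W o (M - Q F) ||_F^2 over observed entries.
als_objective <- function(M, W, Q, F) {
  R <- (M - Q %*% F) * W
  0.5 * sum(R^2)
}

#' Estimate ancestry coefficients by masked matrix factorization
#'
#' A least-squares stand-in for model-based ancestry programs: dosages/2
#' are factorized as `M ~ Q F` with `Q` rows on the probability simplex
#' (admixture proportions) and cluster allele frequencies `F` in `[0, 1]`.
#' Missing entries are excluded from the residual.  Optimization is
#' block projected gradient with 1/L step sizes, so the objective is
#' non-increasing; the best of `n_restarts` random starts (by residual
#' norm) is returned.  This is a deterministic-given-seed surrogate with
#' the same Q/F interface as Admixture-style programs, not a claim of
#' statistical equivalence.
#'
#' @param g a [genotype_matrix()].
#' @param K number of clusters (`1 <= K <=` individuals).
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @param max_iter maximum outer iterations per start.
#' @param tol relative objective-change convergence tolerance.
#' @return list of class `ancestry_model`: `K`, `Q`, `F`, `objective`
#'   (trace of the best start), `fully_assigned` (per-cluster count of
#'   individuals with max q > 0.9).
#' @export
estimate_ancestry <- function(g, K, seed = 1L, n_restarts = 2L,
                              max_iter = 300L, tol = 1e-7) {
  X <- g$values
  n <- nrow(X); L <- ncol(X)
  check_that(K >= 1, "K must be >= 1")
  check_that(K <= n, "K (%d) exceeds number of individuals (%d)", K, n)
  M <- X / 2
  W <- !is.na(M) * 1
  M[is.na(M)] <- 0
  if (K == 1L) {
    F1 <- matrix(colSums(M * W) / pmax(colSums(W), 1), 1, L)
    Q <- matrix(1, n, 1)
    model <- list(K = 1L, Q = Q, F = F1,
                  objective = als_objective(M, W, Q, F1))
  } else {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- with_seed(seed + 1000L * r, {
        if (r == 1L) {
          # warm start: k-means on the leading principal components
          Mi <- M
          Mi[W == 0] <- 0
          Mc <- sweep(Mi, 2, colSums(Mi) / pmax(colSums(W), 1))
          Mc[W == 0] <- 0
          sc <- svd(Mc, nu = min(K, n), nv = 0)
          sc <- sc$u %*% diag(sc$d[seq_len(min(K, n))], min(K, n))
          km <- stats::kmeans(sc[, seq_len(max(1, min(K - 1, ncol(sc)))),
                                 drop = FALSE],
                              centers = K, nstart = 10, iter.max = 50)
          Q <- matrix(0.2 / (K - 1), n, K)
          Q[cbind(seq_len(n), km$cluster)] <- 0.8
        } else {
          Q <- matrix(stats::rexp(n * K), n, K)
          Q <- Q / rowSums(Q)
        }
        F <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
        obj <- als_objective(M, W, Q, F)
        trace <- obj
        for (it in seq_len(max_iter)) {
          # F-step: clip to [0,1]; Lipschitz constant ||Q'Q||_2
          Lf <- spec_norm(crossprod(Q))
          for (s in 1:2) {
            GF <- -crossprod(Q, (M - Q %*% F) * W)
            F <- pmin(pmax(F - GF / Lf, 0), 1)
          }
          # Q-step: rows on simplex; Lipschitz constant ||F F'||_2
          Lq <- spec_norm(tcrossprod(F))
          for (s in 1:2) {
            GQ <- -((M - Q %*% F) * W) %*% t(F)
            Q <- project_simplex_rows(Q - GQ / Lq)
          }
          obj_new <- als_objective(M, W, Q, F)
          trace <- c(trace, obj_new)
          if (obj - obj_new < tol * max(obj, 1)) { obj <- obj_new; break }
          obj <- obj_new
        }
        list(Q = Q, F = F, objective = trace)
      })
      if (is.null(best) ||
          utils::tail(fit$objective, 1) < utils::tail(best$objective, 1)) {
        best <- fit
      }
    }
    model <- list(K = as.integer(K), Q = best$Q, F = best$F,
                  objective = best$objective)
  }
  rownames(model$Q) <- g$individual_ids
  colnames(model$F) <- g$locus_meta$id
  qmax <- apply(model$Q, 1, max)
  modal <- max.col(model$Q, ties.method = "first")
  model$fully_assigned <- vapply(seq_len(model$K), function(k)
    sum(modal == k & qmax > 0.9), integer(1))
  class(model) <- "ancestry_model"
  model
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat(sprintf("ancestry_model: K = %d, %d individuals, %d loci; fully assigned (q > 0.9) per cluster: %s\n",
              x$K, nrow(x$Q), ncol(x$F),
              paste(x$fully_assigned, collapse = "/")))
  invisible(x)
}

#' Choose the number of clusters by masked-entry cross-validation
#'
#' A fraction of the observed genotype entries is masked; models are fitted
#' for each `K` on the unmasked entries and scored by the mean squared
#' prediction error of `2 * sum_k q_ik F_kl` on the masked entries.  Each
#' `K` also gets the biological-plausibility diagnostics: per-cluster
#' counts of fully assigned individuals (max q > 0.9) and, when `sites`
#' are supplied, a spatial-coherence score (mean fraction of an
#' individual's 5 nearest geographic neighbours sharing its modal
#' cluster).  A `K` is flagged implausible when any cluster has no fully
#' assigned individual.
#'
#' @param g a [genotype_matrix()].
#' @param K_range integer vector of K values to assess.
#' @param mask_fraction fraction of observed entries to mask, in (0, 0.5).
#' @param seed integer seed.
#' @param sites optional site frame for the coherence score.
#' @param ... passed to [estimate_ancestry()].
#' @return data.frame with columns `K`, `cv_error`, `min_fully_assigned`,
#'   `plausible`, `coherence`; attribute `models` holds the fitted models.
#' @export
choose_K <- function(g, K_range = 1:6, mask_fraction = 0.1, seed = 1L,
                     sites = NULL, ...) {
  check_that(mask_fraction > 0 && mask_fraction < 0.5,
             "mask_fraction must lie in (0, 0.5)")
  X <- g$values
  obs <- which(!is.na(X))
  mask <- with_seed(seed, sample(obs, round(mask_fraction * length(obs))))
  Xm <- X
  Xm[mask] <- NA_integer_
  gm <- genotype_matrix(Xm, g$locus_meta, g$individual_ids)
  models <- list()
  rows <- lapply(K_range, function(K) {
    m <- estimate_ancestry(gm, K, seed = seed + K, ...)
    models[[as.character(K)]] <<- m
    pred <- 2 * (m$Q %*% m$F)
    cv <- mean((pred[mask] - X[mask])^2)
    coher <- NA_real_
    if (!is.null(sites)) {
      modal <- max.col(m$Q, ties.method = "first")
      xy <- cbind(sites$longitude, sites$latitude)[match(g$individual_ids,
                                                         sites$individual_id), ]
      D <- as.matrix(stats::dist(xy))
      diag(D) <- Inf
      nn <- apply(D, 1, function(d) order(d)[1:5])
      coher <- mean(vapply(seq_len(nrow(xy)), function(i)
        mean(modal[nn[, i]] == modal[i]), numeric(1)))
    }
    data.frame(K = K, cv_error = cv,
               min_fully_assigned = min(m$fully_assigned),
               plausible = all(m$fully_assigned > 0),
               coherence = coher)
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' Impute missing genotypes from a fitted ancestry model
#'
#' Each missing entry is replaced by the most probable genotype under
#' `Binomial(2, pi_il)` with `pi_il = sum_k q_ik F_kl`; observed entries
#' are untouched.
#'
#' @param g a [genotype_matrix()] the model was fitted on.
#' @param model an `ancestry_model`.
#' @return A complete [genotype_matrix()].
#' @export
impute_genotypes <- function(g, model) {
  X <- g$values
  all_missing <- colSums(!is.na(X)) == 0
  check_that(!any(all_missing), "loci with all entries missing: %s",
             paste(g$locus_meta$id[all_missing], collapse = ", "))
  miss <- which(is.na(X))
  if (length(miss)) {
    Pi <- pmin(pmax(model$Q %*% model$F, 0), 1)
    p <- Pi[miss]
    # mode of Binomial(2, p): probabilities (1-p)^2, 2p(1-p), p^2
    probs <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
    X[miss] <- max.col(probs, ties.method = "first") - 1L
  }
  genotype_matrix(X, g$locus_meta, g$individual_ids)
}

# ---------------------------------------------------------------------------
# Thin-plate-spline interpolation of the Q matrix

# Solve TPS coefficients for possibly multi-column values at points (x, y).
tps_fit <- function(x, y, V, ridge = 1e-8) {
  P <- cbind(1, x, y)
  check_that(qr(P)$rank == 3L, "degenerate (collinear) site geometry")
  r <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  K <- ifelse(r == 0, 0, r^2 * log(r))
  n <- length(x)
  A <- rbind(cbind(K + diag(ridge, n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(as.matrix(V), matrix(0, 3, ncol(as.matrix(V))))
  coef <- solve(A, rhs)
  list(x = x, y = y, w = coef[1:n, , drop = FALSE],
       a = coef[(n + 1):(n + 3), , drop = FALSE])
}

tps_predict <- function(fit, x, y) {
  r <- sqrt(outer(x, fit$x, "-")^2 + outer(y, fit$y, "-")^2)
  K <- ifelse(r == 0, 0, r^2 * log(r))
  K %*% fit$w + cbind(1, x, y) %*% fit$a
}

#' Interpolate ancestry coefficients across the grid
#'
#' Per cluster, a thin-plate spline (radial basis `r^2 log r`, ridge
#' `1e-8`) interpolates the site-mean ancestry coefficients over the
#' environmental grid.  Cell values are clipped to `[0, 1]` and
#' renormalized to the simplex; the modal spatio-genetic group per cell is
#' the argmax (ties to the lowest cluster index).
#'
#' @param model an `ancestry_model`.
#' @param sites site frame (rows = individuals, as elsewhere).
#' @param env an `env_layers` providing the target grid geometry.
#' @param ridge ridge added to the radial kernel diagonal.
#' @return list with `Q_grid` (list of per-cluster matrices), `modal`
#'   (integer matrix of modal groups).
#' @export
interpolate_Q <- function(model, sites, env, ridge = 1e-8) {
  idx <- match(rownames(model$Q), sites$individual_id)
  check_that(!anyNA(idx), "model individuals missing from site table")
  sid <- sites$site_id[idx]
  agg <- stats::aggregate(model$Q, by = list(site_id = sid), FUN = mean)
  us <- sites[!duplicated(sites$site_id), c("site_id", "longitude", "latitude")]
  m <- match(agg$site_id, us$site_id)
  x <- us$longitude[m]; y <- us$latitude[m]
  check_that(length(unique(paste(x, y))) >= 4, "need >= 4 distinct site locations")
  Qs <- as.matrix(agg[, -1, drop = FALSE])
  fit <- tps_fit(x, y, Qs, ridge = ridge)
  gc <- grid_coords(env)
  gx <- rep(gc$lon, each = gc$nrow)
  gy <- rep(gc$lat, times = gc$ncol)
  pred <- tps_predict(fit, gx, gy)
  pred <- pmin(pmax(pred, 0), 1)
  pred <- matrix(pred, ncol = model$K)
  rs <- rowSums(pred)
  pred <- pred / pmax(rs, 1e-12)
  pred[rs <= 0, ] <- 1 / model$K
  Q_grid <- lapply(seq_len(model$K), function(k)
    matrix(pred[, k], gc$nrow, gc$ncol))
  modal <- matrix(max.col(pred, ties.method = "first"), gc$nrow, gc$ncol)
  list(Q_grid = Q_grid, modal = modal, site_fit = fit)
}

# ---------------------------------------------------------------------------
# AMOVA

# Complete dosage matrix with locus means substituted for missing entries.
dosage_complete <- function(g) {
  X <- g$values * 1.0
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}

amova_components <- function(D2, grouping) {
  N <- nrow(D2)
  groups <- split(seq_len(N), grouping)
  G <- length(groups)
  ssd_total <- sum(D2[lower.tri(D2)]) / N
  ssd_within <- sum(vapply(groups, function(ix) {
    d <- D2[ix, ix, drop = FALSE]
    sum(d[lower.tri(d)]) / length(ix)
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  sizes <- lengths(groups)
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  phi <- sigma_among / (sigma_among + sigma_within)
  list(ssd = c(among = ssd_among, within = ssd_within, total = ssd_total),
       df = c(among = df_among, within = df_within),
       ms = c(among = ms_among, within = ms_within),
       n0 = n0,
       sigma = c(among = sigma_among, within = sigma_within),
       phi_st = phi)
}

#' One-level analysis of molecular variance
#'
#' AMOVA on squared Euclidean distances between genotype dosage vectors
#' (missing entries replaced by locus means).  Variance components use the
#' unequal-group-size `n0` coefficient; `Phi_ST = sigma_among /
#' (sigma_among + sigma_within)`; the p-value permutes individuals among
#' groups with the add-one estimator.
#'
#' @param g a [genotype_matrix()].
#' @param grouping factor-like vector, one label per individual.
#' @param n_perm number of permutations (>= 999 recommended).
#' @param seed integer seed for the permutations.
#' @return list of class `amova_result` with components, `phi_st`,
#'   `p_perm`.
#' @export
amova <- function(g, grouping, n_perm = 999L, seed = 1L) {
  grouping <- as.character(grouping)
  sizes <- table(grouping)
  check_that(length(sizes) >= 2, "need >= 2 groups")
  check_that(all(sizes >= 2), "group(s) of size 1: %s",
             paste(names(sizes)[sizes < 2], collapse = ", "))
  X <- dosage_complete(g)
  D2 <- as.matrix(stats::dist(X))^2
  obs <- amova_components(D2, grouping)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      amova_components(D2, sample(grouping))$phi_st >= obs$phi_st
    }, logical(1)))
  })
  out <- c(obs, list(p_perm = (exceed + 1) / (n_perm + 1), n_perm = n_perm))
  class(out) <- "amova_result"
  out
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_ST = %.4f (sigma among %.4f, within %.4f), p = %.4g\n",
              x$phi_st, x$sigma["among"], x$sigma["within"], x$p_perm))
  invisible(x)
}

# ---------------------------------------------------------------------------
# F_ST estimators

# Weir & Cockerham (1984) per-locus variance components a, b, c for one
# biallelic locus across r groups; inputs are per-group sample sizes
# (individuals with calls), alt-allele frequencies and observed
# heterozygote frequencies.
wc_components <- function(n_i, p_i, h_i) {
  ok <- n_i > 0
  n_i <- n_i[ok]; p_i <- p_i[ok]; h_i <- h_i[ok]
  r <- length(n_i)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(n_i)
  nsum <- sum(n_i)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  pbar <- sum(n_i * p_i) / nsum
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / nsum
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# Multilocus WC theta (ratio of sums) for a genotype matrix split by group.
wc_theta <- function(X, grouping) {
  groups <- split(seq_len(nrow(X)), grouping)
  comp <- matrix(0, ncol(X), 3)
  for (l in seq_len(ncol(X))) {
    x <- X[, l]
    n_i <- vapply(groups, function(ix) sum(!is.na(x[ix])), numeric(1))
    p_i <- vapply(groups, function(ix) mean(x[ix], na.rm = TRUE) / 2, numeric(1))
    h_i <- vapply(groups, function(ix) mean(x[ix] == 1, na.rm = TRUE), numeric(1))
    p_i[is.nan(p_i)] <- 0; h_i[is.nan(h_i)] <- 0
    comp[l, ] <- wc_components(n_i, p_i, h_i)
  }
  denom <- sum(comp)
  check_that(is.finite(denom) && denom != 0,
             "F_ST undefined: no polymorphism in the data")
  sum(comp[, 1]) / denom
}

#' Global and pairwise F_ST
#'
#' `global_fst()` is the Nei-style estimator `1 - mean(H_S) / mean(H_T)`
#' over loci, with `H_S` the unweighted group mean of `2p(1-p)` and `H_T`
#' from the unweighted mean allele frequency.  `pairwise_fst()` is the
#' multilocus Weir-Cockerham (1984) theta (ratio of sums of the a, b, c
#' components) for every pair of groups, with one-sided permutation
#' p-values obtained by shuffling individuals between the pair.
#'
#' @param g a [genotype_matrix()].
#' @param grouping one label per individual (>= 2 individuals per group).
#' @param n_perm permutations for the pairwise p-values.
#' @param seed integer seed.
#' @return `global_fst()`: a single number.  `pairwise_fst()`: list with
#'   `theta` (symmetric matrix, zero diagonal) and `p` (permutation
#'   p-values).
#' @export
global_fst <- function(g, grouping) {
  grouping <- as.character(grouping)
  groups <- split(seq_len(nrow(g$values)), grouping)
  check_that(length(groups) >= 2, "need >= 2 groups")
  X <- g$values
  P <- vapply(groups, function(ix)
    colMeans(X[ix, , drop = FALSE], na.rm = TRUE) / 2, numeric(ncol(X)))
  hs <- rowMeans(2 * P * (1 - P))
  pbar <- rowMeans(P)
  ht <- 2 * pbar * (1 - pbar)
  poly <- is.finite(hs) & is.finite(ht) & ht > 0
  check_that(any(poly), "F_ST undefined: monomorphic dataset")
  1 - mean(hs[poly]) / mean(ht[poly])
}

#' @rdname global_fst
#' @export
pairwise_fst <- function(g, grouping, n_perm = 999L, seed = 1L) {
  grouping <- as.character(grouping)
  sizes <- table(grouping)
  check_that(all(sizes >= 2), "group(s) with < 2 individuals: %s",
             paste(names(sizes)[sizes < 2], collapse = ", "))
  gs <- names(sizes)
  G <- length(gs)
  check_that(G >= 2, "need >= 2 groups")
  theta <- p <- matrix(0, G, G, dimnames = list(gs, gs))
  X <- g$values
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    ix <- which(grouping %in% c(gs[i], gs[j]))
    sub <- X[ix, , drop = FALSE]
    lab <- grouping[ix]
    th <- wc_theta(sub, lab)
    exceed <- with_seed(seed + i * 1000L + j, {
      sum(vapply(seq_len(n_perm), function(b)
        wc_theta(sub, sample(lab)) >= th, logical(1)))
    })
    theta[i, j] <- theta[j, i] <- th
    p[i, j] <- p[j, i] <- (exceed + 1) / (n_perm + 1)
  }
  diag(p) <- NA_real_
  list(theta = theta, p = p)
}

# ---------------------------------------------------------------------------
# Geodesics, Mantel, IBD

#' Geodesic distance matrix between group mean coordinates
#'
#' Haversine great-circle distances (sphere radius 6371.0088 km) between
#' the mean longitude/latitude of each group's sites.
#'
#' @param sites site frame.
#' @param by grouping column (default `"zone"`).
#' @return symmetric matrix of distances in km.
#' @export
geodesic_matrix <- function(sites, by = "zone") {
  agg <- stats::aggregate(sites[, c("longitude", "latitude")],
                          by = list(group = sites[[by]]), FUN = mean)
  n <- nrow(agg)
  D <- matrix(0, n, n, dimnames = list(agg$group, agg$group))
  for (i in seq_len(n)) {
    D[i, ] <- geosphere::distHaversine(
      c(agg$longitude[i], agg$latitude[i]),
      cbind(agg$longitude, agg$latitude), r = 6371.0088)
  }
  (D + t(D)) / 2
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements; significance from
#' joint row/column permutations of the second matrix, one-sided upper,
#' add-one p-value.
#'
#' @param D1,D2 symmetric matrices of equal dimension.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999L, seed = 1L) {
  check_that(isSymmetric(unname(as.matrix(D1))) &&
               isSymmetric(unname(as.matrix(D2))),
             "Mantel test requires symmetric matrices")
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  check_that(all(dim(D1) == dim(D2)), "matrices differ in dimension")
  r_obs <- stats::cor(lower_tri(D1), lower_tri(D2))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      ix <- sample(nrow(D2))
      stats::cor(lower_tri(D1), lower_tri(D2[ix, ix])) >= r_obs
    }, logical(1)))
  })
  list(r = r_obs, p = (exceed + 1) / (n_perm + 1))
}

#' Isolation-by-distance summary
#'
#' Mantel test of a pairwise F_ST matrix against geographic distance plus
#' an ordinary least-squares fit; the slope is reported per 100 km.
#'
#' @param fst_matrix symmetric pairwise F_ST matrix.
#' @param dist_matrix matching distance matrix in km.
#' @param n_perm,seed passed to [mantel_test()].
#' @return list with `mantel_r`, `mantel_p`, `slope_per_100km`, `r2`.
#' @export
ibd_fit <- function(fst_matrix, dist_matrix, n_perm = 999L, seed = 1L) {
  mt <- mantel_test(fst_matrix, dist_matrix, n_perm = n_perm, seed = seed)
  y <- lower_tri(as.matrix(fst_matrix))
  x <- lower_tri(as.matrix(dist_matrix))
  fit <- stats::lm(y ~ x)
  list(mantel_r = mt$r, mantel_p = mt$p,
       slope_per_100km = unname(stats::coef(fit)[2]) * 100,
       r2 = summary(fit)$r.squared)
}
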