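# Shared fixtures and independent brute-force oracles used across tests.
# Oracles deliberately take different computational routes from the
# package implementation.

options(geaoffset.quiet = TRUE)

# Small default simulation used by several test files.
tiny_sim <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_individuals = 120, n_sites = 90, n_neutral = 250, n_adaptive = 10,
         grid_shape = c(15L, 20L), seed = seed),
    list(...))
  simulate_dataset(do.call(sim_config, args))
}

# All permutations of a vector (for cluster label alignment, K <= 5).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Mean |Q - Q_true| after the best cluster-label permutation.
q_align_error <- function(Q, Q_true) {
  min(vapply(all_perms(seq_len(ncol(Q))),
             function(p) mean(abs(Q[, p] - Q_true)), numeric(1)))
}

# Moran's I at lag 1 (rook neighbours) by direct double sum.
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  mu <- mean(m)
  num <- 0; wsum <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
        num <- num + (m[i, j] - mu) * (m[i2, j2] - mu)
        wsum <- wsum + 1
      }
    }
  }
  (length(m) / wsum) * num / sum((m - mu)^2)
}

# Connected components (rook adjacency) of cells of `m` equal to `value`.
n_patches <- function(m, value) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (m[i0, j0] == value && !seen[i0, j0]) {
      count <- count + 1L
      stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
      while (length(stack)) {
        cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (d in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
          i <- cur[1] + d[1]; j <- cur[2] + d[2]
          if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
              !seen[i, j] && m[i, j] == value) {
            seen[i, j] <- TRUE
            stack[[length(stack) + 1]] <- c(i, j)
          }
        }
      }
    }
  }
  count
}

# Brute-force RDA oracle: explicit hat matrix + eigendecomposition of the
# fitted cross-product (no QR/SVD shortcuts shared with the implementation).
rda_oracle <- function(Y, X, Z = NULL) {
  Y <- as.matrix(Y); X <- scale(as.matrix(X))
  n <- nrow(Y)
  if (!is.null(Z)) {
    Zi <- cbind(1, as.matrix(Z))
    Hz <- Zi %*% solve(t(Zi) %*% Zi) %*% t(Zi)
    Y <- Y - Hz %*% Y
    X <- X - Hz %*% X
  } else {
    Y <- sweep(Y, 2, colMeans(Y))
  }
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  Yhat <- H %*% Y
  ee <- eigen(t(Yhat) %*% Yhat, symmetric = TRUE)
  list(eig = ee$values[ee$values > 1e-9] / (n - 1),
       r2 = sum(diag(t(Yhat) %*% Yhat)) / sum(diag(t(Y) %*% Y)),
       loadings = ee$vectors)
}

# AMOVA oracle from centroid deviations (not pairwise distances).
amova_oracle <- function(X, grouping) {
  X <- as.matrix(X)
  N <- nrow(X); groups <- split(seq_len(N), grouping); G <- length(groups)
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)
  ss_within <- sum(vapply(groups, function(ix) {
    sum(sweep(X[ix, , drop = FALSE], 2,
              colMeans(X[ix, , drop = FALSE]))^2)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  sizes <- lengths(groups)
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (N - G)
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  s_within <- ms_within
  s_among <- (ms_among - ms_within) / n0
  list(ssd = c(among = ss_among, within = ss_within, total = ss_total),
       sigma = c(among = s_among, within = s_within),
       phi_st = s_among / (s_among + s_within))
}

# Weir-Cockerham theta oracle via the nested allele-level ANOVA
# (populations / individuals / gametes), numerically from expanded
# allele indicators.
wc_theta_oracle <- function(X, grouping) {
  groups <- split(seq_len(nrow(X)), grouping)
  r <- length(groups)
  num <- den <- 0
  for (l in seq_len(ncol(X))) {
    x <- X[, l]
    n_i <- vapply(groups, function(ix) sum(!is.na(x[ix])), numeric(1))
    if (sum(n_i > 0) < 2 || sum(n_i) < 3) next
    p_i <- vapply(groups, function(ix) mean(x[ix], na.rm = TRUE) / 2, numeric(1))
    keep <- n_i > 0
    n_i <- n_i[keep]; p_i <- p_i[keep]
    r_eff <- length(n_i)
    nsum <- sum(n_i)
    pbar <- sum(n_i * p_i) / nsum
    nc <- (nsum - sum(n_i^2) / nsum) / (r_eff - 1)
    # sums of squares on allele indicators
    ss_pop <- sum(2 * n_i * (p_i - pbar)^2)
    ss_ind <- 0; ss_gam <- 0
    for (gname in names(groups)) {
      ix <- groups[[gname]]
      xs <- x[ix]; xs <- xs[!is.na(xs)]
      if (!length(xs)) next
      pg <- mean(xs) / 2
      ss_ind <- ss_ind + sum(2 * (xs / 2 - pg)^2)
      ss_gam <- ss_gam + sum(ifelse(xs == 1, 0.5, 0))
    }
    ms_pop <- ss_pop / (r_eff - 1)
    ms_ind <- ss_ind / (nsum - r_eff)
    ms_gam <- ss_gam / nsum
    sc <- ms_gam
    sb <- (ms_ind - ms_gam) / 2
    sa <- (ms_pop - ms_ind) / (2 * nc)
    num <- num + sa
    den <- den + sa + sb + sc
  }
  num / den
}

# Step-up Benjamini-Hochberg from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
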