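# Candidate adaptive locus detection: RDA-loading Mahalanobis outliers,
# PC-regression outliers, latent-factor mixed-model association, and the
# multi-method consensus rule.

# Genomic-inflation-corrected chi-square p-values from Mahalanobis D2.
gif_pvalues <- function(d2, df) {
  lambda <- stats::median(d2, na.rm = TRUE) / stats::qchisq(0.5, df)
  p <- stats::pchisq(d2 / lambda, df, lower.tail = FALSE)
  list(lambda = lambda, p = p)
}

# Robust Mahalanobis distances: MVE location/scatter (MASS::cov.rob, run
# under a fixed local seed for determinism) followed by one reweighting
# step — classical moments of the 97.5% chi-square core with the usual
# consistency correction — so the estimator is calibrated under a
# Gaussian null while staying resistant to outliers.
robust_mahalanobis <- function(M) {
  M <- as.matrix(M)
  k <- ncol(M)
  cr <- with_seed(20240601L, MASS::cov.rob(M))
  d0 <- stats::mahalanobis(M, cr$center, cr$cov)
  cut <- stats::qchisq(0.975, k)
  core <- d0 <= cut
  if (sum(core) > k + 1) {
    kappa <- stats::pchisq(cut, k + 2) / stats::pchisq(cut, k)
    ctr <- colMeans(M[core, , drop = FALSE])
    cv <- stats::cov(M[core, , drop = FALSE]) / kappa
    stats::mahalanobis(M, ctr, cv)
  } else {
    d0
  }
}

#' RDA-based outlier detection (Mahalanobis distances on locus loadings)
#'
#' Computes, per locus, the Mahalanobis distance of its loadings on the
#' first `k_axes` canonical axes (robust location and scatter estimated
#' across loci, so the outliers themselves do not inflate the reference
#' covariance), applies a genomic inflation factor
#' `lambda = median(D2) / chisq_0.5(k_axes)`, converts to upper-tail
#' chi-square p-values with `k_axes` degrees of freedom, and
#' Benjamini-Hochberg q-values.  Hits are loci with `q < q_threshold`.
#'
#' @param model an `rda_model` fitted with loci as response columns.
#' @param k_axes number of leading canonical axes to use.
#' @param q_threshold FDR threshold for the hit flag.
#' @return data.frame (`id`, `d2`, `p`, `q`, `hit`) with attribute
#'   `lambda`.
#' @export
rdadapt <- function(model, k_axes = 2, q_threshold = 0.05) {
  check_that(k_axes >= 1, "k_axes must be >= 1")
  check_that(length(model$canonical_eigenvalues) >= k_axes,
             "model has %d canonical axes, %d requested",
             length(model$canonical_eigenvalues), k_axes)
  L <- model$locus_loadings[, seq_len(k_axes), drop = FALSE]
  d2 <- robust_mahalanobis(L)
  gp <- gif_pvalues(d2, k_axes)
  q <- stats::p.adjust(gp$p, method = "BH")
  out <- data.frame(id = rownames(model$locus_loadings) %||%
                      paste0("locus", seq_along(d2)),
                    d2 = d2, p = gp$p, q = q, hit = q < q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- gp$lambda
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered (optionally binomial-normalized) dosage response for GEA
#'
#' Returns the individuals x loci dosage matrix centered per locus, with
#' missing entries either pre-imputed (pass a complete matrix) or set to
#' the locus mean.  With `scaling = "binomial"` each locus is divided by
#' its expected binomial standard deviation `sqrt(p (1 - p))` (EIGENSTRAT
#' normalization): this equalizes the null sampling noise across allele
#' frequencies — which keeps the locus-loading null homogeneous in the
#' outlier scans — while leaving any excess, selection-driven variance in
#' place.
#'
#' @param g a [genotype_matrix()].
#' @param scaling `"binomial"` or `"none"`.
#' @return numeric matrix, individuals x loci.
#' @export
gea_response <- function(g, scaling = c("binomial", "none")) {
  scaling <- match.arg(scaling)
  X <- g$values
  mu <- colMeans(X, na.rm = TRUE)
  Y <- sweep(X, 2, mu)
  Y[is.na(Y)] <- 0
  if (scaling == "binomial") {
    p <- mu / 2
    Y <- sweep(Y, 2, sqrt(pmax(p * (1 - p), 1e-6)), "/")
  }
  Y
}

#' pcadapt-style outlier scan against principal components
#'
#' Each locus's (mean-imputed, centered) dosages are regressed on the
#' first `n_pcs` genotype principal components; the vector of regression
#' z-scores is screened by Mahalanobis distance across loci with the same
#' inflation-factor correction (chi-square df = `n_pcs`) and BH q-values.
#' Zero-variance loci get `NA` statistics and are excluded from the
#' inflation factor.
#'
#' @param g a [genotype_matrix()].
#' @param n_pcs number of principal components capturing population
#'   structure.
#' @param q_threshold FDR threshold for the hit flag.
#' @return data.frame (`id`, `d2`, `p`, `q`, `hit`) with attribute
#'   `lambda`.
#' @export
pcadapt_like <- function(g, n_pcs = 2, q_threshold = 0.05) {
  check_that(n_pcs >= 1, "n_pcs must be >= 1")
  pc <- pca_genotypes(g, n_axes = n_pcs)
  S <- pc$scores
  X <- g$values
  mu <- colMeans(X, na.rm = TRUE)
  Yc <- sweep(X, 2, mu)
  Yc[is.na(Yc)] <- 0
  n <- nrow(Yc)
  Qs <- qr.Q(qr(scale(S, center = TRUE, scale = FALSE)))
  B <- crossprod(Qs, Yc)                       # k x L projections
  rss <- colSums(Yc^2) - colSums(B^2)
  df_res <- n - 1 - n_pcs
  sigma2 <- rss / df_res
  zero_var <- colSums(Yc^2) == 0
  Z <- sweep(B, 2, sqrt(pmax(sigma2, .Machine$double.eps)), "/")
  Z[, zero_var] <- NA_real_
  Zt <- t(Z)
  ok <- !zero_var
  d2 <- rep(NA_real_, ncol(X))
  d2[ok] <- robust_mahalanobis(Zt[ok, , drop = FALSE])
  gp <- gif_pvalues(d2[ok], n_pcs)
  p <- q <- rep(NA_real_, ncol(X))
  p[ok] <- gp$p
  q[ok] <- stats::p.adjust(gp$p, method = "BH")
  out <- data.frame(id = g$locus_meta$id, d2 = d2, p = p, q = q,
                    hit = !is.na(q) & q < q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- gp$lambda
  out
}

#' Latent-factor mixed-model association scan
#'
#' A least-squares LFMM: latent factors `U` start as the leading
#' `K_latent` left singular vectors of the centered dosage matrix and are
#' refined once — environmental effects re-estimated controlling for `U`,
#' then `U` recomputed from the dosages minus the environmental part.
#' (Initializing from the residual on the environment instead would leak
#' the structure-environment collinear component out of `U` and grossly
#' inflate the tests when clusters track environmental gradients.)  Each
#' locus then gets a joint F-test of all environmental coefficients
#' controlling for the latent factors; as in standard LFMM practice the
#' statistics are rescaled by a genomic inflation factor before BH
#' q-values are computed.  `K_latent = 0` reduces exactly to the ordinary
#' per-locus multivariate regression F-test (no inflation correction).
#'
#' @param g a [genotype_matrix()] (missing entries mean-imputed).
#' @param env data.frame/matrix of environmental predictors (rows =
#'   individuals).
#' @param K_latent number of latent factors (>= 0), typically the optimal
#'   number of ancestral clusters.
#' @param q_threshold FDR threshold for the hit flag.
#' @return data.frame (`id`, `stat`, `p`, `q`, `hit`).
#' @export
lfmm_like <- function(g, env, K_latent, q_threshold = 0.05) {
  check_that(K_latent >= 0, "K_latent must be >= 0")
  E <- standardize_cols(as.matrix(env), what = "environmental")
  X <- g$values
  mu <- colMeans(X, na.rm = TRUE)
  Y <- sweep(X, 2, mu)
  Y[is.na(Y)] <- 0
  n <- nrow(Y); p <- ncol(E)
  U <- NULL
  if (K_latent > 0) {
    U <- svd(Y, nu = K_latent, nv = 0)$u
    # refinement: env effects controlling U, then U from the env-free part
    Benv <- qr.coef(qr(cbind(1, E, U)), Y)
    env_part <- cbind(1, E) %*% Benv[seq_len(1 + p), , drop = FALSE]
    U <- svd(Y - env_part, nu = K_latent, nv = 0)$u
    qU <- qr(cbind(1, E, U))
    check_that(qU$rank == 1 + p + K_latent,
               "environmental predictors collinear with latent factors")
  }
  X0 <- if (K_latent > 0) cbind(1, U) else matrix(1, n, 1)
  X1 <- cbind(X0, E)
  Q0 <- qr.Q(qr(X0)); Q1 <- qr.Q(qr(X1))
  rss0 <- colSums(Y^2) - colSums(crossprod(Q0, Y)^2)
  rss1 <- colSums(Y^2) - colSums(crossprod(Q1, Y)^2)
  df2 <- n - ncol(X1)
  fstat <- ((rss0 - rss1) / p) / (rss1 / df2)
  if (K_latent > 0) {
    lambda <- stats::median(fstat * p, na.rm = TRUE) / stats::qchisq(0.5, p)
    pval <- stats::pchisq(fstat * p / lambda, p, lower.tail = FALSE)
  } else {
    pval <- stats::pf(fstat, p, df2, lower.tail = FALSE)
  }
  q <- stats::p.adjust(pval, method = "BH")
  data.frame(id = g$locus_meta$id, stat = fstat, p = pval, q = q,
             hit = !is.na(q) & q < q_threshold,
             stringsAsFactors = FALSE)
}

#' Multi-method consensus of candidate loci
#'
#' Loci flagged by at least `min_methods` of the supplied per-method hit
#' sets; per-method counts are logged.  A warning is raised when the
#' consensus is empty (the sensitivity switch downstream can then fall
#' back to the union or to all loci).
#'
#' @param method_hits named list of character vectors of locus ids.
#' @param min_methods minimum number of methods that must agree.
#' @return character vector of consensus locus ids.
#' @export
consensus_loci <- function(method_hits, min_methods = 2) {
  check_that(length(method_hits) >= 2, "supply hits from >= 2 methods")
  counts <- table(unlist(lapply(method_hits, unique)))
  go_log("consensus: per-method hit counts: %s",
         paste(sprintf("%s=%d", names(method_hits),
                       vapply(method_hits, length, integer(1))),
               collapse = ", "))
  out <- names(counts)[counts >= min_methods]
  if (!length(out)) {
    warning("consensus is empty; consider the union or all-loci sensitivity modes",
            call. = FALSE)
  }
  out
}
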