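# PCA, ancestry factorization, choice of K, imputation, Q interpolation,
# AMOVA, F_ST, Mantel / isolation by distance.

# Two crisp clusters with given alt-allele frequencies.
two_cluster_g <- function(n_per = 30, L = 120, p1 = 0.05, p2 = 0.95,
                          seed = 1) {
  withr::with_seed(seed, {
    vals <- rbind(matrix(rbinom(n_per * L, 2, p1), n_per, L),
                  matrix(rbinom(n_per * L, 2, p2), n_per, L))
  })
  genotype_matrix(vals,
                  data.frame(id = sprintf("L%03d", 1:L), contig = sprintf("c%03d", 1:L),
                             position = 1:L, ref = "A", alt = "T"),
                  sprintf("I%03d", seq_len(2 * n_per)))
}

test_that("genotype PCA matches an eigendecomposition of the covariance matrix", {
  s <- tiny_sim(seed = 2, missing_rate = 0)
  pc <- pca_genotypes(s$genotypes)
  X <- scale(s$genotypes$values, scale = FALSE)
  ee <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  k <- 5
  expect_lt(max(abs(pc$eigenvalues[1:k] - ee$values[1:k])), 1e-8)
  # scores reproduce projections up to sign
  for (j in 1:3) {
    sc <- X %*% ee$vectors[, j]
    expect_lt(min(max(abs(pc$scores[, j] - sc)),
                  max(abs(pc$scores[, j] + sc))), 1e-6)
  }
  # eigenvalue sum equals total centered variance
  expect_lt(abs(sum(pc$eigenvalues) - sum(X^2) / (nrow(X) - 1)), 1e-8)
})

test_that("PCA separates two fixed groups on PC1 with all among-group variance", {
  g <- two_cluster_g(10, 40, p1 = 0, p2 = 1)
  pc <- pca_genotypes(g)
  grp <- rep(1:2, each = 10)
  mu <- tapply(pc$scores[, 1], grp, mean)
  ss_among <- sum(10 * (mu - mean(pc$scores[, 1]))^2)
  expect_gt(ss_among / sum((pc$scores[, 1] - mean(pc$scores[, 1]))^2), 0.999)
  expect_error(pca_genotypes(genotype_matrix(matrix(1L, 3, 3),
    data.frame(id = c("a", "b", "c"), contig = c("a", "b", "c"),
               position = 1:3, ref = "A", alt = "T"), c("i1", "i2", "i3"))),
    "zero-variance")
})

test_that("ancestry at K = 1 gives the closed form and errors past n", {
  g <- two_cluster_g(5, 30)
  m <- estimate_ancestry(g, 1)
  expect_true(all(m$Q == 1))
  expect_equal(as.vector(m$F), unname(colMeans(g$values) / 2))
  expect_error(estimate_ancestry(g, 99), "exceeds")
})

test_that("ancestry objective is non-increasing and two clusters are recovered", {
  g <- two_cluster_g(30, 120)
  m <- estimate_ancestry(g, 2, seed = 3, n_restarts = 2)
  expect_true(all(diff(m$objective) <= 1e-9))
  true_Q <- rbind(matrix(c(1, 0), 30, 2, byrow = TRUE),
                  matrix(c(0, 1), 30, 2, byrow = TRUE))
  expect_lt(q_align_error(m$Q, true_Q), 0.05)
})

test_that("masked cross-validation picks K = 1 for unstructured data", {
  withr::with_seed(5, vals <- matrix(rbinom(80 * 150, 2, 0.4), 80, 150))
  g <- genotype_matrix(vals,
                       data.frame(id = sprintf("L%03d", 1:150),
                                  contig = sprintf("c%03d", 1:150),
                                  position = 1:150, ref = "A", alt = "T"),
                       sprintf("I%03d", 1:80))
  cv <- choose_K(g, K_range = 1:3, mask_fraction = 0.15, seed = 2,
                 n_restarts = 1)
  expect_equal(cv$K[which.min(cv$cv_error)], 1L)
})

test_that("a K whose extra cluster has no fully assigned individuals is implausible", {
  # strongly admixed two-cluster landscape: a third cluster attracts no
  # fully assigned individuals
  s <- tiny_sim(seed = 1, n_individuals = 120, n_sites = 90,
                n_neutral = 250, n_adaptive = 0, K_true = 2,
                temperature = 1.2)
  cv <- choose_K(s$genotypes, K_range = 2:3, mask_fraction = 0.1, seed = 2,
                 n_restarts = 1)
  expect_true(cv$plausible[cv$K == 2])
  expect_false(cv$plausible[cv$K == 3])
})

test_that("imputation leaves complete data alone and fills forced modes", {
  g <- two_cluster_g(5, 20)
  m <- estimate_ancestry(g, 1)
  expect_identical(impute_genotypes(g, m)$values, g$values)
  # forced mode: q = (1, 0), F_1l = 0 -> imputed genotype 0
  vals <- matrix(c(NA, 0L, 0L, 0L), 2, 2)
  gm <- genotype_matrix(vals, data.frame(id = c("a", "b"), contig = c("a", "b"),
                                         position = 1:2, ref = "A", alt = "T"),
                        c("i1", "i2"))
  model <- list(K = 2L, Q = matrix(c(1, 1, 0, 0), 2, 2),
                F = matrix(0, 2, 2))
  expect_equal(impute_genotypes(gm, model)$values[1, 1], 0L)
  # all-missing locus errors
  vals2 <- matrix(c(NA, NA, 0L, 1L), 2, 2)
  gm2 <- genotype_matrix(vals2, gm$locus_meta, gm$individual_ids)
  expect_error(impute_genotypes(gm2, model), "all entries missing")
})

test_that("ancestry-model imputation approaches the Bayes-optimal recovery rate", {
  s <- tiny_sim(seed = 8, n_individuals = 150, n_sites = 110,
                n_neutral = 400, n_adaptive = 0, drift = 0.15,
                missing_rate = 0, K_true = 3)
  g <- s$genotypes
  withr::with_seed(4, mask <- sample(length(g$values),
                                     round(0.15 * length(g$values))))
  vals <- g$values
  truth_vals <- vals[mask]
  vals[mask] <- NA_integer_
  gm <- genotype_matrix(vals, g$locus_meta, g$individual_ids)
  m <- estimate_ancestry(gm, 3, seed = 2, n_restarts = 1)
  gi <- impute_genotypes(gm, m)
  # Bayes-optimal exact recovery given the TRUE generating frequencies:
  # modal-genotype probability at each masked entry.  With ancestral
  # frequencies ~ U(0.1, 0.9) this tops out well below 1 (about 0.63),
  # so the fitted model is held to >= 90% of the oracle.
  Pi <- s$truth$true_Q %*% s$truth$true_cluster_freqs
  pm <- Pi[mask]
  bayes <- mean(pmax((1 - pm)^2, 2 * pm * (1 - pm), pm^2))
  acc <- mean(gi$values[mask] == truth_vals)
  expect_gte(acc, 0.9 * bayes)
  expect_gte(acc, 0.55)
})

test_that("thin-plate-spline Q interpolation reproduces site values and stays on the simplex", {
  s <- tiny_sim(seed = 6, n_individuals = 60, n_sites = 45,
                n_neutral = 150, n_adaptive = 0)
  m <- estimate_ancestry(s$genotypes, 3, seed = 1, n_restarts = 1)
  interp <- interpolate_Q(m, s$sites, s$env)
  # evaluation at a site reproduces that site's mean q
  agg <- aggregate(m$Q, by = list(site_id = s$sites$site_id), FUN = mean)
  us <- s$sites[!duplicated(s$sites$site_id), ]
  i <- match(agg$site_id[1], us$site_id)
  pred <- geaoffset:::tps_predict(interp$site_fit, us$longitude[i],
                                  us$latitude[i])
  expect_lt(max(abs(pred - as.numeric(agg[1, -1]))), 1e-5)
  # cells on the simplex
  Qsum <- Reduce(`+`, interp$Q_grid)
  expect_lt(max(abs(Qsum - 1)), 1e-9)
  expect_true(all(interp$modal %in% 1:3))
})

test_that("degenerate collinear site geometry is rejected for interpolation", {
  sites <- data.frame(individual_id = sprintf("i%d", 1:5),
                      site_id = sprintf("s%d", 1:5),
                      longitude = 1:5, latitude = 2 * (1:5) + 3,
                      zone = "Z1")
  model <- list(K = 2L, Q = matrix(0.5, 5, 2,
                                   dimnames = list(sites$individual_id, NULL)))
  env <- structure(list(grids = list(present = list(v = matrix(0, 4, 4))),
                        xllcorner = 0, yllcorner = 0, cellsize = 1),
                   class = "env_layers")
  expect_error(interpolate_Q(model, sites, env), "collinear|degenerate")
})

test_that("AMOVA components match the sums-of-squares oracle and flag fixed differences", {
  withr::with_seed(3, vals <- matrix(sample(0:2, 18, TRUE), 6, 3))
  g <- genotype_matrix(vals, data.frame(id = paste0("l", 1:3),
                                        contig = paste0("l", 1:3),
                                        position = 1:3, ref = "A", alt = "T"),
                       paste0("i", 1:6))
  grp <- c("a", "a", "b", "b", "c", "c")
  res <- amova(g, grp, n_perm = 99, seed = 1)
  o <- amova_oracle(vals, grp)
  expect_lt(max(abs(res$ssd - o$ssd)), 1e-10)
  expect_lt(max(abs(res$sigma - o$sigma)), 1e-10)
  expect_lt(abs(res$phi_st - o$phi_st), 1e-10)
  # two groups fixed for opposite alleles -> Phi = 1
  gfix <- genotype_matrix(rbind(matrix(0L, 3, 4), matrix(2L, 3, 4)),
                          data.frame(id = paste0("l", 1:4),
                                     contig = paste0("l", 1:4),
                                     position = 1:4, ref = "A", alt = "T"),
                          paste0("i", 1:6))
  expect_equal(amova(gfix, rep(c("a", "b"), each = 3), n_perm = 99)$phi_st, 1)
  expect_error(amova(gfix, c("a", rep("b", 5))), "size 1")
})

test_that("Weir-Cockerham theta matches the allele-level ANOVA oracle", {
  # hand dataset: 2 demes, 2 loci
  vals <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L,
                   2L, 2L, 1L, 0L, 0L, 1L), 6, 2)
  g <- genotype_matrix(vals, data.frame(id = c("l1", "l2"),
                                        contig = c("l1", "l2"),
                                        position = 1:2, ref = "A", alt = "T"),
                       paste0("i", 1:6))
  grp <- rep(c("a", "b"), each = 3)
  pf <- pairwise_fst(g, grp, n_perm = 99, seed = 1)
  expect_lt(abs(pf$theta["a", "b"] - wc_theta_oracle(vals, grp)), 1e-10)
  # random larger dataset, 3 groups: every pair against the oracle
  withr::with_seed(11, vr <- matrix(rbinom(60 * 40, 2,
                                           rep(runif(40, .2, .8), each = 60)),
                                    60, 40))
  gr <- genotype_matrix(vr, data.frame(id = paste0("l", 1:40),
                                       contig = paste0("l", 1:40),
                                       position = 1:40, ref = "A", alt = "T"),
                        paste0("i", 1:60))
  grp3 <- rep(c("a", "b", "c"), each = 20)
  pf3 <- pairwise_fst(gr, grp3, n_perm = 99, seed = 1)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ix <- grp3 %in% pair
    expect_lt(abs(pf3$theta[pair[1], pair[2]] -
                    wc_theta_oracle(vr[ix, ], grp3[ix])), 1e-10)
  }
})

test_that("theta is 1 for fixed opposite groups and ~0 for identical groups", {
  gfix <- genotype_matrix(rbind(matrix(0L, 4, 6), matrix(2L, 4, 6)),
                          data.frame(id = paste0("l", 1:6),
                                     contig = paste0("l", 1:6),
                                     position = 1:6, ref = "A", alt = "T"),
                          paste0("i", 1:8))
  grp <- rep(c("a", "b"), each = 4)
  expect_equal(pairwise_fst(gfix, grp, n_perm = 99)$theta["a", "b"], 1)
  withr::with_seed(9, vals <- matrix(rbinom(40 * 500, 2,
                                            rep(runif(500, .1, .9), each = 40)),
                                     40, 500))
  gsame <- genotype_matrix(vals, data.frame(id = paste0("l", 1:500),
                                            contig = paste0("l", 1:500),
                                            position = 1:500, ref = "A",
                                            alt = "T"),
                           paste0("i", 1:40))
  th <- pairwise_fst(gsame, rep(c("a", "b"), 20), n_perm = 99)$theta["a", "b"]
  expect_lt(abs(th), 0.02)
  gm <- genotype_matrix(matrix(0L, 4, 3),
                        data.frame(id = paste0("l", 1:3), contig = paste0("l", 1:3),
                                   position = 1:3, ref = "A", alt = "T"),
                        paste0("i", 1:4))
  expect_error(global_fst(gm, rep(c("a", "b"), each = 2)), "monomorphic")
})

test_that("AMOVA Phi and WC theta rank drift levels identically", {
  stats <- t(vapply(c(0.02, 0.08, 0.2), function(f) {
    s <- tiny_sim(seed = 17, n_individuals = 120, n_sites = 90,
                  n_neutral = 200, n_adaptive = 0, drift = f,
                  missing_rate = 0, temperature = 0, K_true = 2)
    grp <- apply(s$truth$true_Q, 1, which.max)
    c(amova(s$genotypes, grp, n_perm = 99)$phi_st,
      pairwise_fst(s$genotypes, grp, n_perm = 99)$theta[1, 2])
  }, numeric(2)))
  expect_true(all(diff(stats[, 1]) > 0))
  expect_true(all(diff(stats[, 2]) > 0))
})

test_that("haversine distances, Mantel affine invariance, and the IBD fit behave", {
  sites <- data.frame(individual_id = c("a", "b"), site_id = c("sa", "sb"),
                      longitude = c(0, 1), latitude = c(0, 0),
                      zone = c("za", "zb"))
  D <- geodesic_matrix(sites)
  expect_lt(abs(D["za", "zb"] - 111.195), 0.01)
  expect_equal(D["za", "za"], 0)

  withr::with_seed(2, D1 <- as.matrix(dist(matrix(rnorm(12), 6, 2))))
  mt <- mantel_test(D1, 3 * D1 + 2, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_error(mantel_test(D1, matrix(rnorm(36), 6, 6)), "symmetric")

  ibd <- suppressWarnings(ibd_fit(0.002 + 0.00007 * D1, D1, n_perm = 99, seed = 1))
  expect_lt(abs(ibd$slope_per_100km - 0.007), 1e-9)
  expect_gt(ibd$r2, 0.999)
})

test_that("Mantel agrees with vegan on a random pair of matrices", {
  skip_if_not_installed("vegan")
  withr::with_seed(14, {
    D1 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    D2 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  })
  mt <- mantel_test(D1, D2, n_perm = 999, seed = 3)
  vm <- vegan::mantel(D1, D2, permutations = 999)
  expect_lt(abs(mt$r - vm$statistic), 1e-10)
  expect_lt(abs(mt$p - vm$signif), 0.05)
})
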