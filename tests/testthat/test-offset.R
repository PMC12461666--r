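# Adaptive landscapes, genomic offsets, z' standardization, donor maps.

# Hand-built environment: two variables on a small grid with known
# standardization statistics.
toy_env <- function(g1p, g2p, g1f = g1p, g2f = g2p,
                    mean1 = 0, sd1 = 1, mean2 = 0, sd2 = 1) {
  structure(list(
    grids = list(present = list(v1 = g1p, v2 = g2p),
                 future = list(v1 = g1f, v2 = g2f)),
    xllcorner = 0, yllcorner = 0, cellsize = 1,
    site_values = NULL,
    standardization = data.frame(variable = c("v1", "v2"),
                                 mean = c(mean1, mean2),
                                 sd = c(sd1, sd2))),
    class = "env_layers")
}

toy_model <- function(loadings, eig = rep(1, ncol(loadings))) {
  structure(list(canonical_eigenvalues = eig,
                 variable_loadings = loadings),
            class = "rda_model")
}

test_that("the adaptive index is the loading-weighted sum of standardized values", {
  # single variable, loading 1, value = mean + sd  ->  index 1
  m1 <- toy_model(matrix(1, 1, 1, dimnames = list("v1", NULL)))
  env1 <- toy_env(matrix(5 + 2, 2, 2), matrix(0, 2, 2), mean1 = 5, sd1 = 2)
  al <- adaptive_index(m1, env1, "present", axes = 1)
  expect_equal(unname(al$index$RDA1), matrix(1, 2, 2))
  # two variables, loadings (0.6, -0.8), standardized values (1, 0.5) -> 0.2
  m2 <- toy_model(matrix(c(0.6, -0.8), 2, 1,
                         dimnames = list(c("v1", "v2"), NULL)))
  env2 <- toy_env(matrix(1, 2, 2), matrix(0.5, 2, 2))
  al2 <- adaptive_index(m2, env2, "present", axes = 1)
  expect_equal(unname(al2$index$RDA1), matrix(0.6 - 0.4, 2, 2))
  # missing variable is named in the error
  m3 <- toy_model(matrix(1, 1, 1, dimnames = list("nope", NULL)))
  expect_error(adaptive_index(m3, env2, "present", axes = 1), "nope")
})

test_that("identical periods give identical landscapes and zero offsets", {
  m <- toy_model(matrix(c(0.6, -0.8, 0.2, 0.9), 2, 2,
                        dimnames = list(c("v1", "v2"), NULL)),
                 eig = c(2, 1))
  withr::with_seed(4, {
    g1 <- matrix(rnorm(12), 3, 4); g2 <- matrix(rnorm(12), 3, 4)
  })
  env <- toy_env(g1, g2)   # future defaults to present
  ap <- adaptive_index(m, env, "present")
  af <- adaptive_index(m, env, "future")
  expect_identical(ap$index, af$index)
  off <- genomic_offset(ap, af)
  expect_equal(off, matrix(0, 3, 4))
})

test_that("one-axis offsets reduce to |delta index| and two-axis matches hand arithmetic", {
  m <- toy_model(matrix(c(1, 0), 2, 1, dimnames = list(c("v1", "v2"), NULL)))
  env <- toy_env(matrix(c(1, 2, 3, 4), 2, 2), matrix(0, 2, 2),
                 g1f = matrix(c(2, 1, 5, 2), 2, 2))
  ap <- adaptive_index(m, env, "present", axes = 1)
  af <- adaptive_index(m, env, "future", axes = 1)
  off <- genomic_offset(ap, af, weighting = "none")
  expect_equal(off, abs(matrix(c(1, -1, 2, -2), 2, 2)))
  # two axes, weights = none: Euclidean distance on a 2x2 fixture
  m2 <- toy_model(matrix(c(1, 0, 0, 1), 2, 2,
                         dimnames = list(c("v1", "v2"), NULL)))
  envA <- toy_env(matrix(0, 2, 2), matrix(0, 2, 2),
                  g1f = matrix(3, 2, 2), g2f = matrix(4, 2, 2))
  a <- adaptive_index(m2, envA, "present")
  b <- adaptive_index(m2, envA, "future")
  expect_equal(genomic_offset(a, b, weighting = "none"), matrix(5, 2, 2))
})

test_that("the reference distribution enumerates small grids and is seed-stable", {
  m <- toy_model(matrix(c(1, 0), 2, 1, dimnames = list(c("v1", "v2"), NULL)))
  env <- toy_env(matrix(c(0, 1, 3, NA), 2, 2), matrix(0, 2, 2))
  a <- adaptive_index(m, env, "present", axes = 1)
  ref <- reference_distribution(a, weighting = "none")
  expect_equal(ref$values, c(1, 2, 3))   # pairwise |differences| of 0,1,3
  big <- toy_env(matrix(rnorm(400), 20, 20), matrix(0, 20, 20))
  ab <- adaptive_index(m, big, "present", axes = 1)
  r1 <- reference_distribution(ab, max_pairs = 500, seed = 9)
  r2 <- reference_distribution(ab, max_pairs = 500, seed = 9)
  expect_identical(r1$values, r2$values)
  expect_length(r1$values, 500)
})

test_that("z' anchors the Empirical Rule percentiles for any continuous reference", {
  withr::with_seed(42, ref <- rlnorm(1e5))
  x1 <- quantile(ref, 2 * pnorm(1) - 1, names = FALSE)
  x2 <- quantile(ref, 2 * pnorm(2) - 1, names = FALSE)
  expect_lt(abs(zprime(x1, ref) - 1), 0.01)
  expect_lt(abs(zprime(x2, ref) - 2), 0.01)
  expect_lte(zprime(min(ref), ref), 0.01)
  # distribution-free fractions below z' = 1 and z' = 2
  z <- zprime(ref, ref)
  expect_lt(abs(mean(z <= 1) - 0.6827), 0.005)
  expect_lt(abs(mean(z <= 2) - 0.9545), 0.005)
  expect_error(zprime(1, rep(2, 10)), "degenerate")
})

test_that("z' is invariant under strictly monotone rescaling of offsets and reference", {
  withr::with_seed(7, {
    ref <- rgamma(5000, 2)
    x_on <- sample(ref, 50)            # points of the reference itself
    x_off <- runif(50, 0, max(ref))    # arbitrary points
  })
  f <- function(v) log1p(v)^1.5
  # exact at reference order statistics (pure rank property) ...
  expect_lt(max(abs(zprime(x_on, ref) - zprime(f(x_on), f(ref)))), 1e-9)
  # ... and only interpolation-limited between them
  expect_lt(max(abs(zprime(x_off, ref) - zprime(f(x_off), f(ref)))), 0.01)
})

test_that("threshold masks are monotone in the threshold", {
  withr::with_seed(8, z <- matrix(runif(100, 0, 2), 10, 10))
  m08 <- threshold_mask(z, 0.8)
  m10 <- threshold_mask(z, 1.0)
  expect_true(all(which(m10) %in% which(m08)))
  expect_equal(sum(threshold_mask(z, 3)), 0)
})

test_that("donor offsets at the recipient equal the temporal offset and rank donors", {
  m <- toy_model(matrix(c(1, 0, 0, 1), 2, 2,
                        dimnames = list(c("v1", "v2"), NULL)),
                 eig = c(1.5, 0.5))
  withr::with_seed(10, {
    env <- toy_env(matrix(rnorm(25), 5, 5), matrix(rnorm(25), 5, 5),
                   g1f = matrix(rnorm(25, 1), 5, 5),
                   g2f = matrix(rnorm(25, -0.5), 5, 5))
  })
  ap <- adaptive_index(m, env, "present")
  af <- adaptive_index(m, env, "future")
  ref <- reference_distribution(ap)
  temporal <- genomic_offset(ap, af)
  don <- donor_offset(ap, af, c(3, 3), ref)
  expect_lt(abs(don$raw[3, 3] - temporal[3, 3]), 1e-12)
  expect_true(all(diff(don$ranking$z) >= -1e-12))
  # a donor whose present index equals the recipient's future index
  target <- vapply(af$index, function(mm) mm[3, 3], numeric(1))
  ap2 <- ap
  ap2$index$RDA1[1, 1] <- target[1]; ap2$index$RDA2[1, 1] <- target[2]
  don2 <- donor_offset(ap2, af, c(3, 3), ref)
  expect_equal(don2$raw[1, 1], 0)
  expect_true(don2$suitable[1, 1])
  # suitability shrinks as the threshold decreases
  d_hi <- donor_offset(ap, af, c(3, 3), ref, threshold = 1)
  d_lo <- donor_offset(ap, af, c(3, 3), ref, threshold = 0.5)
  expect_true(all(which(d_lo$suitable) %in% which(d_hi$suitable)))
})

test_that("enriched RDA explains a perfectly linear candidate locus", {
  withr::with_seed(12, {
    e <- rnorm(30)
    freqs <- cbind(l1 = 0.5 + 0.1 * scale(e)[, 1])
  })
  m <- enriched_rda(freqs, data.frame(v1 = e))
  expect_gt(m$r_squared, 1 - 1e-9)
  expect_error(enriched_rda(freqs[0, , drop = FALSE], data.frame(v1 = numeric(0))),
               ">= 3 sites")
  expect_error(enriched_rda(matrix(numeric(0), 30, 0), data.frame(v1 = e)),
               "no candidate")
})

test_that("site allele frequencies average dosages over non-missing calls", {
  vals <- matrix(c(0L, 2L, NA, 2L, 1L, 1L), 3, 2)
  g <- genotype_matrix(vals, data.frame(id = c("l1", "l2"),
                                        contig = c("l1", "l2"),
                                        position = 1:2, ref = "A", alt = "T"),
                       c("i1", "i2", "i3"))
  sites <- data.frame(individual_id = c("i1", "i2", "i3"),
                      site_id = c("s1", "s1", "s2"),
                      longitude = c(0, 0, 1), latitude = c(0, 0, 1),
                      zone = "Z1")
  f <- site_allele_freqs(g, sites)
  expect_equal(f["s1", "l1"], 0.5)   # (0 + 2)/2 dosages -> mean/2
  expect_equal(f["s2", "l1"], 0)     # no calls at all -> guarded to 0
  expect_equal(f["s1", "l2"], mean(c(2, 1)) / 2)
})
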