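# Synthetic genotype / site / environment generator.
#
# The generator produces data with the statistical structure the downstream
# analyses assume: K spatially coherent admixed ancestral clusters
# (Balding-Nichols allele frequencies), a small set of adaptive loci with
# logistic clines along one environmental variable each, smooth present and
# shifted future environmental grids, and missing genotype calls at random.

#' Simulation configuration
#'
#' Defaults emulate the study system the package targets: 735 individuals
#' from 534 sites genotyped at ~8.3k biallelic SNPs with 16.6% missing
#' calls, four spatially coherent admixed clusters, and half a dozen
#' bioclim/soil-like environmental variables on a ~4 deg x 6 deg grid.
#'
#' @param n_individuals number of individuals.
#' @param n_sites number of sampling sites (1-2 individuals per site;
#'   requires `n_sites <= n_individuals <= 2 * n_sites`).
#' @param grid_shape integer `(rows, cols)` of the environmental grid.
#' @param K_true number of ancestral clusters.
#' @param n_neutral,n_adaptive neutral and adaptive locus counts
#'   (`n_adaptive <= n_neutral`).
#' @param drift Balding-Nichols F parameter in (0, 1); larger = more
#'   inter-cluster differentiation.
#' @param effect_size slope of the adaptive logistic clines on the
#'   standardized driving variable.
#' @param missing_rate fraction of genotype calls set missing completely at
#'   random, in `[0, 1)`.
#' @param env_vars named numeric vector: variable names with their spatial
#'   autocorrelation length scales in degrees.
#' @param future_delta named numeric vector of additive per-variable shifts
#'   (in present-field SD units) applied to the future period; variables
#'   absent default to 0 (e.g. soil variables held constant).
#' @param future_gradient named numeric vector: optional additional
#'   south-to-north linear component of the future shift.
#' @param temperature softmax temperature (degrees) for spatial cluster
#'   membership decay; smaller = crisper clusters.
#' @param gradient_strength amplitude of the deterministic geographic
#'   gradient added to each present-day field (SD units of the random
#'   field).
#' @param shared_contig_frac fraction of loci sharing a contig with the
#'   preceding locus (exercises the one-SNP-per-contig filter).
#' @param origin `(lon, lat)` of the grid's lower-left corner.
#' @param cellsize grid cell size in degrees.
#' @param seed integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 735,
                       n_sites = 534,
                       grid_shape = c(40L, 60L),
                       K_true = 4L,
                       n_neutral = 8264L,
                       n_adaptive = 84L,
                       drift = 0.10,
                       effect_size = 2,
                       missing_rate = 0.166,
                       env_vars = c(temp.seas = 3.0, prec.driest = 2.5,
                                    prec.seas = 2.5, isotherm = 2.0,
                                    clay = 1.5, soc = 1.5),
                       future_delta = c(temp.seas = 1.0, prec.driest = -1.0,
                                        prec.seas = 0.8, isotherm = 0.5),
                       future_gradient = c(temp.seas = 0.4),
                       temperature = 0.25,
                       gradient_strength = 1.5,
                       shared_contig_frac = 0.05,
                       origin = c(8, 48),
                       cellsize = 0.1,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_sites = as.integer(n_sites),
              grid_shape = as.integer(grid_shape),
              K_true = as.integer(K_true),
              n_neutral = as.integer(n_neutral),
              n_adaptive = as.integer(n_adaptive),
              drift = drift, effect_size = effect_size,
              missing_rate = missing_rate,
              env_vars = env_vars,
              future_delta = future_delta,
              future_gradient = future_gradient,
              temperature = temperature,
              gradient_strength = gradient_strength,
              shared_contig_frac = shared_contig_frac,
              origin = origin, cellsize = cellsize,
              seed = as.integer(seed))
  check_that(cfg$n_adaptive <= cfg$n_neutral, "n_adaptive must be <= n_neutral")
  check_that(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
             "missing_rate must lie in [0, 1)")
  check_that(cfg$drift > 0 && cfg$drift < 1, "drift must lie in (0, 1)")
  check_that(length(cfg$grid_shape) == 2L && all(cfg$grid_shape >= 1L),
             "grid_shape must be two positive integers")
  check_that(prod(cfg$grid_shape) >= cfg$n_sites,
             "grid has %d cells but %d sites requested",
             prod(cfg$grid_shape), cfg$n_sites)
  check_that(cfg$n_individuals >= cfg$n_sites &&
               cfg$n_individuals <= 2L * cfg$n_sites,
             "need n_sites <= n_individuals <= 2*n_sites (1-2 per site)")
  check_that(all(cfg$env_vars > 0), "length scales must be positive")
  check_that(is.finite(cfg$effect_size), "effect_size must be finite")
  class(cfg) <- "sim_config"
  cfg
}

# Cell-center coordinates of the grid (row 1 = northernmost).
grid_coords <- function(env) {
  nr <- nrow(env$grids$present[[1]]); nc <- ncol(env$grids$present[[1]])
  lon <- env$xllcorner + (seq_len(nc) - 0.5) * env$cellsize
  lat <- env$yllcorner + (nr - seq_len(nr) + 0.5) * env$cellsize
  list(lon = lon, lat = lat, nrow = nr, ncol = nc)
}

# Smooth a white-noise matrix with a separable Gaussian kernel of standard
# deviation `sigma` cells; returns a unit-variance Gaussian random field.
gaussian_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    smooth_mat <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      W <- exp(-d^2 / (2 * sigma^2))
      W / rowSums(W)
    }
    z <- smooth_mat(nr) %*% z %*% t(smooth_mat(nc))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate present and future environmental layers
#'
#' Each variable's present grid is a unit-variance Gaussian random field
#' (Gaussian-kernel-smoothed white noise at the variable's length scale)
#' plus a deterministic geographic gradient (alternating latitudinal /
#' longitudinal across variables).  The future grid is the present grid
#' plus the configured additive shift and optional south-north gradient;
#' variables without a configured shift (e.g. soil) are held constant.
#'
#' @param config a [sim_config()].
#' @return An `env_layers` object (grids per variable per period, grid
#'   geometry; site values and standardization statistics are attached
#'   later by [sample_env_at_sites()]).
#' @export
make_environment <- function(config) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  vars <- names(config$env_vars)
  check_that(!(nr == 1 && nc == 1 && any(config$env_vars > 0)),
             "cannot request spatial autocorrelation on a 1x1 grid")
  lon_u <- (seq_len(nc) - 0.5) / nc  # 0..1 west->east
  lat_u <- (nr - seq_len(nr) + 0.5) / nr  # 0..1 south->north, row 1 = north
  present <- future <- stats::setNames(vector("list", length(vars)), vars)
  with_seed(config$seed, {
    for (j in seq_along(vars)) {
      v <- vars[j]
      sigma_cells <- config$env_vars[[v]] / config$cellsize
      f <- gaussian_field(nr, nc, sigma_cells)
      grad <- if (j %% 2 == 1) {
        matrix(rep(lat_u, nc), nr, nc)          # latitudinal gradient
      } else {
        matrix(rep(lon_u, each = nr), nr, nc)   # longitudinal gradient
      }
      present[[v]] <- f + config$gradient_strength * (grad - mean(grad)) * 2
      shift <- if (v %in% names(config$future_delta))
        config$future_delta[[v]] else 0
      gslope <- if (v %in% names(config$future_gradient))
        config$future_gradient[[v]] else 0
      future[[v]] <- present[[v]] + shift +
        gslope * (matrix(rep(lat_u, nc), nr, nc) - 0.5) * 2
    }
  })
  structure(list(grids = list(present = present, future = future),
                 xllcorner = config$origin[1], yllcorner = config$origin[2],
                 cellsize = config$cellsize,
                 site_values = NULL, standardization = NULL),
            class = "env_layers")
}

#' @export
print.env_layers <- function(x, ...) {
  g <- x$grids$present[[1]]
  cat(sprintf("env_layers: %d variables, %d x %d grid, periods present/future%s\n",
              length(x$grids$present), nrow(g), ncol(g),
              if (is.null(x$site_values)) "" else
                sprintf(", %d sites sampled", nrow(x$site_values$present))))
  invisible(x)
}

# Bilinear interpolation of a grid (row 1 = northernmost) at lon/lat points,
# clamped to the cell-center hull.
bilinear_sample <- function(grid, lon, lat, xll, yll, cellsize) {
  nr <- nrow(grid); nc <- ncol(grid)
  cx <- (lon - xll) / cellsize + 0.5          # column coordinate, 1-based
  cy <- nr - (lat - yll) / cellsize + 0.5     # row coordinate, 1-based
  cx <- pmin(pmax(cx, 1), nc); cy <- pmin(pmax(cy, 1), nr)
  x0 <- pmin(floor(cx), nc - 1L); y0 <- pmin(floor(cy), nr - 1L)
  if (nc == 1L) x0 <- rep(1L, length(cx))
  if (nr == 1L) y0 <- rep(1L, length(cy))
  fx <- cx - x0; fy <- cy - y0
  g <- function(i, j) grid[cbind(pmin(pmax(i, 1), nr), pmin(pmax(j, 1), nc))]
  (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x0 + 1)) +
    fy * ((1 - fx) * g(y0 + 1, x0) + fx * g(y0 + 1, x0 + 1))
}

#' Attach per-site environmental values and standardization statistics
#'
#' Samples every variable's grids bilinearly at the site coordinates and
#' stores per-variable mean/SD computed from the *present-period site
#' values* — the calibration statistics used for the standardized `b`
#' values of the adaptive index.
#'
#' @param env an `env_layers` object from [make_environment()].
#' @param sites a site frame (see [validate_sites()]); one row per
#'   individual, sites identified by `site_id`.
#' @return `env`, with `site_values` (one row per unique site, per period)
#'   and `standardization` filled in.
#' @export
sample_env_at_sites <- function(env, sites) {
  us <- sites[!duplicated(sites$site_id), c("site_id", "longitude", "latitude")]
  vals <- function(period) {
    out <- data.frame(site_id = us$site_id, stringsAsFactors = FALSE)
    for (v in names(env$grids[[period]])) {
      out[[v]] <- bilinear_sample(env$grids[[period]][[v]],
                                  us$longitude, us$latitude,
                                  env$xllcorner, env$yllcorner, env$cellsize)
    }
    out
  }
  env$site_values <- list(present = vals("present"), future = vals("future"))
  pv <- env$site_values$present[, -1, drop = FALSE]
  sds <- vapply(pv, stats::sd, numeric(1))
  check_that(all(sds > 0), "zero SD in present-period site values")
  env$standardization <- data.frame(variable = names(pv),
                                    mean = vapply(pv, mean, numeric(1)),
                                    sd = sds, row.names = NULL,
                                    stringsAsFactors = FALSE)
  env
}

# Fixed, well-spread focal points (unit square) for up to 8 clusters.
cluster_focals <- function(K) {
  base <- rbind(c(0.20, 0.75), c(0.80, 0.70), c(0.25, 0.20), c(0.55, 0.45),
                c(0.85, 0.15), c(0.10, 0.45), c(0.50, 0.90), c(0.70, 0.95))
  if (K <= nrow(base)) base[seq_len(K), , drop = FALSE]
  else rbind(base, matrix(stats::runif(2 * (K - nrow(base))), ncol = 2))
}

#' Place sites and generate ground-truth ancestry
#'
#' Sites are placed in distinct random grid cells (jittered within the
#' cell).  Each site's true ancestry vector is a softmax of negative
#' distances to `K_true` focal points, so membership decays smoothly with
#' distance and clusters are spatially coherent; the softmax `temperature`
#' controls admixture.  Individuals are assigned 1-2 per site.  Zone labels
#' are a 3 x 3 grid of geographic blocks, standing in for seed transfer
#' zones.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (site frame, one row per individual) and
#'   `truth` (a `sim_truth` carrying `true_Q`, focal points and, after
#'   [make_genotypes()], locus-level generating parameters).
#' @export
make_populations <- function(config) {
  check_that(config$K_true >= 1, "K_true must be >= 1")
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  check_that(config$n_sites <= nr * nc, "more sites than grid cells")
  ext_lon <- nc * config$cellsize; ext_lat <- nr * config$cellsize
  with_seed(config$seed + 1L, {
    cells <- sample.int(nr * nc, config$n_sites)
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    lon <- config$origin[1] + (col - 0.5 + stats::runif(config$n_sites, -0.4, 0.4)) *
      config$cellsize
    lat <- config$origin[2] + (nr - row + 0.5 + stats::runif(config$n_sites, -0.4, 0.4)) *
      config$cellsize
    foc <- cluster_focals(config$K_true)
    foc_lon <- config$origin[1] + foc[, 1] * ext_lon
    foc_lat <- config$origin[2] + foc[, 2] * ext_lat
    D <- sqrt(outer(lon, foc_lon, "-")^2 + outer(lat, foc_lat, "-")^2)
    if (config$temperature <= 0) {
      Q_site <- matrix(0, config$n_sites, config$K_true)
      Q_site[cbind(seq_len(config$n_sites), max.col(-D))] <- 1
    } else {
      E <- exp(-D / config$temperature)
      Q_site <- E / rowSums(E)
    }
    # 1 individual everywhere, a second at randomly chosen sites
    extra <- sample.int(config$n_sites, config$n_individuals - config$n_sites)
    site_of_ind <- c(seq_len(config$n_sites), extra)
  })
  site_ids <- sprintf("S%04d", seq_len(config$n_sites))
  zone_lon <- cut(lon, breaks = config$origin[1] + ext_lon * (0:3) / 3,
                  labels = FALSE, include.lowest = TRUE)
  zone_lat <- cut(lat, breaks = config$origin[2] + ext_lat * (0:3) / 3,
                  labels = FALSE, include.lowest = TRUE)
  zones <- sprintf("Z%d", (zone_lat - 1L) * 3L + zone_lon)
  ord <- order(site_of_ind)
  site_of_ind <- site_of_ind[ord]
  sites <- data.frame(individual_id = sprintf("I%04d", seq_len(config$n_individuals)),
                      site_id = site_ids[site_of_ind],
                      longitude = lon[site_of_ind],
                      latitude = lat[site_of_ind],
                      zone = zones[site_of_ind],
                      stringsAsFactors = FALSE)
  true_Q <- Q_site[site_of_ind, , drop = FALSE]
  rownames(true_Q) <- sites$individual_id
  truth <- structure(list(true_Q = true_Q, site_Q = Q_site,
                          focal_lon = foc_lon, focal_lat = foc_lat,
                          true_cluster_freqs = NULL,
                          adaptive_loci = NULL),
                     class = "sim_truth")
  list(sites = sites, truth = truth)
}

#' Generate genotypes under Balding-Nichols drift plus logistic clines
#'
#' Neutral loci: ancestral frequency `p0 ~ U(0.1, 0.9)`; cluster frequency
#' `p_kl ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` (Balding-Nichols with drift
#' `F`); an individual's expected alternate-allele frequency is
#' `sum_k q_ik p_kl`.  Adaptive loci: expected frequency
#' `plogis(qlogis(p0) + effect_size * z)` where `z` is the standardized
#' present-day value of the locus's designated driving variable at the
#' individual's site.  Genotypes are Binomial(2, expected frequency);
#' missing calls are MCAR at `missing_rate`.  Contigs are unique except a
#' configured fraction sharing the preceding locus's contig.
#'
#' @param sites site frame from [make_populations()].
#' @param truth the matching `sim_truth`.
#' @param env an `env_layers` with site values attached
#'   (see [sample_env_at_sites()]).
#' @param config the [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (updated with cluster frequencies and the adaptive-locus table).
#' @export
make_genotypes <- function(sites, truth, env, config) {
  check_that(is.finite(config$effect_size), "effect_size must be finite")
  check_that(!is.null(env$site_values), "env has no site values; call sample_env_at_sites() first")
  n <- nrow(sites)
  check_that(n == nrow(truth$true_Q), "sites and truth are inconsistent")
  L <- config$n_neutral + config$n_adaptive
  K <- ncol(truth$true_Q)
  vars <- names(config$env_vars)
  # standardized present env per individual for each variable
  sv <- env$site_values$present
  std <- env$standardization
  Z <- sapply(vars, function(v) {
    (sv[[v]][match(sites$site_id, sv$site_id)] - std$mean[std$variable == v]) /
      std$sd[std$variable == v]
  })
  Z <- matrix(Z, nrow = n, dimnames = list(NULL, vars))
  with_seed(config$seed + 2L, {
    p0 <- stats::runif(L, 0.1, 0.9)
    adaptive_idx <- if (config$n_adaptive > 0)
      sort(sample.int(L, config$n_adaptive)) else integer(0)
    F <- config$drift
    P <- matrix(stats::rbeta(K * L, rep(p0 * (1 - F) / F, each = K),
                             rep((1 - p0) * (1 - F) / F, each = K)), K, L)
    driver <- rep_len(vars, length(adaptive_idx))
    Pi <- truth$true_Q %*% P
    if (length(adaptive_idx)) {
      Pi[, adaptive_idx] <- stats::plogis(
        matrix(rep(stats::qlogis(p0[adaptive_idx]), each = n), n) +
          config$effect_size * Z[, driver, drop = FALSE])
      P[, adaptive_idx] <- matrix(rep(p0[adaptive_idx], each = K), K)
    }
    Pi <- pmin(pmax(Pi, 1e-9), 1 - 1e-9)
    G <- matrix(stats::rbinom(n * L, 2L, Pi), n, L)
    if (config$missing_rate > 0) {
      G[stats::runif(n * L) < config$missing_rate] <- NA_integer_
    }
    shared <- rep(FALSE, L)
    if (config$shared_contig_frac > 0 && L > 1) {
      shared[sample(2:L, round(config$shared_contig_frac * L))] <- TRUE
    }
    positions <- sample.int(1e6L, L, replace = TRUE)
  })
  contig_no <- cumsum(!shared)
  meta <- data.frame(id = sprintf("L%05d", seq_len(L)),
                     contig = sprintf("ctg%05d", contig_no),
                     position = positions,
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  g <- genotype_matrix(G, meta, sites$individual_id)
  truth$true_cluster_freqs <- P
  truth$p0 <- p0
  truth$adaptive_loci <- if (length(adaptive_idx)) {
    data.frame(id = meta$id[adaptive_idx],
               variable = driver,
               p0 = p0[adaptive_idx],
               effect = config$effect_size,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), variable = character(0),
               p0 = numeric(0), effect = numeric(0))
  }
  list(genotypes = g, truth = truth)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [make_environment()], [make_populations()],
#' [sample_env_at_sites()] and [make_genotypes()] in order.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `sites`, `env`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  env <- make_environment(config)
  pops <- make_populations(config)
  env <- sample_env_at_sites(env, pops$sites)
  gg <- make_genotypes(pops$sites, pops$truth, env, config)
  list(genotypes = gg$genotypes, sites = pops$sites, env = env,
       truth = gg$truth, config = config)
}
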