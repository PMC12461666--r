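# Adaptive landscapes and genomic offsets: adaptively enriched RDA,
# per-cell adaptive indices, temporal/spatial/donor offsets, rank-based
# z-prime standardization against the contemporary spatial-offset
# reference distribution, and the z' = 1 vulnerability threshold.

#' Adaptively enriched RDA
#'
#' RDA of per-site allele frequencies at the candidate adaptive loci on
#' the (site-level) environmental variables, with no conditioners; the
#' first two axes are conventionally retained for the adaptive landscape.
#'
#' @param candidate_freqs sites x candidate-loci matrix of allele
#'   frequencies.
#' @param env_site_values data.frame of environmental values at the same
#'   sites (columns = variables).
#' @return An `rda_model` (see [rda_fit()]).
#' @export
enriched_rda <- function(candidate_freqs, env_site_values) {
  Yf <- as.matrix(candidate_freqs)
  check_that(ncol(Yf) >= 1, "no candidate loci supplied")
  check_that(nrow(Yf) >= 3, "need >= 3 sites for the enriched RDA")
  rda_fit(Yf, env_site_values)
}

#' Site-level allele frequencies of selected loci
#'
#' Mean dosage / 2 per site over non-missing calls.
#'
#' @param g a [genotype_matrix()].
#' @param sites site frame.
#' @param loci locus ids to keep (default all).
#' @return matrix sites x loci; rownames are site ids.
#' @export
site_allele_freqs <- function(g, sites, loci = g$locus_meta$id) {
  keep <- match(loci, g$locus_meta$id)
  check_that(!anyNA(keep), "unknown locus id(s)")
  X <- g$values[, keep, drop = FALSE] / 2
  sid <- sites$site_id[match(g$individual_ids, sites$individual_id)]
  agg <- rowsum(ifelse(is.na(X), 0, X), sid) /
    pmax(rowsum(1 - is.na(X) * 1, sid), 1)
  agg
}

#' Project the adaptive index across the environmental grid
#'
#' For grid cell `c` and retained axis `r` the adaptive index is
#' `sum_i a_ir * b_ic`, where `a_ir` is variable `i`'s loading on axis `r`
#' (its correlation with the axis) and `b_ic` its standardized value in
#' cell `c`.  Standardization statistics (mean, SD per variable) come from
#' the present-period calibration sites stored in `env`, so the site-based
#' model and the grid projection share one scale.
#'
#' @param model `rda_model` from [enriched_rda()].
#' @param env an `env_layers` with standardization attached.
#' @param period `"present"` or `"future"`.
#' @param axes integer vector of axes (default 1:2, capped at the model's
#'   axis count).
#' @return list of class `adaptive_landscape`: `index` (list of per-axis
#'   grids), `axes`, `loadings`, `eig_share`, grid geometry.
#' @export
adaptive_index <- function(model, env, period = c("present", "future"),
                           axes = 1:2) {
  period <- match.arg(period)
  axes <- axes[axes <= ncol(model$variable_loadings)]
  check_that(length(axes) >= 1, "model has no canonical axes to project")
  vars <- rownames(model$variable_loadings)
  missing_vars <- setdiff(vars, names(env$grids[[period]]))
  check_that(length(missing_vars) == 0, "variable(s) missing from layer set: %s",
             paste(missing_vars, collapse = ", "))
  std <- env$standardization
  check_that(!is.null(std), "env has no standardization statistics")
  idx <- lapply(axes, function(r) {
    acc <- 0
    for (v in vars) {
      b <- (env$grids[[period]][[v]] - std$mean[std$variable == v]) /
        std$sd[std$variable == v]
      acc <- acc + model$variable_loadings[v, r] * b
    }
    acc
  })
  names(idx) <- paste0("RDA", axes)
  eig <- model$canonical_eigenvalues
  structure(list(index = idx, axes = axes,
                 loadings = model$variable_loadings[, axes, drop = FALSE],
                 eig_share = eig[axes] / sum(eig),
                 xllcorner = env$xllcorner, yllcorner = env$yllcorner,
                 cellsize = env$cellsize, period = period),
            class = "adaptive_landscape")
}

#' @export
print.adaptive_landscape <- function(x, ...) {
  cat(sprintf("adaptive_landscape (%s): axes %s on a %d x %d grid\n",
              x$period, paste(x$axes, collapse = ","),
              nrow(x$index[[1]]), ncol(x$index[[1]])))
  invisible(x)
}

offset_weights <- function(landscape, weighting) {
  switch(weighting,
         none = rep(1, length(landscape$axes)),
         sqrt_eigenvalue = sqrt(landscape$eig_share),
         stop("unknown weighting: ", weighting))
}

#' Raw genomic offset between two adaptive landscapes
#'
#' Per cell, the Euclidean distance between the axis-vectors of landscape
#' `A` and landscape `B` (temporal offset when A and B are the same place
#' at two periods).  Axes may be weighted by the square root of their
#' canonical-eigenvalue share (the default) or left unweighted.
#'
#' @param landscape_a,landscape_b `adaptive_landscape`s on the same grid
#'   and axes.
#' @param weighting `"sqrt_eigenvalue"` or `"none"`.
#' @return matrix of non-negative offsets.
#' @export
genomic_offset <- function(landscape_a, landscape_b,
                           weighting = c("sqrt_eigenvalue", "none")) {
  weighting <- match.arg(weighting)
  check_that(identical(landscape_a$axes, landscape_b$axes),
             "landscapes use different axes")
  check_that(all(dim(landscape_a$index[[1]]) == dim(landscape_b$index[[1]])),
             "landscapes use different grids")
  w <- offset_weights(landscape_a, weighting)
  acc <- 0
  for (j in seq_along(landscape_a$axes)) {
    acc <- acc + (w[j] * (landscape_a$index[[j]] - landscape_b$index[[j]]))^2
  }
  sqrt(acc)
}

#' Reference distribution of contemporary spatial offsets
#'
#' Offsets between unordered pairs of valid grid cells of the present-day
#' landscape: all pairs when few, otherwise a seeded uniform subsample of
#' `max_pairs` pairs.  This empirical distribution of present-day spatial
#' environmental contrast anchors the z' standardization.
#'
#' @param landscape_present present-period `adaptive_landscape`.
#' @param max_pairs cap on sampled pairs (default 2e6).
#' @param seed integer seed for the subsample.
#' @param weighting axis weighting, as in [genomic_offset()].
#' @return list of class `reference_distribution`: sorted `values`,
#'   `n_pairs_sampled`, `seed`.
#' @export
reference_distribution <- function(landscape_present, max_pairs = 2e6,
                                   seed = 1L,
                                   weighting = c("sqrt_eigenvalue", "none")) {
  weighting <- match.arg(weighting)
  A <- sapply(landscape_present$index, as.vector)
  A <- matrix(A, ncol = length(landscape_present$axes))
  valid <- which(stats::complete.cases(A))
  m <- length(valid)
  check_that(m >= 2, "need >= 2 valid (non-NODATA) cells")
  w <- offset_weights(landscape_present, weighting)
  Aw <- sweep(A[valid, , drop = FALSE], 2, w, "*")
  n_all <- m * (m - 1) / 2
  if (n_all <= max_pairs) {
    vals <- as.vector(stats::dist(Aw))
    n_sampled <- n_all
  } else {
    vals <- with_seed(seed, {
      i <- sample.int(m, max_pairs, replace = TRUE)
      j <- sample.int(m - 1, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)   # j != i, uniform over ordered pairs
      sqrt(rowSums((Aw[i, , drop = FALSE] - Aw[j, , drop = FALSE])^2))
    })
    n_sampled <- max_pairs
  }
  structure(list(values = sort(vals), n_pairs_sampled = n_sampled,
                 seed = seed, weighting = weighting),
            class = "reference_distribution")
}

#' Rank-based z' standardization of genomic offsets
#'
#' Maps raw offsets to z'-scores through the empirical CDF of the
#' contemporary spatial-offset reference distribution:
#' `z'(x) = qnorm((1 + F(x)) / 2)`, with `F` linearly interpolated between
#' order statistics (plotting positions `i / (n + 1)`) and clamped to
#' `[1/(n+1), n/(n+1)]`.  This half-normal quantile map puts z' = 1 at the
#' 68.27th percentile of the reference and z' = 2 at the 95.45th (the
#' Empirical Rule) by construction; z' is *not* a number of standard
#' deviations.
#'
#' @param raw_offsets numeric vector or matrix of raw offsets.
#' @param reference a `reference_distribution` (or numeric vector of
#'   reference offsets).
#' @return z'-scores with the shape of `raw_offsets`.
#' @export
zprime <- function(raw_offsets, reference) {
  ref <- if (inherits(reference, "reference_distribution"))
    reference$values else sort(as.numeric(reference))
  n <- length(ref)
  check_that(n >= 2 && length(unique(ref)) >= 2,
             "degenerate reference distribution")
  pp <- seq_len(n) / (n + 1)
  Fhat <- stats::approx(ref, pp, xout = as.vector(raw_offsets),
                        rule = 2, ties = list("ordered", max))$y
  z <- stats::qnorm((1 + Fhat) / 2)
  if (is.matrix(raw_offsets)) z <- matrix(z, nrow(raw_offsets), ncol(raw_offsets))
  z
}

#' Threshold mask of vulnerable cells
#'
#' Flags cells whose z'-score exceeds the not-to-exceed threshold
#' (default z' = 1); the count and fraction are logged.
#'
#' @param z matrix (or vector) of z'-scores.
#' @param threshold the not-to-exceed threshold.
#' @return logical mask with the shape of `z` (`NA` propagates).
#' @export
threshold_mask <- function(z, threshold = 1) {
  mask <- z > threshold
  go_log("threshold_mask: %d of %d cells (%.2f%%) exceed z' = %g",
         sum(mask, na.rm = TRUE), sum(!is.na(mask)),
         100 * mean(mask, na.rm = TRUE), threshold)
  mask
}

#' Donor offset surface for a recipient cell
#'
#' For every potential donor cell `d`, the raw donor offset is the
#' distance between `d`'s *present* adaptive index and the recipient
#' cell's *future* adaptive index, standardized with the same contemporary
#' spatial reference distribution as the temporal offset.  Suitable donors
#' have z' below the threshold; evaluated at the recipient cell itself the
#' donor offset equals that cell's temporal offset.
#'
#' @param landscape_present,landscape_future present and future
#'   `adaptive_landscape`s.
#' @param recipient_cell integer `(row, col)` of the recipient.
#' @param reference a `reference_distribution`.
#' @param threshold suitability threshold on z'.
#' @param weighting axis weighting, as in [genomic_offset()].
#' @return list of class `offset_surface`: `raw`, `z`, `suitable` (logical
#'   grid), `ranking` (data.frame of cells sorted by z'), `recipient_cell`.
#' @export
donor_offset <- function(landscape_present, landscape_future, recipient_cell,
                         reference, threshold = 1,
                         weighting = c("sqrt_eigenvalue", "none")) {
  weighting <- match.arg(weighting)
  check_that(identical(landscape_present$axes, landscape_future$axes),
             "landscapes use different axes")
  ri <- recipient_cell[1]; ci <- recipient_cell[2]
  target <- vapply(landscape_future$index, function(m) m[ri, ci], numeric(1))
  check_that(all(is.finite(target)), "recipient cell has no data (NODATA)")
  w <- offset_weights(landscape_present, weighting)
  acc <- 0
  for (j in seq_along(landscape_present$axes)) {
    acc <- acc + (w[j] * (landscape_present$index[[j]] - target[j]))^2
  }
  raw <- sqrt(acc)
  z <- zprime(raw, reference)
  suitable <- z < threshold
  ord <- order(z)
  nr <- nrow(raw)
  ranking <- data.frame(row = (ord - 1L) %% nr + 1L,
                        col = (ord - 1L) %/% nr + 1L,
                        raw = raw[ord], z = z[ord],
                        suitable = suitable[ord])
  structure(list(raw = raw, z = z, suitable = suitable, ranking = ranking,
                 recipient_cell = recipient_cell, threshold = threshold),
            class = "offset_surface")
}
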