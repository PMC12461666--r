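# Config-driven orchestration: simulate (or load) -> filter -> structure ->
# variable selection -> GEA -> offsets -> reports, with one master seed and
# per-stage logging.  Stages communicate through returned objects and the
# plain-text artifacts written under the output directory.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis; round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param sim named list of [sim_config()] overrides (the synthetic input).
#' @param maf_min,one_per_contig locus filter settings.
#' @param K_range candidate cluster numbers for [choose_K()].
#' @param mask_fraction masked-entry fraction for the CV of K.
#' @param n_restarts random restarts for [estimate_ancestry()].
#' @param select_alpha,select_n_perm forward-selection stopping level and
#'   permutation count.
#' @param varclus_cut absolute Spearman correlation defining a variable
#'   cluster branch.
#' @param n_pcs principal components for the pcadapt-style scan.
#' @param q_threshold per-method FDR threshold.
#' @param candidate_mode `"consensus"`, `"union"` or `"all"` — which locus
#'   set feeds the enriched RDA (sensitivity switch).
#' @param axes RDA axes used for the adaptive landscape.
#' @param weighting axis weighting for offsets.
#' @param z_threshold not-to-exceed threshold on z'.
#' @param max_pairs reference-distribution pair cap.
#' @param n_perm permutations for differentiation tests.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(),
                            maf_min = 0.05, one_per_contig = TRUE,
                            K_range = 1:6, mask_fraction = 0.1,
                            n_restarts = 2L,
                            select_alpha = 0.01, select_n_perm = 199L,
                            varclus_cut = 0.7,
                            n_pcs = 2L, q_threshold = 0.05,
                            candidate_mode = c("consensus", "union", "all"),
                            axes = 1:2,
                            weighting = c("sqrt_eigenvalue", "none"),
                            z_threshold = 1,
                            max_pairs = 2e6,
                            n_perm = 999L,
                            seed = 1L,
                            out_dir = "geaoffset_run") {
  cfg <- list(sim = sim, maf_min = maf_min, one_per_contig = one_per_contig,
              K_range = K_range, mask_fraction = mask_fraction,
              n_restarts = as.integer(n_restarts),
              select_alpha = select_alpha,
              select_n_perm = as.integer(select_n_perm),
              varclus_cut = varclus_cut,
              n_pcs = as.integer(n_pcs), q_threshold = q_threshold,
              candidate_mode = match.arg(candidate_mode),
              axes = axes, weighting = match.arg(weighting),
              z_threshold = z_threshold, max_pairs = max_pairs,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$candidate_mode <- raw$candidate_mode %||% "consensus"
  raw$weighting <- raw$weighting %||% "sqrt_eigenvalue"
  do.call(pipeline_config, raw)
}

# Per-individual environmental values for one period.
env_at_individuals <- function(env, sites, period = "present",
                               vars = NULL) {
  sv <- env$site_values[[period]]
  if (is.null(vars)) vars <- setdiff(names(sv), "site_id")
  out <- sv[match(sites$site_id, sv$site_id), vars, drop = FALSE]
  rownames(out) <- sites$individual_id
  out
}

stage_seed <- function(config, k) (config$seed * 131L + k * 7919L) %% .Machine$integer.max

#' Run the full landscape-genomics pipeline
#'
#' Simulates (or loads) the dataset, applies the locus filters, runs the
#' population-structure battery (PCA, cross-validated K, ancestry,
#' imputation, Q interpolation, AMOVA, F_ST, IBD), selects environmental
#' variables (forward selection + Spearman variable clustering), detects
#' candidate adaptive loci by the three GEA methods plus consensus, builds
#' the adaptive landscape and temporal offset with z' standardization and
#' the threshold mask, and maps donor suitability for the most exposed
#' cell.  All artifacts are written as plain-text CSV / TSV / ESRI ASCII
#' files plus a JSON manifest; identical config + seed gives byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param data optional pre-built dataset (as from [simulate_dataset()]);
#'   when `NULL` the `sim` settings of the config are simulated.
#' @return invisible list with the main stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package = "geaoffset",
                   version = as.character(utils::packageVersion("geaoffset")),
                   seed = config$seed)

  # -- stage: simulate -------------------------------------------------------
  if (is.null(data)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    data <- simulate_dataset(scfg)
  }
  g <- data$genotypes; sites <- data$sites; env <- data$env
  validate_sites(sites, g)
  write_genotypes(g, out("genotypes.tsv"))
  utils::write.csv(sites, out("sites.csv"), row.names = FALSE)
  if (!is.null(data$truth$adaptive_loci)) {
    utils::write.csv(data$truth$adaptive_loci, out("truth_adaptive_loci.csv"),
                     row.names = FALSE)
  }
  for (v in names(env$grids$present)) {
    for (per in c("present", "future")) {
      write_ascii_grid(env$grids[[per]][[v]],
                       out(sprintf("env_%s_%s.asc", v, per)),
                       env$xllcorner, env$yllcorner, env$cellsize)
    }
  }
  manifest$n_individuals <- nrow(g$values)
  manifest$n_loci_raw <- ncol(g$values)
  go_log("pipeline: input %d individuals x %d loci", nrow(g$values), ncol(g$values))

  # -- stage: filter ---------------------------------------------------------
  g <- filter_loci(g, maf_min = config$maf_min,
                   one_per_contig = config$one_per_contig)
  manifest$n_loci_filtered <- ncol(g$values)

  # -- stage: structure ------------------------------------------------------
  pca <- pca_genotypes(g, n_axes = 10)
  utils::write.csv(data.frame(individual_id = g$individual_ids,
                              pca$scores[, 1:2]),
                   out("pca_scores.csv"), row.names = FALSE)
  cv <- choose_K(g, K_range = config$K_range,
                 mask_fraction = config$mask_fraction,
                 seed = stage_seed(config, 2L), sites = sites,
                 n_restarts = config$n_restarts)
  utils::write.csv(cv, out("choose_K.csv"), row.names = FALSE)
  K_opt <- cv$K[which.min(cv$cv_error)]
  manifest$K_opt <- K_opt
  model <- estimate_ancestry(g, K_opt, seed = stage_seed(config, 3L),
                             n_restarts = config$n_restarts)
  utils::write.csv(data.frame(individual_id = rownames(model$Q), model$Q),
                   out("Q_matrix.csv"), row.names = FALSE)
  g_imp <- impute_genotypes(g, model)
  interp <- interpolate_Q(model, sites, env)
  write_ascii_grid(interp$modal, out("modal_group.asc"),
                   env$xllcorner, env$yllcorner, env$cellsize)
  am <- amova(g, sites$zone, n_perm = config$n_perm,
              seed = stage_seed(config, 4L))
  gfst <- global_fst(g, sites$zone)
  pfst <- pairwise_fst(g, sites$zone, n_perm = 99L,
                       seed = stage_seed(config, 5L))
  D_geo <- geodesic_matrix(sites, by = "zone")
  ibd <- ibd_fit(pfst$theta[rownames(D_geo), rownames(D_geo)], D_geo,
                 n_perm = config$n_perm, seed = stage_seed(config, 6L))
  utils::write.csv(data.frame(statistic = c("phi_st", "amova_p", "global_fst",
                                            "ibd_mantel_r", "ibd_mantel_p",
                                            "ibd_slope_per_100km", "ibd_r2"),
                              value = c(am$phi_st, am$p_perm, gfst,
                                        ibd$mantel_r, ibd$mantel_p,
                                        ibd$slope_per_100km, ibd$r2)),
                   out("differentiation.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(pfst$theta), out("pairwise_fst.csv"))

  # -- stage: select-env -----------------------------------------------------
  E_ind <- env_at_individuals(env, sites)
  Y <- sweep(g_imp$values, 2, colMeans(g_imp$values))
  fs <- forward_select(Y, E_ind, alpha = config$select_alpha,
                       n_perm = config$select_n_perm,
                       seed = stage_seed(config, 7L))
  utils::write.csv(fs$trace, out("forward_selection.csv"), row.names = FALSE)
  sel <- fs$selected
  if (length(sel) >= 2) {
    vc <- varclus_spearman(E_ind[, sel, drop = FALSE],
                           cut = config$varclus_cut)
    # representative per branch: the earliest-selected variable
    sel <- sel[!duplicated(vc$membership[sel])]
  }
  if (!length(sel)) {
    go_log("pipeline: forward selection empty; keeping all variables")
    sel <- colnames(E_ind)
  }
  manifest$selected_env <- sel

  # variance partitioning among environment, geography and ancestry
  if (model$K > 1) {
    geo_tab <- data.frame(lon = sites$longitude, lat = sites$latitude)
    vp <- variance_partition(Y, E_ind[, sel, drop = FALSE], geo_tab,
                             model$Q[, -model$K, drop = FALSE],
                             n_perm = config$n_perm,
                             seed = stage_seed(config, 9L))
    utils::write.csv(as.data.frame(vp), out("variance_partition.csv"),
                     row.names = FALSE)
  } else {
    go_log("pipeline: K_opt = 1, skipping ancestry block of the variance partition")
  }

  # -- stage: gea ------------------------------------------------------------
  Zcond <- model$Q[, -model$K, drop = FALSE]   # drop one column: simplex rows
  Ygea <- gea_response(g_imp, scaling = "binomial")
  gea_model <- if (ncol(Zcond) > 0) {
    rda_fit(Ygea, E_ind[, sel, drop = FALSE], Z = Zcond)
  } else {
    rda_fit(Ygea, E_ind[, sel, drop = FALSE])
  }
  k_axes <- min(max(config$axes), length(gea_model$canonical_eigenvalues))
  rd <- rdadapt(gea_model, k_axes = k_axes, q_threshold = config$q_threshold)
  pc_scan <- pcadapt_like(g_imp, n_pcs = config$n_pcs,
                          q_threshold = config$q_threshold)
  lf <- lfmm_like(g_imp, E_ind[, sel, drop = FALSE], K_latent = K_opt,
                  q_threshold = config$q_threshold)
  hits <- list(rda = rd$id[rd$hit], pcadapt = pc_scan$id[pc_scan$hit],
               lfmm = lf$id[lf$hit])
  cons <- suppressWarnings(consensus_loci(hits, min_methods = 2))
  candidates <- switch(config$candidate_mode,
                       consensus = cons,
                       union = unique(unlist(hits)),
                       all = g$locus_meta$id)
  if (!length(candidates)) {
    go_log("pipeline: %s candidate set empty; falling back to union",
           config$candidate_mode)
    candidates <- unique(unlist(hits))
  }
  check_that(length(candidates) > 0, "no candidate loci from any method")
  per_locus <- data.frame(id = g$locus_meta$id,
                          rda_q = rd$q, pcadapt_q = pc_scan$q, lfmm_q = lf$q,
                          rda_hit = rd$hit, pcadapt_hit = pc_scan$hit,
                          lfmm_hit = lf$hit,
                          consensus = g$locus_meta$id %in% cons)
  utils::write.csv(per_locus, out("gea_per_locus.csv"), row.names = FALSE)
  manifest$gea_counts <- lapply(hits, length)
  manifest$n_consensus <- length(cons)
  manifest$n_candidates <- length(candidates)

  # -- stage: offset ---------------------------------------------------------
  freqs <- site_allele_freqs(g_imp, sites, loci = candidates)
  sv <- env$site_values$present
  E_site <- sv[match(rownames(freqs), sv$site_id), sel, drop = FALSE]
  en_model <- enriched_rda(freqs, E_site)
  axes <- config$axes[config$axes <= length(en_model$canonical_eigenvalues)]
  land_p <- adaptive_index(en_model, env, "present", axes = axes)
  land_f <- adaptive_index(en_model, env, "future", axes = axes)
  raw <- genomic_offset(land_p, land_f, weighting = config$weighting)
  ref <- reference_distribution(land_p, max_pairs = config$max_pairs,
                                seed = stage_seed(config, 8L),
                                weighting = config$weighting)
  z <- zprime(raw, ref)
  mask <- threshold_mask(z, config$z_threshold)
  for (nm in seq_along(axes)) {
    write_ascii_grid(land_p$index[[nm]],
                     out(sprintf("adaptive_index_RDA%d_present.asc", axes[nm])),
                     env$xllcorner, env$yllcorner, env$cellsize)
    write_ascii_grid(land_f$index[[nm]],
                     out(sprintf("adaptive_index_RDA%d_future.asc", axes[nm])),
                     env$xllcorner, env$yllcorner, env$cellsize)
  }
  write_ascii_grid(raw, out("temporal_offset_raw.asc"),
                   env$xllcorner, env$yllcorner, env$cellsize)
  write_ascii_grid(z, out("temporal_offset_zprime.asc"),
                   env$xllcorner, env$yllcorner, env$cellsize)
  write_ascii_grid(mask * 1, out("vulnerable_mask.asc"),
                   env$xllcorner, env$yllcorner, env$cellsize)
  utils::write.csv(data.frame(quantile = c(0, 0.25, 0.5, 0.75, 1),
                              value = stats::quantile(ref$values,
                                                      c(0, 0.25, 0.5, 0.75, 1),
                                                      names = FALSE)),
                   out("reference_summary.csv"), row.names = FALSE)
  manifest$n_vulnerable <- sum(mask, na.rm = TRUE)
  manifest$z_range <- range(z)

  # -- stage: donor ----------------------------------------------------------
  worst <- which(z == max(z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  donor <- donor_offset(land_p, land_f, worst, ref,
                        threshold = config$z_threshold,
                        weighting = config$weighting)
  write_ascii_grid(donor$z, out("donor_zprime.asc"),
                   env$xllcorner, env$yllcorner, env$cellsize)
  utils::write.csv(utils::head(donor$ranking, 100), out("donor_ranking.csv"),
                   row.names = FALSE)
  manifest$recipient_cell <- as.integer(worst)
  manifest$n_suitable_donors <- sum(donor$suitable, na.rm = TRUE)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genotypes = g, sites = sites, env = env, pca = pca,
                 choose_K = cv, ancestry = model, amova = am,
                 global_fst = gfst, pairwise_fst = pfst, ibd = ibd,
                 selected_env = sel, gea = per_locus, candidates = candidates,
                 enriched = en_model, landscape_present = land_p,
                 landscape_future = land_f, offset_raw = raw, zprime = z,
                 mask = mask, donor = donor, manifest = manifest))
}
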