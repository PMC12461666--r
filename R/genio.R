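# Genotype / site / raster input-output and locus filtering.

#' Construct a genotype matrix object
#'
#' The central genotype container: an individuals x loci integer matrix of
#' alternate-allele dosages (0, 1, 2, or `NA` for missing calls) with
#' per-locus metadata.
#'
#' @param values integer matrix, individuals x loci, entries in
#'   `{0, 1, 2, NA}`.
#' @param locus_meta data.frame with columns `id`, `contig`, `position`,
#'   `ref`, `alt`; one row per locus, `id` unique.
#' @param individual_ids character vector, one per row of `values`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, locus_meta, individual_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  check_that(all(values %in% c(0L, 1L, 2L) | is.na(values)),
             "genotype values must be 0, 1, 2 or NA")
  check_that(nrow(locus_meta) == ncol(values),
             "locus_meta rows (%d) != number of loci (%d)",
             nrow(locus_meta), ncol(values))
  check_that(length(individual_ids) == nrow(values),
             "individual_ids length (%d) != number of individuals (%d)",
             length(individual_ids), nrow(values))
  check_that(!anyDuplicated(locus_meta$id), "locus ids must be unique")
  rownames(values) <- individual_ids
  colnames(values) <- locus_meta$id
  structure(list(values = values,
                 locus_meta = as.data.frame(locus_meta),
                 individual_ids = as.character(individual_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Per-locus alternate allele frequency
#'
#' Allele counts over non-missing calls only; loci with no calls give `NaN`.
#' @param g a [genotype_matrix()].
#' @return numeric vector of length `ncol(g$values)` in `[0, 1]`.
#' @export
allele_freq <- function(g) {
  colMeans(g$values, na.rm = TRUE) / 2
}

#' Validate an individual -> site table against a genotype matrix
#'
#' A site frame is a plain data.frame with columns `individual_id`,
#' `site_id`, `longitude`, `latitude`, `zone`.  Every individual of `g`
#' must appear exactly once.
#' @param sites data.frame as above.
#' @param g optional [genotype_matrix()] to cross-check individuals.
#' @return `sites`, invisibly, after validation.
#' @export
validate_sites <- function(sites, g = NULL) {
  need <- c("individual_id", "site_id", "longitude", "latitude", "zone")
  miss <- setdiff(need, names(sites))
  check_that(length(miss) == 0L, "site table missing column(s): %s",
             paste(miss, collapse = ", "))
  check_that(all(abs(sites$latitude) <= 90), "latitudes must lie in [-90, 90]")
  check_that(!anyDuplicated(sites$individual_id),
             "duplicated individual_id in site table")
  if (!is.null(g)) {
    check_that(setequal(sites$individual_id, g$individual_ids),
               "site table and genotype matrix list different individuals")
  }
  invisible(sites)
}

# ---------------------------------------------------------------------------
# 0/1/2 TSV matrix (canonical interchange format)

#' Read or write genotypes
#'
#' `read_genotypes()` reads a genotype matrix from either the canonical
#' 0/1/2 tab-separated matrix (`format = "tsv012"`; header row of locus ids,
#' first column of individual ids, empty/`NA` cells = missing) or a minimal
#' biallelic VCF with GT fields (`format = "vcf"`).  For VCF, diploid GT is
#' converted to the dosage of the alternate allele, `./.` to missing, and
#' multiallelic records are dropped with a logged count.
#'
#' @param path file to read.
#' @param format `"vcf"` or `"tsv012"`.
#' @param locus_meta for `tsv012`, an optional data.frame of locus metadata
#'   (id, contig, position, ref, alt); defaults are synthesized from the
#'   header when absent.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv012", "vcf"),
                           locus_meta = NULL) {
  format <- match.arg(format)
  check_that(file.exists(path), "file not found: %s", path)
  if (format == "tsv012") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "integer"
    if (is.null(locus_meta)) {
      locus_meta <- data.frame(id = colnames(vals),
                               contig = colnames(vals),
                               position = seq_len(ncol(vals)),
                               ref = "A", alt = "T",
                               stringsAsFactors = FALSE)
    }
    return(genotype_matrix(vals, locus_meta, ids))
  }
  read_genotypes_vcf(path)
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path, n = 2000L)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) == 0L) {
    stop(sprintf("malformed VCF header in %s: no #CHROM line found within the first %d lines",
                 path, length(lines)), call. = FALSE)
  }
  cols <- strsplit(lines[hdr[1]], "\t")[[1]]
  if (length(cols) < 10L || !identical(cols[1:9],
      c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT"))) {
    stop(sprintf("malformed VCF header at line %d of %s", hdr[1], path),
         call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    go_log("read_genotypes: rejected %d multiallelic record(s)", sum(multi))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  ok <- is.na(gt) | grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gt)
  if (!all(ok)) {
    stop(sprintf("non-diploid GT encountered (e.g. '%s')", gt[!ok][1]),
         call. = FALSE)
  }
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  dose <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dose[is.na(gt) | a1 == "." | a2 == "."] <- NA_integer_
  vals <- t(matrix(dose, nrow = nrow(fix)))
  ids <- colnames(gt)
  locus_ids <- fix[, "ID"]
  fallback <- is.na(locus_ids) | locus_ids == "."
  locus_ids[fallback] <- paste0(fix[fallback, "CHROM"], "_", fix[fallback, "POS"])
  meta <- data.frame(id = locus_ids,
                     contig = fix[, "CHROM"],
                     position = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_matrix(vals, meta, ids)
}

#' @rdname read_genotypes
#' @param g a [genotype_matrix()] to write.
#' @export
write_genotypes <- function(g, path, format = c("tsv012", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv012") {
    tab <- data.frame(individual_id = g$individual_ids,
                      g$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  m <- g$locus_meta
  gtxt <- g$values
  codes <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  body <- vapply(seq_len(ncol(gtxt)), function(l) {
    gl <- gtxt[, l]
    s <- ifelse(is.na(gl), "./.", codes[as.character(gl)])
    paste(c(m$contig[l], m$position[l], m$id[l], m$ref[l], m$alt[l],
            ".", "PASS", ".", "GT", s), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$individual_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Locus filters

#' Filter loci by minor allele frequency and contig
#'
#' Minor-allele frequency is computed over non-missing allele calls only.
#' Loci with MAF below `maf_min` are removed; when `one_per_contig = TRUE`
#' only one SNP is retained per contig: the locus with the highest call
#' rate, ties broken by lowest position.  The operation is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param one_per_contig keep a single SNP per contig?
#' @return The filtered [genotype_matrix()]; the filter report is logged.
#' @export
filter_loci <- function(g, maf_min = 0.05, one_per_contig = TRUE) {
  check_that(maf_min >= 0 && maf_min <= 0.5, "maf_min must lie in [0, 0.5]")
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min
  n_maf <- sum(!keep)
  if (one_per_contig) {
    idx <- which(keep)
    if (length(idx)) {
      call_rate <- colMeans(!is.na(g$values[, idx, drop = FALSE]))
      ord <- order(g$locus_meta$contig[idx], -call_rate,
                   g$locus_meta$position[idx])
      first <- !duplicated(g$locus_meta$contig[idx][ord])
      sel <- sort(idx[ord][first])
      keep <- logical(length(keep))
      keep[sel] <- TRUE
    }
  }
  n_contig <- sum(!keep) - n_maf
  go_log("filter_loci: %d loci in; %d removed at MAF < %.3g; %d removed as contig duplicates; %d retained",
         ncol(g$values), n_maf, maf_min, max(n_contig, 0), sum(keep))
  if (!any(keep)) warning("filter_loci: no loci retained", call. = FALSE)
  genotype_matrix(g$values[, keep, drop = FALSE],
                  g$locus_meta[keep, , drop = FALSE],
                  g$individual_ids)
}

# ---------------------------------------------------------------------------
# ESRI ASCII rasters

#' Read and write ESRI ASCII grids
#'
#' Minimal, exact reader/writer for the 6-line-header ESRI ASCII raster
#' dialect (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`; data rows run north to south).  NODATA cells map to `NA`.
#'
#' @param path file path.
#' @return `read_ascii_grid()`: a list with `values` (matrix, row 1 =
#'   northernmost), `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  check_that(all(need %in% keys), "ESRI ASCII header incomplete in %s", path)
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  body <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  check_that(length(body) == nc * nr,
             "grid body has %d values, header promises %d (%s)",
             length(body), nc * nr, path)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  list(values = m, xllcorner = unname(vals["xllcorner"]),
       yllcorner = unname(vals["yllcorner"]),
       cellsize = unname(vals["cellsize"]),
       nodata = unname(vals["nodata_value"]))
}

#' @rdname read_ascii_grid
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell size (square cells).
#' @param nodata value standing in for `NA` cells on disk.
#' @export
write_ascii_grid <- function(values, path, xllcorner, yllcorner, cellsize,
                             nodata = -9999) {
  values <- as.matrix(values)
  out <- values
  out[is.na(out)] <- nodata
  hdr <- c(paste("ncols", ncol(values)),
           paste("nrows", nrow(values)),
           paste("xllcorner", format(xllcorner, digits = 15)),
           paste("yllcorner", format(yllcorner, digits = 15)),
           paste("cellsize", format(cellsize, digits = 15)),
           paste("NODATA_value", nodata))
  body <- apply(out, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
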