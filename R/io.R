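# Readers for the standard file layouts (VCF genotypes with QC, expression
# / covariate / annotation tables, TSS BED) and writers for result tables.
# Coordinates are 1-based in VCF and in memory; BED input is converted from
# 0-based half-open at read time.

#' Genotype QC settings
#'
#' @param gq_min genotype-quality threshold: calls with GQ below it are
#'   marked missing (default 20).
#' @param site_missing_max maximum per-site missing rate before the site is
#'   removed (default 0.05).
#' @param maf_max rarity cutoff: sites are kept when the post-imputation
#'   minor allele frequency is in `(0, maf_max)` (default 0.05; 0.01 for
#'   the strict rare-variant definition).
#' @param drop_vqsr_fail remove sites whose FILTER field is neither `PASS`
#'   nor `.` (default `TRUE`).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(gq_min = 20, site_missing_max = 0.05, maf_max = 0.05,
                      drop_vqsr_fail = TRUE) {
  stopifnot(gq_min >= 0, site_missing_max >= 0, site_missing_max <= 1,
            maf_max > 0, maf_max <= 0.5)
  structure(list(gq_min = gq_min, site_missing_max = site_missing_max,
                 maf_max = maf_max, drop_vqsr_fail = drop_vqsr_fail),
            class = "qc_config")
}

# Count occurrences of allele index `allele` in a vector of GT strings
# ("0/1", "1|1", "./."); NA for missing calls.
gt_allele_counts <- function(gt, allele) {
  codes <- unique(gt)
  per_code <- vapply(codes, function(cc) {
    if (is.na(cc)) return(NA_integer_)
    al <- strsplit(gsub("|", "/", cc, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == as.character(allele))
  }, 0L)
  per_code[match(gt, codes)]
}

#' Read genotypes from a VCF with quality control
#'
#' QC chain: autosomal sites only; sites failing VQSR (non-PASS FILTER)
#' removed; multiallelic records split into per-alternate-allele variants;
#' genotype calls with GQ below `gq_min` marked missing; sites with a
#' missing rate above `site_missing_max` removed; remaining missing calls
#' imputed as homozygous reference (dosage 0, justified by the low
#' frequency of rare variants); minor allele frequency computed after
#' imputation (flipping to the reference allele when the alternate is the
#' major allele); sites kept when `0 < maf < maf_max`. Every removal is
#' counted by reason, and input sites = survivors + removals.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF with GT, and
#'   GQ where available.
#' @param qc a [qc_config()].
#' @return A list: `variants` (a [variant_set()], samples x variants),
#'   `samples`, `report` (tibble reason, n), `n_input`.
#' @export
read_genotypes_with_qc <- function(vcf_path, qc = qc_config()) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  n_input <- nrow(fix)
  report <- c(non_autosomal = 0L, vqsr_fail = 0L, missing_rate = 0L,
              monomorphic = 0L, not_rare = 0L)

  autosomes <- c(as.character(1:22), paste0("chr", 1:22))
  keep <- fix$CHROM %in% autosomes
  report["non_autosomal"] <- sum(!keep)
  if (qc$drop_vqsr_fail) {
    fail <- !(is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."))
    report["vqsr_fail"] <- sum(fail & keep)
    keep <- keep & !fail
  }
  if (!any(keep)) {
    stop("no autosomal PASS sites in ", vcf_path, call. = FALSE)
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  has_gq <- any(grepl("GQ", vcf@gt[, 1], fixed = TRUE))
  if (has_gq) {
    gq <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  } else {
    warning("VCF has no GQ field; genotype-quality filtering skipped")
    gq <- NULL
  }

  rows <- which(keep)
  out_dos <- list(); out_pos <- c(); out_id <- c(); out_chrom <- c()
  out_maf <- c()
  # per-site missing-rate and MAF bookkeeping happens per alternate allele
  n_multi_split <- 0L
  for (ri in rows) {
    alts <- strsplit(fix$ALT[ri], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1) n_multi_split <- n_multi_split + 1L
    gtr <- gt[ri, ]
    if (!is.null(gq)) gtr[!is.na(gq[ri, ]) & gq[ri, ] < qc$gq_min] <- NA
    miss <- is.na(gtr) | grepl(".", gtr, fixed = TRUE)
    if (mean(miss) > qc$site_missing_max) {
      report["missing_rate"] <- report["missing_rate"] + 1L
      next
    }
    site_kept <- FALSE
    site_mono <- FALSE
    for (ai in seq_along(alts)) {
      dos <- gt_allele_counts(gtr, ai)
      dos[is.na(dos)] <- 0L  # impute missing as homozygous reference
      p_alt <- mean(dos) / 2
      if (p_alt > 0.5) {  # alternate is the major allele; flip
        dos <- 2L - dos
        p_alt <- 1 - p_alt
      }
      if (p_alt == 0) { site_mono <- TRUE; next }
      if (p_alt >= qc$maf_max) { next }
      out_dos[[length(out_dos) + 1L]] <- dos
      vid <- if (!is.na(fix$ID[ri]) && fix$ID[ri] != ".") fix$ID[ri] else {
        paste0(fix$CHROM[ri], ":", fix$POS[ri], "_", fix$REF[ri], ">",
               alts[ai])
      }
      if (length(alts) > 1) vid <- paste0(vid, ":alt", ai)
      out_id <- c(out_id, vid)
      out_pos <- c(out_pos, as.integer(fix$POS[ri]))
      out_chrom <- c(out_chrom, fix$CHROM[ri])
      out_maf <- c(out_maf, p_alt)
      site_kept <- TRUE
    }
    if (!site_kept) {
      if (site_mono) report["monomorphic"] <- report["monomorphic"] + 1L
      else report["not_rare"] <- report["not_rare"] + 1L
    }
  }
  if (length(out_dos) == 0) {
    stop("no variants survive QC in ", vcf_path, call. = FALSE)
  }
  G <- do.call(cbind, out_dos)
  rownames(G) <- samples
  vs <- variant_set(G, maf = out_maf, positions = out_pos, ids = out_id,
                    chrom = out_chrom, maf_threshold = qc$maf_max)
  list(variants = vs, samples = samples,
       report = tibble::tibble(reason = names(report),
                               n = as.integer(report)),
       n_input = n_input, n_multiallelic_split = n_multi_split)
}

#' Read an expression matrix (genes x samples)
#'
#' Tab-separated, first column `gene_id`, one column per sample.
#'
#' @param path file path.
#' @return numeric matrix with gene-id rownames.
#' @export
read_expression <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb[[1]]
  m
}

#' Read a covariate table (samples x covariates)
#'
#' Tab-separated, first column `sample_id`.
#' @param path file path.
#' @return data frame with sample-id rownames.
#' @export
read_covariates <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  df <- as.data.frame(tb[, -1])
  rownames(df) <- tb[[1]]
  df
}

#' Read a per-variant annotation table
#'
#' Tab-separated with columns `id`, `chrom`, `pos`, and score columns such
#' as `cadd` and `linsight`.
#' @param path file path.
#' @return tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read gene TSS coordinates from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based on read.
#' The TSS is the interval start for `+` strand genes and the interval end
#' for `-` strand genes (strand column optional; `+` assumed).
#'
#' @param path BED file (chrom, start, end, gene_id, \[score, strand\]).
#' @return tibble: gene_id, chrom, tss, start, end, strand.
#' @export
read_tss <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  names(tb)[1:4] <- c("chrom", "start0", "end", "gene_id")
  strand <- if (ncol(tb) >= 6) tb[[6]] else rep("+", nrow(tb))
  tibble::tibble(
    gene_id = tb$gene_id, chrom = tb$chrom,
    start = tb$start0 + 1L, end = tb$end,
    strand = strand,
    tss = ifelse(strand == "-", tb$end, tb$start0 + 1L)
  )
}

#' Intersect sample sets across genotype, expression and covariate inputs
#'
#' @param genotype_samples,expression_samples,covariate_samples character
#'   vectors of sample ids.
#' @return A list: `samples` (the intersection, in genotype order),
#'   `dropped` (tibble source, sample_id). Errors when the intersection is
#'   empty, with id diagnostics.
#' @export
align_samples <- function(genotype_samples, expression_samples,
                          covariate_samples = NULL) {
  common <- intersect(genotype_samples, expression_samples)
  if (!is.null(covariate_samples)) common <- intersect(common,
                                                       covariate_samples)
  if (length(common) == 0) {
    stop("no samples shared across inputs; e.g. genotype ids ",
         paste(utils::head(genotype_samples, 3), collapse = ", "),
         " vs expression ids ",
         paste(utils::head(expression_samples, 3), collapse = ", "),
         call. = FALSE)
  }
  sets <- list(genotype = genotype_samples, expression = expression_samples)
  if (!is.null(covariate_samples)) sets$covariates <- covariate_samples
  dropped <- dplyr::bind_rows(lapply(names(sets), function(s) {
    d <- setdiff(sets[[s]], common)
    if (length(d) == 0) return(NULL)
    tibble::tibble(source = s, sample_id = d)
  }))
  list(samples = genotype_samples[genotype_samples %in% common],
       dropped = dropped)
}

#' Write a result table as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
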