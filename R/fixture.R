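# Synthetic fixture generator: a complete small dataset (VCF + expression +
# covariates + annotations + TSS BED + truth table) with the statistical
# structure of the simulation study, runnable through the whole pipeline.
# It stands in for access-controlled eQTL datasets and is labelled
# synthetic throughout.

#' Fixture generation settings
#'
#' Defaults describe the standard desk-scale fixture: 200 genes, 300
#' samples, ~30 rare variants per 20-kb TSS window (the scale of the
#' simulation study), 5 planted rare-variant
#' eGenes with effect constant `a = 1.5` and causal ratio 10%, one tissue.
#' Population MAFs are floored at `1/(2 n_samples)` so every variant is
#' observable in the cohort (as in a cohort-ascertained variant set), and
#' planted causal variants are drawn among variants with at least
#' `min_causal_carriers` carriers and an in-sample frequency safely below
#' the rarity cutoff, so a planted eGene actually carries signal in the
#' variant set the pipeline tests (a drawn "rare" variant whose realized
#' sample frequency drifts above the cutoff would be removed by QC and its
#' signal lost by construction).
#'
#' @param n_samples cohort size.
#' @param n_genes number of genes.
#' @param variants_per_window mean rare-variant count per gene window
#'   (Poisson).
#' @param n_planted number of planted rare-variant eGenes.
#' @param a,causal_ratio planted effect constant and causal fraction (see
#'   [phenotype_sim_config()]).
#' @param n_tissues number of tissues to emulate (expression files are
#'   written per tissue).
#' @param maf_threshold rarity cutoff.
#' @param min_causal_carriers minimum carrier count for a planted causal
#'   variant.
#' @param seed integer seed; fixtures are byte-identical given the seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples = 300, n_genes = 200,
                         variants_per_window = 30, n_planted = 5,
                         a = 1.5, causal_ratio = 0.1, n_tissues = 1,
                         maf_threshold = 0.05, min_causal_carriers = 3,
                         seed = 1) {
  stopifnot(n_planted <= n_genes, n_samples >= 10)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 variants_per_window = variants_per_window,
                 n_planted = n_planted, a = a, causal_ratio = causal_ratio,
                 n_tissues = n_tissues, maf_threshold = maf_threshold,
                 min_causal_carriers = min_causal_carriers, seed = seed),
            class = "fixture_spec")
}

#' Generate an on-disk synthetic eQTL fixture
#'
#' Writes `genotypes.vcf`, `expression_<tissue>.tsv`, `covariates.tsv`,
#' `annotations.tsv`, `tss.bed` and `truth.tsv` under `dir`. Genes are laid
#' out 100 kb apart on chr1 so 20-kb windows never overlap; each window
#' gets Poisson-many rare variants with spectrum-drawn MAFs (floored at
#' `1/(2N)`) and LD-free Binomial(2, maf) genotypes. Expression is
#' covariate effects plus noise, and for planted genes additionally
#' `beta' G` with `|beta_i| = a |log10 maf_i|` and mixed signs. The VCF
#' carries GT:GQ calls with a small rate of low-GQ and missing calls, one
#' decoy site with a high missing rate and one VQSR-failing decoy site, so
#' the QC chain is exercised end to end.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return A list: `paths` (named file paths), `truth` (tibble of planted
#'   genes and causal variants), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- spec$n_samples
  with_seed(spec$seed, {
    samples <- sprintf("S%04d", seq_len(N))
    gene_ids <- sprintf("GENE%04d", seq_len(spec$n_genes))
    tss <- 50000L + (seq_len(spec$n_genes) - 1L) * 100000L
    planted <- sort(sample.int(spec$n_genes, spec$n_planted))

    # genotypes per gene window
    all_pos <- c(); all_id <- c(); all_maf <- c(); dos_cols <- list()
    var_gene <- c()
    for (gi in seq_len(spec$n_genes)) {
      k <- 0L
      while (k == 0L) k <- rpois(1, spec$variants_per_window)
      maf <- pmax(draw_sfs_maf(k, 1 / (2 * N), spec$maf_threshold),
                  1 / (2 * N))
      pos <- sort(sample(seq(tss[gi] - 20000L, tss[gi] + 20000L), k))
      G <- matrix(rbinom(N * k, 2, rep(maf, each = N)), nrow = N)
      dos_cols[[gi]] <- G
      all_pos <- c(all_pos, pos)
      all_maf <- c(all_maf, maf)
      all_id <- c(all_id, sprintf("var_%s_%d", gene_ids[gi], seq_len(k)))
      var_gene <- c(var_gene, rep(gene_ids[gi], k))
    }
    G_all <- do.call(cbind, dos_cols)

    # covariates: sex, two expression PCs
    cov <- data.frame(sex = rbinom(N, 1, 0.5), pc1 = rnorm(N),
                      pc2 = rnorm(N), row.names = samples)

    # expression per tissue: covariate effects + (planted) signal + noise
    truth_rows <- list()
    expr_paths <- character(spec$n_tissues)
    for (ti in seq_len(spec$n_tissues)) {
      tissue <- sprintf("tissue%d", ti)
      E <- matrix(NA_real_, spec$n_genes, N,
                  dimnames = list(gene_ids, samples))
      gamma <- matrix(rnorm(spec$n_genes * 3, 0, 0.5), ncol = 3)
      covm <- as.matrix(cov)
      for (gi in seq_len(spec$n_genes)) {
        base <- as.numeric(covm %*% gamma[gi, ]) + rnorm(N) + rnorm(N)
        if (gi %in% planted) {
          Gg <- dos_cols[[gi]]
          carriers <- colSums(Gg > 0)
          emp_maf <- colMeans(Gg) / 2
          eligible <- which(carriers >= spec$min_causal_carriers &
                              emp_maf < 0.9 * spec$maf_threshold)
          s <- max(1L, as.integer(round(spec$causal_ratio * ncol(Gg))))
          s <- min(s, length(eligible))
          if (s == 0L) {
            eligible <- order(carriers, decreasing = TRUE)[1]
            s <- 1L
          }
          ci <- sort(sample(eligible, s))
          mafs <- all_maf[var_gene == gene_ids[gi]][ci]
          beta <- ifelse(runif(s) < 0.5, -1, 1) * spec$a * abs(log10(mafs))
          base <- base + as.numeric(Gg[, ci, drop = FALSE] %*% beta)
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            tissue = tissue, gene_id = gene_ids[gi],
            causal_id = sprintf("var_%s_%d", gene_ids[gi], ci),
            maf = mafs, beta = beta)
        }
        E[gi, ] <- base
      }
      expr_paths[ti] <- file.path(dir, sprintf("expression_%s.tsv", tissue))
      readr::write_tsv(
        tibble::as_tibble(E, rownames = "gene_id"), expr_paths[ti])
    }

    # VCF with GT:GQ; sprinkle low-GQ and missing calls, plus QC decoys
    k_tot <- ncol(G_all)
    # mostly high-confidence calls; ~0.5% low-GQ and ~0.2% missing calls
    gq <- matrix(pmin(99L, pmax(21L, as.integer(rnorm(N * k_tot, 80, 15)))),
                 nrow = N)
    low_gq <- runif(N * k_tot) < 0.005
    gq[low_gq] <- sample(2:19, sum(low_gq), replace = TRUE)
    missing <- matrix(runif(N * k_tot) < 0.002, nrow = N)
    filter_col <- rep("PASS", k_tot)

    gt_code <- c("0/0", "0/1", "1/1")
    vcf_path <- file.path(dir, "genotypes.vcf")
    con <- file(vcf_path, "w")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=lrtq synthetic fixture generator",
      "##contig=<ID=chr1>",
      "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"synthetic VQSR fail\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t")), con)
    # decoy sites appended after the real variants
    decoy_pos <- c(max(all_pos) + 1000L, max(all_pos) + 2000L)
    for (vi in seq_len(k_tot)) {
      gt <- gt_code[G_all[, vi] + 1L]
      gt[missing[, vi]] <- "./."
      fields <- paste0(gt, ":", gq[, vi])
      writeLines(paste(c("chr1", all_pos[vi], all_id[vi], "A", "G", "100",
                         filter_col[vi], ".", "GT:GQ", fields),
                       collapse = "\t"), con)
    }
    # high-missing decoy (>5% missing) and VQSR-fail decoy
    gt_decoy <- gt_code[rbinom(N, 2, 0.02) + 1L]
    gt_decoy[seq_len(ceiling(N * 0.08))] <- "./."
    writeLines(paste(c("chr1", decoy_pos[1], "decoy_missing", "A", "G",
                       "100", "PASS", ".", "GT:GQ",
                       paste0(gt_decoy, ":50")), collapse = "\t"), con)
    gt_decoy2 <- gt_code[rbinom(N, 2, 0.02) + 1L]
    writeLines(paste(c("chr1", decoy_pos[2], "decoy_vqsr", "A", "G", "100",
                       "VQSRTrancheSNP99.90to100.00", ".", "GT:GQ",
                       paste0(gt_decoy2, ":50")), collapse = "\t"), con)
    close(con)

    # covariates, annotations, TSS BED, truth
    cov_path <- file.path(dir, "covariates.tsv")
    readr::write_tsv(tibble::as_tibble(cov, rownames = "sample_id"),
                     cov_path)
    ann_path <- file.path(dir, "annotations.tsv")
    tssd <- abs(all_pos - tss[match(var_gene, gene_ids)])
    ann <- tibble::tibble(
      id = all_id, chrom = "chr1", pos = all_pos, maf = all_maf,
      tss_distance = tssd,
      cadd = round(pmax(0, rnorm(k_tot, 10, 8)), 3),
      linsight = round(pmin(pmax(stats::rbeta(k_tot, 1, 6), 1e-4),
                            0.9999), 4))
    # emulate incomplete annotation coverage
    ann$cadd[runif(k_tot) < 0.05] <- NA
    ann$linsight[runif(k_tot) < 0.05] <- NA
    readr::write_tsv(ann, ann_path)
    tss_path <- file.path(dir, "tss.bed")
    readr::write_tsv(
      tibble::tibble(chrom = "chr1", start0 = tss - 1L,
                     end = tss + 5000L, gene_id = gene_ids,
                     score = 0L, strand = "+"),
      tss_path, col_names = FALSE)
    truth <- if (length(truth_rows) > 0) dplyr::bind_rows(truth_rows) else
      tibble::tibble(tissue = character(), gene_id = character(),
                     causal_id = character(), maf = numeric(),
                     beta = numeric())
    truth_path <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, truth_path)

    list(paths = list(vcf = vcf_path, expression = expr_paths,
                      covariates = cov_path, annotations = ann_path,
                      tss = tss_path, truth = truth_path),
         truth = truth, spec = spec)
  })
}
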