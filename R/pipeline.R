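# eQTL-style discovery pipeline: per-gene rare-variant grouping around the
# TSS, annotation-based weighting, covariate residualization with
# rank-based inverse normal transformation, per-gene association tests,
# FDR eGene calling, and the downstream tissue-sharing / outlier /
# enrichment summaries.

#' Group variants into per-gene TSS windows
#'
#' A variant belongs to a gene when it lies within `window_bp` of the
#' transcription start site (closed interval, 1-based coordinates) or
#' inside the gene body (when `start`/`end` columns are present). A variant
#' may belong to several genes. Genes whose window holds no variant are
#' reported and skipped; variants on other chromosomes are excluded and
#' counted.
#'
#' @param variants a [variant_set()] with `positions` (and `chrom` when the
#'   gene table spans several chromosomes).
#' @param genes tibble with columns `gene_id`, `tss`, and optionally
#'   `chrom`, `start`, `end`.
#' @param window_bp window half-width around the TSS (default 20000).
#' @return A list with `windows` (named list of `variant_set`, one per gene
#'   with at least one variant) and `report` (tibble gene_id, n_variants).
#' @export
assign_variants_to_windows <- function(variants, genes, window_bp = 20000) {
  stopifnot(window_bp > 0)
  if (is.null(variants$positions)) {
    stop("variant positions are required for window assignment",
         call. = FALSE)
  }
  pos <- variants$positions
  vchrom <- variants$chrom
  has_body <- all(c("start", "end") %in% names(genes))
  windows <- list()
  counts <- integer(nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    keep <- abs(pos - g$tss) <= window_bp
    if (has_body) keep <- keep | (pos >= g$start & pos <= g$end)
    if (!is.null(vchrom) && "chrom" %in% names(genes)) {
      keep <- keep & vchrom == g$chrom
    }
    counts[gi] <- sum(keep)
    if (any(keep)) {
      windows[[g$gene_id]] <- variant_set(
        variants$dosages[, keep, drop = FALSE],
        maf = variants$maf[keep], positions = pos[keep],
        ids = variants$ids[keep],
        chrom = if (is.null(vchrom)) NULL else vchrom[keep],
        maf_threshold = variants$maf_threshold)
    }
  }
  list(windows = windows,
       report = tibble::tibble(gene_id = genes$gene_id,
                               n_variants = counts))
}

#' Residualize expression on covariates and inverse-normal transform
#'
#' Per gene: ordinary least-squares residuals on the covariates (plus
#' intercept), followed by the rank-based inverse normal transform with the
#' Blom offset, `qnorm((rank - 3/8) / (n + 1/4))`; ties get average ranks.
#' The output for each gene is an exact permutation of fixed normal
#' quantiles. Collinear covariate columns are dropped with a warning.
#'
#' @param expression numeric matrix, genes in rows, samples in columns.
#' @param covariates data frame or matrix (samples x covariates), or
#'   `NULL` for centering only.
#' @return matrix of transformed expression, same shape as `expression`.
#' @export
residualize_and_int <- function(expression, covariates = NULL) {
  expression <- as.matrix(expression)
  N <- ncol(expression)
  X <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    cv <- cv[, apply(cv, 2, function(x) var(x) > 0), drop = FALSE]
    X <- cbind(X, cv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1, ncol(X))]
    warning(sprintf("dropping %d collinear covariate column(s): %s",
                    length(drop_idx),
                    paste(colnames(X)[drop_idx], collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(expression)))
  out <- t(apply(resid, 1, inverse_normal_transform))
  dimnames(out) <- dimnames(expression)
  out
}

#' Rank-based inverse normal transform (Blom offset)
#'
#' @param x numeric vector.
#' @param offset Blom constant `c`; quantiles are
#'   `qnorm((rank - c) / (n + 1 - 2c))`. Default 3/8.
#' @return numeric vector, an exact permutation of fixed normal quantiles.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  n <- length(x)
  qnorm((rank(x, ties.method = "average") - offset) / (n + 1 - 2 * offset))
}

weight_scheme_names <- c("uniform", "maf", "tss", "cadd", "linsight",
                         "maf_tss", "maf_cadd", "maf_cadd_tss")

#' Per-variant weights for a weighting scheme
#'
#' The eight schemes: `uniform` (all 1); `maf` (inverse MAF);
#' `tss` (inverse TSS distance, `1 / (1 + d)` so `d = 0` is finite);
#' `cadd` / `linsight` (raw functional scores); and the products
#' `maf_tss`, `maf_cadd`, `maf_cadd_tss` (components multiply before
#' normalization). Weights are normalized to a maximum of 1. Variants with
#' a missing annotation get the scheme's minimum observed weight; the
#' substitution count is reported in a warning.
#'
#' @param scheme one of
#'   `r paste0('\x60', paste(weight_scheme_names, collapse = '\x60, \x60'), '\x60')`.
#' @param annotations tibble with per-variant columns among `maf`,
#'   `tss_distance`, `cadd`, `linsight` (only those the scheme needs).
#' @return numeric weight vector with `max(w) = 1`.
#' @export
build_weights <- function(scheme, annotations) {
  scheme <- match.arg(scheme, weight_scheme_names)
  k <- nrow(annotations)
  if (scheme == "uniform") return(rep(1, k))
  parts <- strsplit(scheme, "_", fixed = TRUE)[[1]]
  w <- rep(1, k)
  for (p in parts) {
    comp <- switch(p,
      maf = 1 / annotations$maf,
      tss = 1 / (1 + annotations$tss_distance),
      cadd = annotations$cadd,
      linsight = annotations$linsight,
      stop("unknown weight component: ", p, call. = FALSE))
    w <- w * comp
  }
  n_missing <- sum(!is.finite(w) | is.na(w))
  if (n_missing == k) {
    warning(sprintf("scheme '%s': every annotation missing; uniform weights",
                    scheme))
    return(rep(1, k))
  }
  if (n_missing > 0) {
    warning(sprintf(
      "scheme '%s': %d variant(s) with missing annotation assigned the minimum observed weight",
      scheme, n_missing))
    w[!is.finite(w) | is.na(w)] <- min(w[is.finite(w)], na.rm = TRUE)
  }
  w / max(w)
}

#' Per-gene rare-variant association tests
#'
#' Runs one method over a list of per-gene variant sets against the
#' matching rows of a (residualized, transformed) expression matrix, using
#' per-gene weights from a weighting scheme. LRT-q and VT use adaptive
#' permutations; per-gene seeds derive from `seed` and the gene index, so
#' the whole table is reproducible.
#'
#' @param windows named list of per-gene [variant_set()]s (from
#'   [assign_variants_to_windows()]).
#' @param phenotypes numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns; or a single numeric vector shared by all genes.
#' @param method one of `r paste0(names(method_labels), collapse = ", ")`.
#' @param weight_scheme weighting scheme name (see [build_weights()]).
#' @param annotations tibble of per-variant annotations with an `id`
#'   column matching variant ids (required for non-uniform schemes).
#' @param seed master seed.
#' @param stage1,max_perm,futility_p adaptive permutation settings for the
#'   permutation-based methods.
#' @return tibble: gene_id, n_variants, p_value, permutations_used,
#'   skipped, reason.
#' @export
run_gene_tests <- function(windows, phenotypes, method = "lrtq",
                           weight_scheme = "uniform", annotations = NULL,
                           seed = 1, stage1 = 1000, max_perm = 100000,
                           futility_p = 0.05) {
  method <- match.arg(method, names(method_labels))
  gene_ids <- names(windows)
  rows <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    gid <- gene_ids[gi]
    vs <- windows[[gid]]
    e <- if (is.matrix(phenotypes)) phenotypes[gid, ] else phenotypes
    k <- n_variants(vs)
    if (all(vs$dosages == vs$dosages[1, 1]) || var(e) == 0) {
      rows[[gi]] <- tibble::tibble(gene_id = gid, n_variants = k,
                                   p_value = NA_real_,
                                   permutations_used = NA_integer_,
                                   skipped = TRUE,
                                   reason = "degenerate window or phenotype")
      next
    }
    w <- if (weight_scheme == "uniform") rep(1, k) else {
      if (is.null(annotations)) {
        stop("annotations are required for scheme '", weight_scheme, "'",
             call. = FALSE)
      }
      ann <- annotations[match(vs$ids, annotations$id), , drop = FALSE]
      if ("maf" %in% names(ann) == FALSE || anyNA(ann$maf)) ann$maf <- vs$maf
      build_weights(weight_scheme, ann)
    }
    p <- run_rv_methods(vs, e, method, weights = w, n_perm = max_perm,
                        adaptive = method %in% c("lrtq", "vt", "wss"),
                        stage1 = stage1, futility_p = futility_p,
                        seed = derive_seed(seed, gi))
    rows[[gi]] <- tibble::tibble(gene_id = gid, n_variants = k,
                                 p_value = unname(p[method]),
                                 permutations_used = NA_integer_,
                                 skipped = FALSE, reason = NA_character_)
  }
  dplyr::bind_rows(rows)
}

#' Call eGenes by FDR control
#'
#' Benjamini-Hochberg q-values by default; the Storey variant (with the
#' `pi0` estimate at `lambda = 0.5`) is available since eQTL studies often
#' report Storey q-values. A fixed p-value threshold mode replaces FDR for
#' sensitivity analyses where the p-value distribution is heterogeneous.
#'
#' @param calls tibble with at least `gene_id` and `p_value` (rows with
#'   missing p are carried through unflagged).
#' @param fdr_level FDR level (default 0.05).
#' @param method `"BH"` (default) or `"storey"`.
#' @param fixed_threshold when non-`NULL`, significance is `p_value <
#'   fixed_threshold` and q-values are reported but not used for calling.
#' @return the input tibble plus `q_value` and `significant`.
#' @export
call_egenes <- function(calls, fdr_level = 0.05, method = c("BH", "storey"),
                        fixed_threshold = NULL) {
  method <- match.arg(method)
  p <- calls$p_value
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p[ok] > 0.5) / 0.5)
    q[ok] <- pmin(q[ok] * pi0, 1)
  }
  sig <- if (is.null(fixed_threshold)) q <= fdr_level else p < fixed_threshold
  dplyr::mutate(calls, q_value = q, significant = !is.na(sig) & sig)
}

#' Fraction of eGenes shared between two tissues
#'
#' `|A intersect B| / min(|A|, |B|)`; undefined (NA, with a warning) when
#' either set is empty.
#'
#' @param egenes_a,egenes_b character vectors of eGene ids.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' tissue_sharing_fraction(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5"))
tissue_sharing_fraction <- function(egenes_a, egenes_b) {
  a <- unique(egenes_a)
  b <- unique(egenes_b)
  if (length(a) == 0 || length(b) == 0) {
    warning("tissue-sharing fraction undefined for an empty eGene set")
    return(NA_real_)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise tissue-sharing matrix
#'
#' @param membership tibble with columns `gene_id`, `tissue` (one row per
#'   eGene-tissue pair).
#' @return tibble (tissue_a, tissue_b, fraction) over unordered pairs.
#' @export
tissue_sharing_matrix <- function(membership) {
  tissues <- sort(unique(membership$tissue))
  sets <- split(membership$gene_id, membership$tissue)
  tidyr::expand_grid(tissue_a = tissues, tissue_b = tissues) |>
    dplyr::filter(.data$tissue_a < .data$tissue_b) |>
    dplyr::rowwise() |>
    dplyr::mutate(fraction = suppressWarnings(
      tissue_sharing_fraction(sets[[.data$tissue_a]],
                              sets[[.data$tissue_b]]))) |>
    dplyr::ungroup()
}

#' Tissue-specificity bins of eGenes
#'
#' Proportion of distinct eGenes detected in exactly one tissue, in 2-4
#' tissues, and in more than 4 tissues.
#'
#' @inheritParams tissue_sharing_matrix
#' @return tibble (bin, n_genes, proportion); proportions sum to 1.
#' @export
tissue_specificity_bins <- function(membership) {
  counts <- dplyr::distinct(membership, .data$gene_id, .data$tissue) |>
    dplyr::count(.data$gene_id)
  bins <- cut(counts$n, breaks = c(0, 1, 4, Inf),
              labels = c("1 tissue", "2-4 tissues", ">4 tissues"))
  tibble::tibble(bin = levels(bins)) |>
    dplyr::mutate(n_genes = as.integer(table(bins)[.data$bin]),
                  proportion = .data$n_genes / nrow(counts))
}

#' Top-N eGenes per tissue by q-value
#'
#' Matched-count selection used to compare common-variant eGene sharing
#' against rare-variant eGene sharing: from each tissue's full ranking,
#' keep the `n_per_tissue[t]` genes with the smallest q-values.
#'
#' @param calls tibble with `gene_id`, `tissue`, `q_value`.
#' @param n_per_tissue named integer vector, tissue -> count.
#' @return membership tibble (`gene_id`, `tissue`).
#' @export
top_egenes_by_q <- function(calls, n_per_tissue) {
  out <- lapply(names(n_per_tissue), function(t) {
    sub <- dplyr::arrange(dplyr::filter(calls, .data$tissue == t),
                          .data$q_value)
    utils::head(sub, n_per_tissue[[t]])[, c("gene_id", "tissue")]
  })
  dplyr::bind_rows(out)
}

#' Expression outlier Z-scores
#'
#' Pipeline: `log2(TPM + 1)` transform, per-gene Z-standardization,
#' OLS residualization on covariates, re-standardization, and flagging of
#' samples with `|Z|` above the threshold. Genes with zero expression
#' variance are excluded with a warning. Z-standardization prior to
#' residualization avoids the outlier shrinkage a rank-based quantile
#' normalization would cause.
#'
#' @param tpm numeric matrix of TPM expression, genes x samples.
#' @param covariates data frame / matrix (samples x covariates) or `NULL`.
#' @param z_threshold outlier cutoff on `|Z|` (default 2; thresholds from
#'   1 to 10 are conventional for sensitivity analyses).
#' @param log_transform apply `log2(TPM + 1)` first (default `TRUE`; set
#'   `FALSE` when the matrix is already log-scale).
#' @return A list of class `outlier_table`: `Z` (matrix), `outliers`
#'   (logical matrix), `excluded_genes`, `z_threshold`.
#' @export
expression_outlier_zscores <- function(tpm, covariates = NULL,
                                       z_threshold = 2,
                                       log_transform = TRUE) {
  x <- as.matrix(tpm)
  if (log_transform) x <- log2(x + 1)
  v <- apply(x, 1, var)
  excluded <- rownames(x)[v == 0]
  if (length(excluded) > 0) {
    warning(sprintf("excluding %d gene(s) with zero expression variance",
                    length(excluded)))
    x <- x[v > 0, , drop = FALSE]
  }
  z1 <- t(scale(t(x)))
  N <- ncol(x)
  X <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    cv <- cv[, apply(cv, 2, function(col) var(col) > 0), drop = FALSE]
    X <- cbind(X, cv)
  }
  resid <- t(qr.resid(qr(X), t(z1)))
  Z <- t(scale(t(resid)))
  dimnames(Z) <- dimnames(x)
  structure(list(Z = Z, outliers = abs(Z) > z_threshold,
                 excluded_genes = excluded, z_threshold = z_threshold),
            class = "outlier_table")
}

#' @export
print.outlier_table <- function(x, ...) {
  cat(sprintf("<outlier_table> %d genes x %d samples, |Z| > %g\n",
              nrow(x$Z), ncol(x$Z), x$z_threshold))
  cat(sprintf("  outlier fraction: %.4f\n", mean(x$outliers)))
  invisible(x)
}

#' Enrichment of rare-variant carriers among expression outliers
#'
#' Relative risk: the proportion of outliers carrying a proximal rare
#' variant divided by the same proportion among non-outliers, with the
#' Wald 95% CI from the asymptotic distribution of the log relative risk
#' (`SE = sqrt(1/a - 1/n1 + 1/c - 1/n0)`).
#'
#' @param outlier_flags logical vector (one entry per gene-sample
#'   observation).
#' @param carrier_flags logical vector, same length: carries at least one
#'   proximal rare variant.
#' @return A one-row tibble: estimate, ci_low, ci_high, p_value, and the
#'   2x2 counts; `NA` estimate with a `reason` when undefined.
#' @export
#' @examples
#' outlier_rv_enrichment(rep(c(TRUE, FALSE), c(10, 100)),
#'                       rep(c(TRUE, FALSE, TRUE, FALSE),
#'                           c(8, 2, 40, 60)))
outlier_rv_enrichment <- function(outlier_flags, carrier_flags) {
  stopifnot(length(outlier_flags) == length(carrier_flags))
  n1 <- sum(outlier_flags)
  n0 <- sum(!outlier_flags)
  a <- sum(outlier_flags & carrier_flags)
  c_ <- sum(!outlier_flags & carrier_flags)
  if (n1 == 0 || n0 == 0) {
    return(tibble::tibble(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          n_outlier = n1, n_nonoutlier = n0,
                          carrier_outlier = a, carrier_nonoutlier = c_,
                          reason = "a group is empty"))
  }
  if (c_ == 0 || a == 0) {
    return(tibble::tibble(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          n_outlier = n1, n_nonoutlier = n0,
                          carrier_outlier = a, carrier_nonoutlier = c_,
                          reason = "zero carriers in a group"))
  }
  rr <- (a / n1) / (c_ / n0)
  se <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n0)
  z <- log(rr) / se
  tibble::tibble(
    estimate = rr,
    ci_low = exp(log(rr) - 1.96 * se),
    ci_high = exp(log(rr) + 1.96 * se),
    p_value = 2 * pnorm(-abs(z)),
    n_outlier = n1, n_nonoutlier = n0,
    carrier_outlier = a, carrier_nonoutlier = c_,
    reason = NA_character_
  )
}

#' Enrichment of eGenes in a disease-gene database
#'
#' 2x2 contingency table (eGene vs non-eGene, in-database vs not) over a
#' gene universe, with the conditional-MLE odds ratio, exact two-sided
#' p-value and 95% CI from Fisher's exact test.
#'
#' @param egene_set character vector of eGene ids.
#' @param db_gene_set character vector of database gene ids.
#' @param universe character vector of all tested genes; both sets must be
#'   subsets of it.
#' @return A one-row tibble: estimate (odds ratio), ci_low, ci_high,
#'   p_value and the table counts.
#' @export
disease_enrichment <- function(egene_set, db_gene_set, universe) {
  universe <- unique(universe)
  egene_set <- unique(egene_set)
  db_gene_set <- unique(db_gene_set)
  bad <- setdiff(c(egene_set, db_gene_set), universe)
  if (length(bad) > 0) {
    stop("genes outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5),
         call. = FALSE)
  }
  is_e <- universe %in% egene_set
  is_d <- universe %in% db_gene_set
  tab <- table(factor(is_e, c(TRUE, FALSE)), factor(is_d, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  tibble::tibble(
    estimate = unname(ft$estimate),
    ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
    p_value = ft$p.value,
    egene_in_db = tab[1, 1], egene_not_db = tab[1, 2],
    nonegene_in_db = tab[2, 1], nonegene_not_db = tab[2, 2]
  )
}

#' Regress out the top common eQTL from expression
#'
#' Among common variants (the caller supplies their dosages) within
#' `window_bp` of the TSS, picks the variant with the smallest marginal
#' regression p-value (ties break to the lowest genomic position) and
#' returns the expression residuals on its dosage. With no common variant
#' in the window, the expression comes back unchanged and flagged.
#'
#' @param expression numeric vector for one gene.
#' @param common_dosages numeric matrix (samples x variants) of common
#'   variant dosages.
#' @param positions variant positions (1-based), one per column.
#' @param tss the gene's TSS coordinate.
#' @param window_bp window half-width; conventional values 20000, 50000,
#'   100000.
#' @return A list: `phenotype` (residuals or unchanged), `eqtl_index`,
#'   `eqtl_position`, `eqtl_p`, `adjusted` (logical).
#' @export
regress_out_top_eqtl <- function(expression, common_dosages, positions, tss,
                                 window_bp = 20000) {
  stopifnot(ncol(common_dosages) == length(positions))
  in_win <- which(abs(positions - tss) <= window_bp)
  in_win <- in_win[apply(common_dosages[, in_win, drop = FALSE], 2, var) > 0]
  if (length(in_win) == 0) {
    return(list(phenotype = expression, eqtl_index = NA_integer_,
                eqtl_position = NA_integer_, eqtl_p = NA_real_,
                adjusted = FALSE))
  }
  N <- length(expression)
  pvals <- vapply(in_win, function(j) {
    g <- common_dosages[, j]
    r <- cor(g, expression)
    tval <- r * sqrt((N - 2) / max(1 - r^2, 1e-300))
    2 * pt(-abs(tval), df = N - 2)
  }, 0)
  best <- in_win[order(pvals, positions[in_win])][1]
  fit <- lm.fit(cbind(1, common_dosages[, best]), expression)
  list(phenotype = fit$residuals, eqtl_index = best,
       eqtl_position = positions[best],
       eqtl_p = pvals[which(in_win == best)], adjusted = TRUE)
}

#' End-to-end rare-variant eGene mapping for one tissue
#'
#' Chains the pipeline stages: TSS-window grouping, covariate
#' residualization + inverse normal transform, per-gene association tests
#' with the chosen method and weighting scheme, and FDR eGene calling.
#'
#' @param variants a [variant_set()] for the chromosome/region.
#' @param genes gene table (`gene_id`, `tss`, optional `chrom`, `start`,
#'   `end`).
#' @param expression raw expression matrix (genes x samples; rownames are
#'   gene ids; normalized internally).
#' @param covariates data frame (samples x covariates) or `NULL`.
#' @param annotations per-variant annotation tibble (`id`, `maf`,
#'   `tss_distance`, `cadd`, `linsight`) for non-uniform schemes.
#' @param method association method (default `"lrtq"`).
#' @param weight_scheme weighting scheme (default `"uniform"`).
#' @param window_bp TSS window half-width.
#' @param fdr_level FDR level for eGene calling.
#' @param fdr_method `"BH"` or `"storey"`.
#' @param seed master seed for the per-gene permutation streams.
#' @param stage1,max_perm,futility_p adaptive permutation settings.
#' @return An eGene call tibble: gene_id, n_variants, p_value, q_value,
#'   significant, method, weight_scheme (plus skip bookkeeping).
#' @export
eqtl_map <- function(variants, genes, expression, covariates = NULL,
                     annotations = NULL, method = "lrtq",
                     weight_scheme = "uniform", window_bp = 20000,
                     fdr_level = 0.05, fdr_method = "BH", seed = 1,
                     stage1 = 1000, max_perm = 100000, futility_p = 0.05) {
  aw <- assign_variants_to_windows(variants, genes, window_bp)
  expr <- expression[intersect(rownames(expression), names(aw$windows)), ,
                     drop = FALSE]
  windows <- aw$windows[rownames(expr)]
  phen <- residualize_and_int(expr, covariates)
  calls <- run_gene_tests(windows, phen, method = method,
                          weight_scheme = weight_scheme,
                          annotations = annotations, seed = seed,
                          stage1 = stage1, max_perm = max_perm,
                          futility_p = futility_p)
  calls <- call_egenes(calls, fdr_level = fdr_level, method = fdr_method)
  dplyr::mutate(calls, method = method_labels[[method]],
                weight_scheme = weight_scheme)
}
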