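# Standard rare-variant association tests, re-implemented from their
# published definitions behind the same (variants, phenotype, ...) ->
# rv_test interface as LRT-q, so the simulation harness and the eQTL
# pipeline can swap methods freely. Adaptations forced by the
# quantitative-trait setting are noted per method.

#' Weighted burden test
#'
#' Collapses the variant set into one score per sample, `sum_i w_i g_i`,
#' and tests the phenotype against the score by linear regression
#' (two-sided t-test on the slope). Deterministic.
#'
#' @inheritParams lrtq_statistic
#' @param weights nonnegative per-variant weights; default uniform.
#' @return An `rv_test`.
#' @export
burden_test <- function(variants, phenotype, weights = NULL) {
  check_phenotype(variants, phenotype)
  k <- n_variants(variants)
  if (is.null(weights)) weights <- rep(1, k)
  if (any(weights < 0) || length(weights) != k) {
    stop("weights must be nonnegative, one per variant", call. = FALSE)
  }
  score <- as.numeric(variants$dosages %*% weights)
  N <- length(phenotype)
  if (var(score) == 0 || var(phenotype) == 0) {
    warning("burden score (or phenotype) has zero variance; p = 1")
    return(new_rv_test(0, 1, "Burden"))
  }
  r <- cor(score, phenotype)
  tval <- r * sqrt((N - 2) / max(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tval), df = N - 2)
  new_rv_test(statistic = tval, p_value = p, method = "Burden")
}

#' CMC collapsing test (quantitative adaptation)
#'
#' The combined multivariate and collapsing idea reduced to its collapsing
#' core for a quantitative trait: samples are collapsed to a carrier
#' indicator (any minor allele across the variant set) and carriers are
#' compared to non-carriers with a pooled-variance two-sample t-test.
#'
#' @inheritParams lrtq_statistic
#' @return An `rv_test`.
#' @export
cmc_test <- function(variants, phenotype) {
  check_phenotype(variants, phenotype)
  carrier <- rowSums(variants$dosages) > 0
  if (all(carrier) || !any(carrier) || var(phenotype) == 0) {
    warning("CMC: collapsed genotype (or phenotype) is constant; p = 1")
    return(new_rv_test(0, 1, "CMC"))
  }
  ht <- t.test(phenotype[carrier], phenotype[!carrier], var.equal = TRUE)
  new_rv_test(statistic = unname(ht$statistic), p_value = ht$p.value,
              method = "CMC")
}

#' Weighted-sum (WSS) permutation test
#'
#' Madsen-Browning-style frequency weighting for a quantitative trait:
#' per-variant weights `w_i = 1 / sqrt(N q_i (1 - q_i))` from the allele
#' frequency `q_i`, a genetic score `sum_i w_i g_i` per sample, and a
#' rank-based statistic `|sum_j score_j (rank(e_j) - mean rank)|` whose
#' null distribution comes from phenotype permutations.
#'
#' @inheritParams permutation_pvalue
#' @return An `rv_test` with a permutation p-value
#'   `(1 + exceedances) / (1 + n_perm)`.
#' @export
wss_test <- function(variants, phenotype, n_perm = 1000, seed = NULL) {
  perm_engine(variants, phenotype, methods = "wss",
              stage1 = n_perm, max_perm = n_perm, seed = seed)$wss
}

#' Variable threshold (VT) permutation test
#'
#' For every distinct MAF value `t` in the set (ties collapse into one
#' threshold), computes the burden score over variants with `maf <= t` and
#' its correlation with the phenotype; the statistic is the maximum
#' absolute correlation over thresholds (two-sided, since rare-variant
#' effects may go in either direction). Significance by phenotype
#' permutation.
#'
#' @inheritParams permutation_pvalue
#' @param weights optional nonnegative per-variant weights applied inside
#'   the burden scores; default uniform.
#' @param stage1,max_perm,futility_p,adaptive adaptive two-stage scheme as
#'   in [adaptive_permutation_pvalue()]; with `adaptive = FALSE` a fixed
#'   `n_perm`-permutation test is run.
#' @return An `rv_test`.
#' @export
vt_test <- function(variants, phenotype, n_perm = 1000, seed = NULL,
                    weights = NULL, adaptive = FALSE, stage1 = 1000,
                    max_perm = 100000, futility_p = 0.05) {
  if (adaptive) {
    perm_engine(variants, phenotype, methods = "vt", weights = weights,
                stage1 = stage1, max_perm = max_perm,
                futility_p = futility_p, seed = seed)$vt
  } else {
    perm_engine(variants, phenotype, methods = "vt", weights = weights,
                stage1 = n_perm, max_perm = n_perm, seed = seed)$vt
  }
}

# Cauchy combination of p-values (the ACAT transform): robust to
# dependence among the components. p-values are clipped to
# [1e-15, 1 - 1e-15] to keep the tangent finite.
acat_combine <- function(p, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(p))
  keep <- !is.na(p)
  p <- p[keep]
  weights <- weights[keep]
  if (length(p) == 0 || sum(weights) <= 0) return(NA_real_)
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clipped for the Cauchy combination")
  }
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  tstat <- sum(weights * tan((0.5 - p) * pi)) / sum(weights)
  0.5 - atan(tstat) / pi
}

# Per-variant marginal regression p-values (two-sided t-test on the slope);
# NA for variants with constant dosage.
single_variant_pvalues <- function(variants, phenotype) {
  N <- length(phenotype)
  ec <- phenotype - mean(phenotype)
  sse <- sum(ec^2)
  vapply(seq_len(n_variants(variants)), function(i) {
    g <- variants$dosages[, i]
    vg <- sum((g - mean(g))^2)
    if (vg == 0 || sse == 0) return(NA_real_)
    r <- sum((g - mean(g)) * ec) / sqrt(vg * sse)
    tval <- r * sqrt((N - 2) / max(1 - r^2, 1e-300))
    2 * pt(-abs(tval), df = N - 2)
  }, 0)
}

#' ACAT-V: Cauchy combination of single-variant p-values
#'
#' Combines per-variant marginal-regression p-values with the Cauchy
#' transform `T = sum_j w_j tan((0.5 - p_j) pi) / sum_j w_j`,
#' `p = 0.5 - atan(T) / pi`. Variants with constant dosage have no defined
#' single-variant p-value and are dropped from the combination.
#'
#' @inheritParams burden_test
#' @return An `rv_test` (deterministic).
#' @export
acat_v <- function(variants, phenotype, weights = NULL) {
  check_phenotype(variants, phenotype)
  k <- n_variants(variants)
  if (is.null(weights)) weights <- rep(1, k)
  pj <- single_variant_pvalues(variants, phenotype)
  if (all(is.na(pj))) {
    warning("ACAT-V: no variant has a defined single-variant p-value; p = 1")
    return(new_rv_test(0, 1, "ACAT-V"))
  }
  p <- acat_combine(pj, weights)
  new_rv_test(statistic = tan((0.5 - p) * pi), p_value = p,
              method = "ACAT-V", details = list(component_p = pj))
}

#' ACAT-O: omnibus Cauchy combination of component tests
#'
#' Equal-weight Cauchy combination of the supplied component p-values; the
#' conventional component set is VT, ACAT-V and SKAT-O.
#'
#' @param component_pvalues named numeric vector of at least two component
#'   p-values.
#' @return An `rv_test`.
#' @export
#' @examples
#' acat_o(c(VT = 0.5, `ACAT-V` = 0.5, `SKAT-O` = 0.5))$p_value  # 0.5
acat_o <- function(component_pvalues) {
  pv <- component_pvalues[!is.na(component_pvalues)]
  if (length(pv) < 2) {
    stop("ACAT-O needs at least two component p-values", call. = FALSE)
  }
  p <- acat_combine(pv)
  new_rv_test(statistic = tan((0.5 - p) * pi), p_value = p,
              method = "ACAT-O", details = list(components = pv))
}
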