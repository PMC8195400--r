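# Simulation study: synthetic rare-variant genotypes from a neutral-like
# site frequency spectrum (LD-free, matching the core model's independence
# assumption), null and alternative phenotype models, and harnesses that
# estimate type-I error and power for any plugged-in test.

#' Genotype-region simulation settings
#'
#' Defaults describe a 5-kb region carrying 33.1 rare variants on average
#' among 1,000 individuals (the standard operating point of the study); a
#' 3-kb region with 19.8 rare variants on average is the conventional
#' smaller setting.
#'
#' @param region_length region size in bp (cosmetic; governs positions).
#' @param target_mean_rare_variants Poisson mean of the rare-variant count.
#' @param maf_threshold rarity cutoff (population MAF strictly below it).
#' @param n_individuals diploid sample size.
#' @param pool_haplotypes size of the notional haplotype pool; sets the
#'   lower MAF bound `1 / pool_haplotypes`.
#' @return A list of class `region_config`.
#' @export
region_config <- function(region_length = 5000,
                          target_mean_rare_variants = 33.1,
                          maf_threshold = 0.05,
                          n_individuals = 1000,
                          pool_haplotypes = 50000) {
  stopifnot(target_mean_rare_variants > 0,
            maf_threshold > 0, maf_threshold < 0.5,
            n_individuals >= 2, pool_haplotypes > 2 / maf_threshold)
  structure(list(region_length = region_length,
                 target_mean_rare_variants = target_mean_rare_variants,
                 maf_threshold = maf_threshold,
                 n_individuals = n_individuals,
                 pool_haplotypes = pool_haplotypes),
            class = "region_config")
}

# Draw population MAFs from a neutral-like spectrum with density
# proportional to 1/x, truncated to [1/pool_haplotypes, maf_threshold).
# Inverse-CDF: x = a * (b/a)^u with u ~ Uniform(0,1).
draw_sfs_maf <- function(k, lower, upper) {
  u <- runif(k)
  pmin(lower * (upper / lower)^u, upper * (1 - 1e-12))
}

#' Simulate rare-variant genotypes for one region
#'
#' The variant count is Poisson with the configured mean (redrawn if zero,
#' so a region never comes back empty); population MAFs follow a
#' neutral-like spectrum (density proportional to 1/x, truncated to
#' `[1/pool_haplotypes, maf_threshold)`); per-individual dosages are
#' independent Binomial(2, maf) draws across variants -- deliberately
#' LD-free, consistent with the independence assumption of the core test.
#'
#' @param config a [region_config()].
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return A [variant_set()].
#' @export
simulate_region <- function(config = region_config(), seed = NULL) {
  with_seed(seed, {
    k <- 0L
    while (k == 0L) k <- rpois(1, config$target_mean_rare_variants)
    maf <- draw_sfs_maf(k, 1 / config$pool_haplotypes, config$maf_threshold)
    N <- config$n_individuals
    G <- matrix(rbinom(N * k, 2, rep(maf, each = N)), nrow = N, ncol = k)
    variant_set(G, maf = maf,
                positions = sort(sample.int(config$region_length, k,
                                            replace = TRUE)),
                maf_threshold = config$maf_threshold)
  })
}

#' Simulate a null phenotype
#'
#' `E_j = A_j + eps_j` with independent `A_j ~ N(0,1)` (a stand-in for
#' covariate effects) and `eps_j ~ N(0,1)` noise; no genotype term, so the
#' phenotype is independent of any variant set by construction. Marginal
#' variance 2.
#'
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_null_phenotype <- function(n, seed = NULL) {
  with_seed(seed, rnorm(n) + rnorm(n))
}

#' Phenotype simulation settings for the alternative model
#'
#' @param a effect-size constant; causal effect sizes are
#'   `|beta_i| = a * |log10(maf_i)|` (so at MAF `1/2000`,
#'   `a = 1.5` gives `|beta| = 4.95`).
#' @param causal_ratio fraction of rare variants that are causal;
#'   `s = round(causal_ratio * k)` with a floor of one causal variant.
#' @param negative_sign_prob probability a causal effect is negative
#'   (default 0.5: mixed effect directions).
#' @param random_effect_mode draw `a` afresh per causal variant from
#'   `N(1, 1)` to add noise to effect sizes.
#' @param unequal_variance_mode carriers of causal variants receive a
#'   covariate term with variance 2 instead of 1 (robustness setting that
#'   violates the pooled-variance assumption).
#' @param noise_sd standard deviation of the error term.
#' @return A list of class `phenotype_sim_config`.
#' @export
phenotype_sim_config <- function(a = 0.9, causal_ratio = 0.1,
                                 negative_sign_prob = 0.5,
                                 random_effect_mode = FALSE,
                                 unequal_variance_mode = FALSE,
                                 noise_sd = 1) {
  stopifnot(causal_ratio > 0, causal_ratio <= 1,
            negative_sign_prob >= 0, negative_sign_prob <= 1)
  structure(list(a = a, causal_ratio = causal_ratio,
                 negative_sign_prob = negative_sign_prob,
                 random_effect_mode = random_effect_mode,
                 unequal_variance_mode = unequal_variance_mode,
                 noise_sd = noise_sd),
            class = "phenotype_sim_config")
}

#' Simulate a phenotype under the alternative model
#'
#' `E_j = A_j + beta' G_j + eps_j`: `s = round(causal_ratio * k)` variants
#' (at least one) are drawn uniformly as causal; effect magnitudes are
#' `a * |log10(maf_i)|` with signs negative with probability
#' `negative_sign_prob`. With `unequal_variance_mode`, individuals carrying
#' at least one causal variant get a covariate term of variance 2 instead
#' of 1. `a = 0` reduces exactly to the null model.
#'
#' @param variants a [variant_set()].
#' @param config a [phenotype_sim_config()].
#' @param seed optional integer seed.
#' @return A list with `phenotype` (numeric) and `causal`, a tibble of the
#'   planted causal variants (`index`, `id`, `maf`, `beta`).
#' @export
simulate_alt_phenotype <- function(variants, config = phenotype_sim_config(),
                                   seed = NULL) {
  k <- n_variants(variants)
  N <- n_samples(variants)
  with_seed(seed, {
    s <- max(1L, as.integer(round(config$causal_ratio * k)))
    causal_idx <- sort(sample.int(k, s))
    a_i <- if (config$random_effect_mode) rnorm(s, 1, 1) else rep(config$a, s)
    sign_i <- ifelse(runif(s) < config$negative_sign_prob, -1, 1)
    beta <- sign_i * abs(a_i) * abs(log10(variants$maf[causal_idx]))
    genetic <- as.numeric(
      variants$dosages[, causal_idx, drop = FALSE] %*% beta)
    if (config$unequal_variance_mode) {
      carrier <- rowSums(
        variants$dosages[, causal_idx, drop = FALSE]) > 0
      covar <- ifelse(carrier, rnorm(N, 0, sqrt(2)), rnorm(N, 0, 1))
    } else {
      covar <- rnorm(N)
    }
    phenotype <- covar + genetic + rnorm(N, 0, config$noise_sd)
    list(phenotype = phenotype,
         causal = tibble::tibble(index = causal_idx,
                                 id = variants$ids[causal_idx],
                                 maf = variants$maf[causal_idx],
                                 beta = beta))
  })
}

method_labels <- c(lrtq = "LRT-q", cmc = "CMC", wss = "WSS",
                   burden = "Burden", vt = "VT", acatv = "ACAT-V",
                   acato = "ACAT-O", skat = "SKAT", skato = "SKAT-O")

#' Run a panel of rare-variant tests on one dataset
#'
#' Uniform interface used by the simulation harnesses: runs each requested
#' method on the same variant set and phenotype and returns the p-values.
#' Permutation-based methods (LRT-q, VT, WSS) share one permutation stream;
#' ACAT-O is the Cauchy combination of the VT, ACAT-V and SKAT-O p-values
#' (computed on demand when not requested themselves).
#'
#' @param variants a [variant_set()].
#' @param phenotype numeric phenotype vector.
#' @param methods subset of `c("lrtq", "cmc", "wss", "burden", "vt",
#'   "acatv", "acato", "skat", "skato")`.
#' @param weights per-variant weights used by the weight-aware methods;
#'   default uniform (LRT-q then uses the constant prior 0.5).
#' @param n_perm maximum permutations for the permutation-based methods.
#' @param adaptive use two-stage early stopping for LRT-q/VT/WSS.
#' @param stage1,futility_p adaptive screening parameters.
#' @param seed optional integer seed.
#' @return named numeric vector of p-values.
#' @export
run_rv_methods <- function(variants, phenotype,
                           methods = names(method_labels),
                           weights = NULL, n_perm = 1000,
                           adaptive = FALSE, stage1 = 1000,
                           futility_p = 0.05, seed = NULL) {
  methods <- match.arg(methods, names(method_labels), several.ok = TRUE)
  k <- n_variants(variants)
  if (is.null(weights)) weights <- rep(1, k)
  need <- methods
  if ("acato" %in% methods) need <- union(need, c("vt", "acatv", "skato"))
  with_seed(seed, {
    p <- numeric(0)
    perm_methods <- intersect(c("lrtq", "vt", "wss"), need)
    if (length(perm_methods) > 0) {
      prior <- if ("lrtq" %in% perm_methods) {
        weights_to_priors(weights, uniform_constant = 0.5)
      } else NULL
      st1 <- if (adaptive) min(stage1, n_perm) else n_perm
      res <- perm_engine(variants, phenotype, methods = perm_methods,
                         prior = prior, weights = weights,
                         stage1 = st1, max_perm = n_perm,
                         futility_p = futility_p)
      p <- vapply(res, function(r) r$p_value, 0)
    }
    if ("cmc" %in% need) p[["cmc"]] <- cmc_test(variants, phenotype)$p_value
    if ("burden" %in% need) {
      p[["burden"]] <- burden_test(variants, phenotype, weights)$p_value
    }
    if ("acatv" %in% need) {
      p[["acatv"]] <- acat_v(variants, phenotype, weights)$p_value
    }
    if ("skat" %in% need) {
      p[["skat"]] <- skat_test(variants, phenotype, weights)$p_value
    }
    if ("skato" %in% need) {
      p[["skato"]] <- skat_o(variants, phenotype, weights)$p_value
    }
    if ("acato" %in% methods) {
      # permutation p-values can be exactly 1 under the null; the clip
      # warning is routine here, not a data problem
      p[["acato"]] <- suppressWarnings(
        acat_o(c(VT = p[["vt"]], `ACAT-V` = p[["acatv"]],
                 `SKAT-O` = p[["skato"]]))$p_value)
    }
    p[methods]
  })
}

new_sim_table <- function(rates, pvalues, settings) {
  structure(list(rates = rates, pvalues = pvalues, settings = settings),
            class = "sim_table")
}

#' @export
print.sim_table <- function(x, ...) {
  cat(sprintf("<sim_table> %s, %d replicates\n",
              x$settings$kind, x$settings$n_reps))
  print(x$rates, n = 40)
  invisible(x)
}

#' @rdname estimate_type1_error
#' @param x a `sim_table`.
#' @param ... unused.
#' @export
tidy.sim_table <- function(x, ...) x$rates

binom_ci <- function(x, n) {
  ci <- stats::binom.test(x, n)$conf.int
  tibble::tibble(ci_lo = ci[1], ci_hi = ci[2])
}

#' Estimate type-I error rates by null simulation
#'
#' Replicates the null study design: per replicate, a fresh rare-variant
#' region and an independent phenotype `E = A + eps`; every requested
#' method is run with uniform weights, and the rejection fraction at each
#' significance level is reported with an exact binomial 95% CI. Rows where
#' fewer than ~10 rejections are expected (`n_reps * alpha < 10`) are
#' flagged `unstable`.
#'
#' @param methods methods to run (see [run_rv_methods()]).
#' @param n_reps number of null replicates.
#' @param alphas significance levels.
#' @param region a [region_config()].
#' @param n_perm maximum permutations for permutation-based methods.
#' @param adaptive,stage1,futility_p early-stopping settings for the
#'   permutation-based methods.
#' @param seed master seed; per-replicate seeds are derived by a
#'   counter-based scheme.
#' @return A `sim_table`: `$rates` is a tibble (method, alpha, rejections,
#'   n_reps, estimate, ci_lo, ci_hi, unstable); `$pvalues` holds the
#'   per-replicate p-values in long form.
#' @export
estimate_type1_error <- function(methods = c("lrtq", "cmc", "wss", "burden",
                                             "vt", "acatv", "acato", "skato"),
                                 n_reps = 10000,
                                 alphas = c(0.05, 0.01),
                                 region = region_config(),
                                 n_perm = 10000, adaptive = TRUE,
                                 stage1 = 1000, futility_p = 0.05,
                                 seed = 1) {
  methods <- match.arg(methods, names(method_labels), several.ok = TRUE)
  pmat <- matrix(NA_real_, n_reps, length(methods),
                 dimnames = list(NULL, methods))
  for (rep_i in seq_len(n_reps)) {
    rs <- derive_seed(seed, rep_i)
    pmat[rep_i, ] <- with_seed(rs, {
      vs <- simulate_region(region)
      e <- simulate_null_phenotype(region$n_individuals)
      run_rv_methods(vs, e, methods, n_perm = n_perm, adaptive = adaptive,
                     stage1 = stage1, futility_p = futility_p)
    })
  }
  rates <- tidyr::expand_grid(method = methods, alpha = alphas) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rejections = sum(pmat[, .data$method] < .data$alpha),
      n_reps = n_reps,
      estimate = .data$rejections / n_reps,
      binom_ci(.data$rejections, n_reps),
      unstable = n_reps * .data$alpha < 10
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(method = unname(method_labels[.data$method]))
  pvalues <- tibble::as_tibble(pmat) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    tidyr::pivot_longer(-"replicate", names_to = "method",
                        values_to = "p_value") |>
    dplyr::mutate(method = unname(method_labels[.data$method]))
  new_sim_table(rates, pvalues,
                list(kind = "type-I error", n_reps = n_reps, region = region,
                     n_perm = n_perm, adaptive = adaptive, seed = seed))
}

#' Estimate statistical power over an effect-size grid
#'
#' Per grid cell `(a, causal_ratio)` and replicate, draws a region and an
#' alternative phenotype with mixed-sign effects and reports each method's
#' rejection fraction at `alpha`. Replicate seeds depend only on the
#' replicate counter, so grid cells are coupled (the same genotypes and
#' noise are reused across `a` values), which makes power comparisons
#' across the grid nearly paired.
#'
#' @inheritParams estimate_type1_error
#' @param a_grid effect-size constants to scan.
#' @param causal_ratios causal-variant fractions to scan.
#' @param alpha significance level for power (default 0.05).
#' @param sim_config base [phenotype_sim_config()]; its `a` and
#'   `causal_ratio` are overridden by the grid.
#' @param n_perm permutations for the permutation-based methods (fixed
#'   count, no early stopping, as in the power study design).
#' @return A `sim_table` with `$rates` columns (method, a, causal_ratio,
#'   power, ci_lo, ci_hi, n_reps).
#' @export
estimate_power <- function(methods = c("lrtq", "cmc", "wss", "burden", "vt",
                                       "acatv", "acato", "skato"),
                           a_grid = c(0.3, 0.6, 0.9, 1.2, 1.5),
                           causal_ratios = 0.1,
                           n_reps = 2000, alpha = 0.05,
                           region = region_config(),
                           sim_config = phenotype_sim_config(),
                           n_perm = 1000, seed = 1) {
  methods <- match.arg(methods, names(method_labels), several.ok = TRUE)
  grid <- tidyr::expand_grid(a = a_grid, causal_ratio = causal_ratios)
  out <- vector("list", nrow(grid))
  pv <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cfg <- sim_config
    cfg$a <- grid$a[gi]
    cfg$causal_ratio <- grid$causal_ratio[gi]
    pmat <- matrix(NA_real_, n_reps, length(methods),
                   dimnames = list(NULL, methods))
    for (rep_i in seq_len(n_reps)) {
      rs <- derive_seed(seed, rep_i)
      pmat[rep_i, ] <- with_seed(rs, {
        vs <- simulate_region(region)
        sim <- simulate_alt_phenotype(vs, cfg)
        run_rv_methods(vs, sim$phenotype, methods, n_perm = n_perm,
                       adaptive = FALSE)
      })
    }
    out[[gi]] <- tibble::tibble(method = methods) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        a = grid$a[gi], causal_ratio = grid$causal_ratio[gi],
        rejections = sum(pmat[, .data$method] < alpha),
        n_reps = n_reps,
        power = .data$rejections / n_reps,
        binom_ci(.data$rejections, n_reps)
      ) |>
      dplyr::ungroup()
    pv[[gi]] <- tibble::as_tibble(pmat) |>
      dplyr::mutate(replicate = dplyr::row_number(),
                    a = grid$a[gi], causal_ratio = grid$causal_ratio[gi]) |>
      tidyr::pivot_longer(c(-"replicate", -"a", -"causal_ratio"),
                          names_to = "method", values_to = "p_value")
    }
  rates <- dplyr::bind_rows(out) |>
    dplyr::mutate(method = unname(method_labels[.data$method]))
  pvalues <- dplyr::bind_rows(pv) |>
    dplyr::mutate(method = unname(method_labels[.data$method]))
  new_sim_table(rates, pvalues,
                list(kind = "power", n_reps = n_reps, alpha = alpha,
                     region = region, n_perm = n_perm, seed = seed))
}

#' Plot a simulation table
#'
#' Power tables are drawn as power curves over the effect-size constant
#' (one line per method, faceted by causal ratio); type-I tables as
#' estimates with binomial CIs against the nominal level.
#'
#' @param object a `sim_table`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sim_table <- function(object, ...) {
  r <- object$rates
  if ("power" %in% names(r)) {
    ggplot2::ggplot(r, ggplot2::aes(x = .data$a, y = .data$power,
                                    colour = .data$method)) +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                            ymax = .data$ci_hi)) +
      ggplot2::facet_wrap(~causal_ratio, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "effect-size constant a", y = "power",
                    colour = "method") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(r, ggplot2::aes(x = .data$method, y = .data$estimate)) +
      ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                            ymax = .data$ci_hi)) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                          linetype = 2, colour = "grey40") +
      ggplot2::facet_wrap(~alpha, scales = "free_y",
                          labeller = ggplot2::label_both) +
      ggplot2::labs(x = NULL, y = "rejection fraction") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}
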