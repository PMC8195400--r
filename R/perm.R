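# Permutation machinery shared by the permutation-based tests (LRT-q, VT,
# WSS). The phenotype vector is permuted across samples; genotypes, priors
# and weights stay fixed, which preserves any genotype correlation and is
# the standard permutation null for eQTL testing. The statistics only need,
# per permutation, the per-variant sums of the (centered) phenotype over
# carriers and the dosage-weighted analogues; those sums come from the
# compiled loop in src/perm_core.cpp, and the statistic arithmetic stays in
# vectorized R.

perm_engine <- function(variants, phenotype, methods = "lrtq",
                        prior = NULL, weights = NULL,
                        stage1 = 1000L, max_perm = stage1,
                        futility_p = 0.05, seed = NULL,
                        include_null_scenario = TRUE,
                        block_size = 5000L) {
  check_phenotype(variants, phenotype)
  stopifnot(stage1 >= 1, max_perm >= stage1)
  methods <- match.arg(methods, c("lrtq", "vt", "wss"), several.ok = TRUE)
  k <- n_variants(variants)
  N <- length(phenotype)
  if (is.null(weights)) weights <- rep(1, k)
  ec <- phenotype - mean(phenotype)
  SS0 <- sum(ec^2)
  cs <- carrier_structure(variants$dosages)
  need_rank <- "wss" %in% methods
  rcc <- if (need_rank) rank(phenotype) - (N + 1) / 2 else NULL

  if ("lrtq" %in% methods) prior <- resolve_prior(prior, k)

  # VT threshold structure: sorted distinct MAFs; ties collapse into one
  # threshold; thresholds whose cumulative score has zero variance are
  # skipped.
  vt <- NULL
  if ("vt" %in% methods) {
    tvals <- sort(unique(variants$maf))
    A <- outer(tvals, variants$maf, function(t, m) as.numeric(m <= t)) *
      rep(weights, each = length(tvals))             # T x k
    X <- variants$dosages %*% t(A)                   # N x T cumulative scores
    Xc <- sweep(X, 2, colMeans(X))
    ssx <- colSums(Xc^2)
    vt <- list(A = A, ssx = ssx, valid = ssx > 0)
    if (!any(vt$valid)) {
      warning("VT: every threshold score is constant; p = 1")
    }
  }
  wss_w <- if ("wss" %in% methods) {
    q <- variants$maf
    1 / sqrt(N * q * (1 - q))
  } else NULL

  sum_over <- function(vals, weight_by_dosage) {
    if (weight_by_dosage) {
      vapply(seq_len(k), function(i) sum(cs$dos[[i]] * vals[cs$idx[[i]] + 1L]),
             0)
    } else {
      vapply(cs$idx, function(ii) sum(vals[ii + 1L]), 0)
    }
  }

  stat_fns <- list(
    lrtq = function(S_ind, D_dos, D_rank) {
      lambda_from_llr(llr_from_sums(S_ind, cs$n, cs$m, N, SS0), prior$c,
                      include_null_scenario)
    },
    vt = function(S_ind, D_dos, D_rank) {
      if (!any(vt$valid)) return(rep(0, ncol(D_dos)))
      cum <- vt$A %*% D_dos                          # T x B
      z <- abs(cum[vt$valid, , drop = FALSE]) /
        sqrt(vt$ssx[vt$valid] * max(SS0, 1e-300))
      apply(z, 2, max)
    },
    wss = function(S_ind, D_dos, D_rank) {
      abs(as.numeric(crossprod(wss_w, D_rank)))
    }
  )

  obs <- list(
    S_ind = matrix(sum_over(ec, FALSE), ncol = 1),
    D_dos = matrix(sum_over(ec, TRUE), ncol = 1),
    D_rank = if (need_rank) matrix(sum_over(rcc, TRUE), ncol = 1) else NULL
  )
  obs_stat <- vapply(methods, function(m) {
    stat_fns[[m]](obs$S_ind, obs$D_dos, obs$D_rank)[1]
  }, 0)
  tol <- 1e-9 * (1 + abs(obs_stat))

  counts <- setNames(numeric(length(methods)), methods)
  done <- setNames(numeric(length(methods)), methods)
  active <- methods

  with_seed(seed, {
    total <- 0L
    stage1 <- as.integer(min(stage1, max_perm))
    while (length(active) > 0L && total < max_perm) {
      B <- if (total == 0L) stage1 else
        as.integer(min(block_size, max_perm - total))
      vals <- cbind(ec,
                    if (need_rank && "wss" %in% active) rcc else NULL)
      res <- .perm_carrier_sums(cs$idx, cs$dos, vals, B)
      S_ind <- res$ind[[1]]
      D_dos <- res$dos[[1]]
      D_rank <- if (ncol(vals) > 1) res$dos[[2]] else NULL
      for (m in active) {
        st <- stat_fns[[m]](S_ind, D_dos, D_rank)
        counts[m] <- counts[m] + sum(st >= obs_stat[m] - tol[m])
        done[m] <- done[m] + B
      }
      total <- total + B
      if (total == stage1) {
        p_int <- (1 + counts[active]) / (1 + done[active])
        active <- active[p_int <= futility_p]
      }
    }
  })

  p <- (1 + counts) / (1 + done)
  out <- lapply(methods, function(m) {
    label <- c(lrtq = "LRT-q", vt = "VT", wss = "WSS")[[m]]
    res <- new_rv_test(statistic = obs_stat[[m]], p_value = p[[m]],
                       method = label,
                       permutations_used = as.integer(done[[m]]))
    if (m == "lrtq") {
      res$details <- list(prior = prior,
                          include_null_scenario = include_null_scenario)
    }
    res
  })
  names(out) <- methods
  out
}

#' Permutation p-value for the LRT-q statistic
#'
#' Permutes the phenotype vector `n_perm` times (genotypes and priors
#' fixed) and reports `p = (1 + #[Lambda_perm >= Lambda_obs]) /
#' (1 + n_perm)`, so the p-value is never zero. Reproducible for a given
#' `seed`.
#'
#' @inheritParams lrtq_statistic
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed for the permutation stream; the
#'   caller's RNG state is restored afterwards.
#' @param statistic_fn optional custom statistic
#'   `function(variants, phenotype, prior)` returning a scalar; when
#'   supplied a generic (slower) permutation loop is used.
#' @return An `rv_test` with the statistic, p-value and
#'   `permutations_used`.
#' @export
permutation_pvalue <- function(variants, phenotype, prior = NULL,
                               n_perm = 1000, seed = NULL,
                               statistic_fn = NULL,
                               include_null_scenario = TRUE) {
  stopifnot(n_perm >= 1)
  if (!is.null(statistic_fn)) {
    prior <- resolve_prior(prior, n_variants(variants))
    obs <- statistic_fn(variants, phenotype, prior)
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        statistic_fn(variants, sample(phenotype), prior)
      }, 0) >= obs - 1e-9 * (1 + abs(obs)))
    })
    return(new_rv_test(statistic = obs,
                       p_value = (1 + exceed) / (1 + n_perm),
                       method = "LRT-q (custom statistic)",
                       permutations_used = as.integer(n_perm)))
  }
  res <- perm_engine(variants, phenotype, methods = "lrtq", prior = prior,
                     stage1 = n_perm, max_perm = n_perm, seed = seed,
                     include_null_scenario = include_null_scenario)
  res$lrtq$per_variant <- lrtq_statistic(variants, phenotype,
                                         res$lrtq$details$prior,
                                         include_null_scenario)$per_variant
  res$lrtq
}

#' Adaptive (two-stage) permutation p-value
#'
#' Runs `stage1` permutations first; when the interim p-value exceeds
#' `futility_p` the test stops early and reports the stage-1 p-value
#' (`permutations_used = stage1`). Otherwise permutations continue to
#' `max_perm` for a more precise p-value. Under the assumption that most
#' genes are null, the majority of tests stop after the first stage while
#' promising signals get the full-resolution p-value.
#'
#' @inheritParams permutation_pvalue
#' @param stage1 permutations in the screening stage (default 1000).
#' @param max_perm total permutations for tests passing the screen
#'   (default 100000).
#' @param futility_p interim p-value above which the test stops early
#'   (default 0.05).
#' @return An `rv_test` with the statistic, p-value and
#'   `permutations_used` (either `stage1` or `max_perm`).
#' @export
adaptive_permutation_pvalue <- function(variants, phenotype, prior = NULL,
                                        stage1 = 1000, max_perm = 100000,
                                        futility_p = 0.05, seed = NULL,
                                        statistic_fn = NULL,
                                        include_null_scenario = TRUE) {
  stopifnot(stage1 <= max_perm)
  if (!is.null(statistic_fn)) {
    res1 <- permutation_pvalue(variants, phenotype, prior, n_perm = stage1,
                               seed = seed, statistic_fn = statistic_fn)
    if (res1$p_value > futility_p) return(res1)
    return(permutation_pvalue(variants, phenotype, prior, n_perm = max_perm,
                              seed = seed, statistic_fn = statistic_fn))
  }
  res <- perm_engine(variants, phenotype, methods = "lrtq", prior = prior,
                     stage1 = stage1, max_perm = max_perm,
                     futility_p = futility_p, seed = seed,
                     include_null_scenario = include_null_scenario)
  res$lrtq$per_variant <- lrtq_statistic(variants, phenotype,
                                         res$lrtq$details$prior,
                                         include_null_scenario)$per_variant
  res$lrtq
}

#' One-call LRT-q association test
#'
#' Convenience wrapper: derives causal priors from annotation weights (via
#' [weights_to_priors()], with uniform weights mapped to the constant prior
#' 0.5) and computes an adaptive or fixed permutation p-value.
#'
#' @inheritParams adaptive_permutation_pvalue
#' @param weights optional nonnegative annotation weights (one per
#'   variant); ignored when `prior` is given.
#' @param adaptive use the two-stage adaptive scheme (default `TRUE`); when
#'   `FALSE` a fixed `max_perm`-permutation test is run.
#' @return An `rv_test`.
#' @export
lrtq_test <- function(variants, phenotype, weights = NULL, prior = NULL,
                      adaptive = TRUE, stage1 = 1000, max_perm = 100000,
                      futility_p = 0.05, seed = NULL,
                      include_null_scenario = TRUE) {
  if (is.null(prior)) {
    prior <- if (is.null(weights)) {
      causal_prior(rep(0.5, n_variants(variants)), "uniform:constant")
    } else {
      weights_to_priors(weights, uniform_constant = 0.5)
    }
  }
  if (adaptive) {
    adaptive_permutation_pvalue(variants, phenotype, prior, stage1 = stage1,
                                max_perm = max_perm, futility_p = futility_p,
                                seed = seed,
                                include_null_scenario = include_null_scenario)
  } else {
    permutation_pvalue(variants, phenotype, prior, n_perm = max_perm,
                       seed = seed,
                       include_null_scenario = include_null_scenario)
  }
}
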