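# Core likelihood-ratio test for rare-variant effects on a quantitative
# trait. Per variant, samples are split into carriers and non-carriers of
# the minor allele; a normal two-group likelihood ratio (common profiled
# variance per model) measures the expression shift; per-variant evidence is
# aggregated across variants through a causal-prior mixture that factorizes
# over variants, and significance comes from a permutation test.

#' Split a phenotype by carrier status of one variant
#'
#' Carriers are samples with dosage > 0 (at least one minor allele,
#' dominant coding); non-carriers have dosage 0. Order is preserved within
#' each group.
#'
#' @param dosage_column integer vector of minor-allele counts in `{0,1,2}`.
#' @param phenotype numeric vector, same length.
#' @return A list of class `carrier_partition` with `noncarrier_values`,
#'   `carrier_values`.
#' @export
#' @examples
#' partition_by_carrier(c(0, 1, 0, 2), c(1, 2, 3, 4))
partition_by_carrier <- function(dosage_column, phenotype) {
  if (length(dosage_column) != length(phenotype)) {
    stop("dosage and phenotype lengths differ", call. = FALSE)
  }
  if (anyNA(dosage_column) || !all(dosage_column %in% 0:2)) {
    stop("dosages must be in {0, 1, 2}", call. = FALSE)
  }
  carrier <- dosage_column > 0
  structure(
    list(noncarrier_values = phenotype[!carrier],
         carrier_values = phenotype[carrier]),
    class = "carrier_partition"
  )
}

#' Per-variant normal log likelihood ratio
#'
#' Profile log likelihood ratio between the two-mean model (carriers and
#' non-carriers have separate means) and the common-mean model, each with a
#' single shared variance profiled out. In closed form,
#' `2 * llr = N * log(SS0 / SS1)` with `SS0` the total sum of squares about
#' the grand mean and `SS1` the pooled within-group sum of squares. The
#' ratio is zero when there are no carriers (the models coincide) and is
#' always nonnegative (the alternative nests the null).
#'
#' @param partition a `carrier_partition`.
#' @return A one-row tibble with `llr`, `mean_noncarrier`, `mean_carrier`,
#'   `pooled_sd` (maximum-likelihood scale, divisor `N`) and `n_carriers`.
#' @export
per_variant_llr <- function(partition) {
  x <- partition$noncarrier_values
  y <- partition$carrier_values
  n <- length(y)
  m <- length(x)
  N <- m + n
  all_v <- c(x, y)
  gm <- mean(all_v)
  ss0 <- sum((all_v - gm)^2)
  if (n == 0L || m == 0L) {
    if (ss0 <= 0 && N > 0) {
      # no carriers and constant phenotype: models still coincide
      return(tibble::tibble(llr = 0, mean_noncarrier = gm, mean_carrier = gm,
                            pooled_sd = 0, n_carriers = n))
    }
    return(tibble::tibble(llr = 0, mean_noncarrier = gm, mean_carrier = gm,
                          pooled_sd = sqrt(ss0 / N), n_carriers = n))
  }
  if (N < 3) stop("need at least 3 observations in total", call. = FALSE)
  if (ss0 <= 0) {
    stop("phenotype has zero total variance (degenerate input)",
         call. = FALSE)
  }
  mx <- mean(x)
  my <- mean(y)
  ss1 <- sum((x - mx)^2) + sum((y - my)^2)
  ss1 <- max(ss1, ss0 * 1e-12)
  tibble::tibble(
    llr = 0.5 * N * log(ss0 / ss1),
    mean_noncarrier = mx, mean_carrier = my,
    pooled_sd = sqrt(ss1 / N), n_carriers = n
  )
}

#' Causal priors for rare variants
#'
#' `causal_prior()` wraps a vector of per-variant causal probabilities;
#' `weights_to_priors()` derives one from nonnegative annotation weights by
#' max-normalization with a floor: `c_i = clip(w_i / max(w), floor, 1)`.
#' A uniform weight vector maps to `c_i = 1` for every variant unless
#' `uniform_constant` is supplied, in which case all priors are set to that
#' constant (0.5 is the conventional noninformative operating point).
#'
#' @param c numeric vector of causal probabilities, each in `(0, 1]`.
#' @param scheme_label provenance string for the weighting scheme.
#' @return An object of class `causal_prior`.
#' @export
causal_prior <- function(c, scheme_label = "custom") {
  c <- as.numeric(c)
  if (length(c) < 1 || any(!is.finite(c)) || any(c <= 0) || any(c > 1)) {
    stop("causal probabilities must lie in (0, 1]", call. = FALSE)
  }
  structure(list(c = c, scheme_label = scheme_label), class = "causal_prior")
}

#' @rdname causal_prior
#' @param weights nonnegative numeric vector, at least one positive entry.
#' @param floor lower clip for the priors, default 0.05.
#' @param uniform_constant optional constant prior to use when all weights
#'   are equal; `NULL` (the default) leaves uniform weights at `c_i = 1`.
#' @export
#' @examples
#' weights_to_priors(c(2, 4))$c          # 0.5, 1
#' weights_to_priors(rep(1, 3), uniform_constant = 0.5)$c
weights_to_priors <- function(weights, floor = 0.05,
                              uniform_constant = NULL,
                              scheme_label = "weights") {
  w <- as.numeric(weights)
  if (length(w) < 1) stop("need at least one weight", call. = FALSE)
  if (anyNA(w) || any(w < 0)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  if (max(w) <= 0) stop("all weights are zero", call. = FALSE)
  if (!is.null(uniform_constant) &&
      isTRUE(all.equal(w, rep(w[1], length(w))))) {
    return(causal_prior(rep(uniform_constant, length(w)),
                        scheme_label = paste0(scheme_label, ":constant")))
  }
  c <- pmin(pmax(w / max(w), floor), 1)
  causal_prior(c, scheme_label = scheme_label)
}

resolve_prior <- function(prior, k) {
  if (is.null(prior)) prior <- causal_prior(rep(0.5, k), "uniform:constant")
  if (is.numeric(prior)) prior <- causal_prior(prior)
  if (!inherits(prior, "causal_prior")) {
    stop("prior must be a causal_prior or numeric vector", call. = FALSE)
  }
  if (length(prior$c) != k) {
    stop("prior length does not match the number of variants", call. = FALSE)
  }
  prior
}

# --- vectorized internals ---------------------------------------------------

# Sparse carrier structure of a dosage matrix: 0-based carrier indices and
# carrier dosages per variant, plus group sizes.
carrier_structure <- function(dosages) {
  k <- ncol(dosages)
  idx <- vector("list", k)
  dos <- vector("list", k)
  for (i in seq_len(k)) {
    w <- which(dosages[, i] > 0L)
    idx[[i]] <- w - 1L
    dos[[i]] <- as.numeric(dosages[w, i])
  }
  list(idx = idx, dos = dos, n = lengths(idx), m = nrow(dosages) - lengths(idx))
}

# Per-variant llr from carrier sums of the *centered* phenotype.
# S: k x B matrix; n, m: carrier / non-carrier counts; SS0 total SS.
# With centered values, SS1 = SS0 - N * s^2 / (m * n).
llr_from_sums <- function(S, n, m, N, SS0) {
  if (SS0 <= 0) return(matrix(0, nrow(S), ncol(S)))
  denom <- m * n
  denom[denom == 0] <- 1  # rows zeroed below
  num <- (N * S^2) / denom
  SS1 <- pmax(SS0 - num, SS0 * 1e-12)
  ll <- 0.5 * N * log(SS0 / SS1)
  ll[n == 0L | m == 0L, ] <- 0
  ll
}

# Aggregate per-variant llr into the mixture log likelihood ratio
# Lambda = sum_i log((1 - c_i) + c_i * exp(llr_i)), computed stably as
# llr_i + log(c_i + (1 - c_i) * exp(-llr_i)). Optionally excludes the
# all-null causal configuration from the alternative (renormalized).
lambda_from_llr <- function(ll, cvec, include_null_scenario = TRUE) {
  lam <- colSums(ll + log(cvec + (1 - cvec) * exp(-ll)))
  if (!include_null_scenario) {
    logp0 <- sum(log1p(-pmin(cvec, 1 - 1e-16)))
    # log((exp(lam) - P0) / (1 - P0)), stable for lam near 0
    d <- pmin(logp0 - lam, -1e-16)
    lam <- lam + log(-expm1(d)) - log(-expm1(min(logp0, -1e-16)))
    lam <- pmax(lam, 0)
  }
  lam
}

#' The LRT-q statistic for a variant set
#'
#' Computes `Lambda = sum_i log((1 - c_i) + c_i * exp(llr_i))`: the log of
#' the ratio between the causal-scenario-marginalized likelihood (which
#' factorizes over independent variants) and the all-null likelihood.
#' Nonnegative; zero when every per-variant ratio is zero or every prior
#' vanishes. Cost O(k * N).
#'
#' @param variants a [variant_set()].
#' @param phenotype numeric phenotype vector (typically covariate-adjusted,
#'   normalized expression).
#' @param prior a [causal_prior()], a numeric vector of causal
#'   probabilities, or `NULL` for the constant prior `c_i = 0.5`.
#' @param include_null_scenario logical; when `FALSE` the all-null causal
#'   configuration is excluded from the alternative's scenario sum (the
#'   "at least one causal variant" convention) and the prior mass is
#'   renormalized. The default includes it, which only shrinks the
#'   statistic toward zero and preserves the ordering of tests.
#' @return An `rv_test` with the statistic, per-variant evidence, and no
#'   p-value (see [permutation_pvalue()]).
#' @export
#' @examples
#' set.seed(1)
#' vs <- variant_set(matrix(rbinom(500, 2, 0.02), 100), maf = rep(0.02, 5))
#' e <- rnorm(100)
#' lrtq_statistic(vs, e)$statistic
lrtq_statistic <- function(variants, phenotype, prior = NULL,
                           include_null_scenario = TRUE) {
  check_phenotype(variants, phenotype)
  k <- n_variants(variants)
  prior <- resolve_prior(prior, k)
  N <- length(phenotype)
  ec <- phenotype - mean(phenotype)
  SS0 <- sum(ec^2)
  cs <- carrier_structure(variants$dosages)
  S <- matrix(vapply(cs$idx, function(ii) sum(ec[ii + 1L]), 0), ncol = 1)
  ll <- llr_from_sums(S, cs$n, cs$m, N, SS0)
  lam <- lambda_from_llr(ll, prior$c, include_null_scenario)
  raw_sums <- vapply(cs$idx, function(ii) sum(phenotype[ii + 1L]), 0)
  gm <- mean(phenotype)
  mean_car <- ifelse(cs$n > 0, raw_sums / pmax(cs$n, 1), gm)
  mean_non <- ifelse(cs$m > 0, (sum(phenotype) - raw_sums) / pmax(cs$m, 1), gm)
  pv <- tibble::tibble(
    id = variants$ids,
    llr = ll[, 1],
    mean_noncarrier = mean_non,
    mean_carrier = mean_car,
    pooled_sd = sqrt(pmax(SS0 - (N * S[, 1]^2) / pmax(cs$m * cs$n, 1), 0) / N),
    n_carriers = cs$n
  )
  new_rv_test(statistic = lam, p_value = NA_real_, method = "LRT-q",
              per_variant = pv,
              details = list(prior = prior,
                             include_null_scenario = include_null_scenario))
}

#' Brute-force scenario enumeration of the LRT-q statistic
#'
#' Reference oracle: sums the scenario-weighted likelihood ratio explicitly
#' over all `2^k` causal configurations, `sum_q P(V_q) * prod_i
#' exp(llr_i * v_i)`, with `P(V_q) = prod_i c_i^{v_i} (1-c_i)^{1-v_i}`.
#' Exponential cost; refuses `k > 12`.
#'
#' @inheritParams lrtq_statistic
#' @return the statistic (numeric scalar).
#' @export
lrtq_bruteforce <- function(variants, phenotype, prior = NULL,
                            include_null_scenario = TRUE) {
  k <- n_variants(variants)
  if (k > 12) stop("brute-force enumeration is limited to k <= 12",
                   call. = FALSE)
  check_phenotype(variants, phenotype)
  prior <- resolve_prior(prior, k)
  ll <- if (var(phenotype) <= 0) rep(0, k) else vapply(seq_len(k), function(i) {
    per_variant_llr(
      partition_by_carrier(variants$dosages[, i], phenotype))$llr
  }, 0)
  cvec <- prior$c
  q_max <- 2^k - 1
  logterms <- vapply(0:q_max, function(q) {
    v <- as.integer(intToBits(q)[seq_len(k)])
    sum(ifelse(v == 1L, log(cvec) + ll, log1p(-cvec)))
  }, 0)
  if (!include_null_scenario) {
    logterms <- logterms[-1]  # q = 0 is the all-null configuration
    logp0 <- sum(log1p(-pmin(cvec, 1 - 1e-16)))
    off <- log(-expm1(min(logp0, -1e-16)))
  } else off <- 0
  mx <- max(logterms)
  log(sum(exp(logterms - mx))) + mx - off
}
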