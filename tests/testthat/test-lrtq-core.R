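# Core statistic: carrier partitioning, per-variant likelihood ratios,
# prior-mixture aggregation and its brute-force scenario oracle.

test_that("carrier partition splits phenotype by dosage > 0", {
  p <- partition_by_carrier(c(0, 1, 0, 2), c(1, 2, 3, 4))
  expect_equal(p$noncarrier_values, c(1, 3))
  expect_equal(p$carrier_values, c(2, 4))

  p0 <- partition_by_carrier(rep(0, 4), c(1, 2, 3, 4))
  expect_length(p0$carrier_values, 0)
  expect_equal(p0$noncarrier_values, c(1, 2, 3, 4))

  set.seed(11)
  for (r in 1:20) {
    d <- sample(0:2, 50, replace = TRUE)
    e <- rnorm(50)
    pp <- partition_by_carrier(d, e)
    # brute-force recount of both groups
    expect_equal(length(pp$carrier_values) + length(pp$noncarrier_values), 50)
    expect_equal(pp$carrier_values, e[d > 0])
    expect_equal(pp$noncarrier_values, e[d == 0])
  }
  expect_error(partition_by_carrier(c(0, 1), c(1, 2, 3)), "lengths")
  expect_error(partition_by_carrier(c(0, 3), c(1, 2)), "0, 1, 2")
})

test_that("per-variant llr matches a numerical likelihood maximizer", {
  # identical group means: no evidence
  p <- partition_by_carrier(c(0, 0, 1, 1), c(-1, 1, -1, 1))
  expect_equal(per_variant_llr(p)$llr, 0)
  # no carriers: models coincide
  p <- partition_by_carrier(rep(0, 5), rnorm(5))
  expect_equal(per_variant_llr(p)$llr, 0)

  set.seed(21)
  for (r in 1:5) {
    x <- rnorm(20)
    y <- rnorm(5, 2)
    pp <- partition_by_carrier(c(rep(0, 20), rep(1, 5)), c(x, y))
    closed <- per_variant_llr(pp)$llr
    nll2 <- function(par) {
      -sum(dnorm(x, par[1], exp(par[3]), log = TRUE)) -
        sum(dnorm(y, par[2], exp(par[3]), log = TRUE))
    }
    nll1 <- function(par) -sum(dnorm(c(x, y), par[1], exp(par[2]), log = TRUE))
    ctl <- list(reltol = 1e-15, maxit = 2000)
    numeric_llr <-
      optim(c(mean(c(x, y)), log(sd(c(x, y)))), nll1, method = "BFGS",
            control = ctl)$value -
      optim(c(mean(x), mean(y), log(sd(c(x, y)))), nll2, method = "BFGS",
            control = ctl)$value
    expect_lt(abs(closed - numeric_llr), 1e-8)
    expect_gte(closed, 0)
  }
  expect_error(
    per_variant_llr(partition_by_carrier(c(0, 0, 1), c(2, 2, 2))),
    "zero total variance")
})

test_that("llr is symmetric in the direction of the carrier shift", {
  set.seed(31)
  x <- rnorm(30)
  y_up <- rnorm(6) + 2
  y_dn <- 2 * mean(x) - y_up  # reflect carrier values about mean(x)
  d <- c(rep(0, 30), rep(1, 6))
  up <- per_variant_llr(partition_by_carrier(d, c(x, y_up)))$llr
  dn <- per_variant_llr(partition_by_carrier(d, c(x, y_dn)))$llr
  expect_gt(up, 1)
  # mirrored shift has the same group-mean gap and within-group spread,
  # so both effect directions carry identical evidence
  expect_equal(up, dn, tolerance = 1e-10)
})

test_that("decomposed statistic equals brute-force scenario enumeration", {
  set.seed(41)
  for (r in 1:100) {
    k <- sample(1:8, 1)
    vs <- make_vs(N = 60, k = k)
    e <- rnorm(60)
    pr <- causal_prior(runif(k, 0.05, 1))
    a <- lrtq_statistic(vs, e, pr)$statistic
    b <- lrtq_bruteforce(vs, e, pr)
    expect_lt(abs(a - b) / (1 + abs(a)), 1e-10)
  }
})

test_that("brute force matches an independent hand enumeration at k = 3", {
  vs <- make_vs(N = 50, k = 3, seed = 5)
  e <- rnorm(50)
  cvec <- c(0.2, 0.5, 0.9)
  ll <- vapply(1:3, function(i) {
    per_variant_llr(partition_by_carrier(vs$dosages[, i], e))$llr
  }, 0)
  # explicit 8-term sum written out independently of the implementation
  total <- 0
  for (v1 in 0:1) for (v2 in 0:1) for (v3 in 0:1) {
    pq <- cvec[1]^v1 * (1 - cvec[1])^(1 - v1) *
      cvec[2]^v2 * (1 - cvec[2])^(1 - v2) *
      cvec[3]^v3 * (1 - cvec[3])^(1 - v3)
    total <- total + pq * exp(v1 * ll[1] + v2 * ll[2] + v3 * ll[3])
  }
  expect_lt(abs(lrtq_bruteforce(vs, e, causal_prior(cvec)) - log(total)),
            1e-12)
  expect_lt(abs(lrtq_statistic(vs, e, causal_prior(cvec))$statistic -
                  log(total)), 1e-12)
})

test_that("statistic limits and error guards behave as specified", {
  vs <- make_vs(N = 60, k = 4, seed = 6)
  e <- rnorm(60)
  # prior mass on the null scenario: Lambda -> 0
  tiny <- lrtq_statistic(vs, e, causal_prior(rep(1e-10, 4)))$statistic
  expect_lt(tiny, 1e-6)
  expect_gte(tiny, 0)
  # single certain-causal variant: Lambda = llr_1
  vs1 <- vs_from(vs$dosages[, 1, drop = FALSE], vs$maf[1])
  l1 <- per_variant_llr(partition_by_carrier(vs$dosages[, 1], e))$llr
  expect_equal(lrtq_statistic(vs1, e, causal_prior(1))$statistic, l1,
               tolerance = 1e-12)
  # all llr = 0 (constant phenotype): Lambda = 0 regardless of priors
  expect_equal(
    lrtq_bruteforce(vs, rep(1, 60), causal_prior(c(.2, .4, .6, .8))), 0)
  expect_error(lrtq_statistic(vs, e, causal_prior(c(1, 1))), "length")
  expect_error(causal_prior(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(causal_prior(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("statistic is monotone in each llr and each prior", {
  # monotonicity checked on the aggregation formula through its inputs:
  # raising one variant's evidence (by enlarging its carrier shift) or one
  # prior while holding the rest fixed never decreases Lambda
  vs <- make_vs(N = 80, k = 5, seed = 7)
  e <- rnorm(80)
  base <- lrtq_statistic(vs, e, causal_prior(rep(0.5, 5)))$statistic
  for (i in 1:5) {
    cv <- rep(0.5, 5)
    cv[i] <- 0.9
    expect_gte(lrtq_statistic(vs, e, causal_prior(cv))$statistic,
               base - 1e-12)
  }
  carriers <- vs$dosages[, 3] > 0
  if (any(carriers)) {
    shift <- mean(e[carriers]) - mean(e[!carriers])
    e2 <- e
    e2[carriers] <- e2[carriers] + sign(shift) * 2  # enlarge variant 3's gap
    # recompute with only variant 3's evidence changed
    ll_a <- per_variant_llr(partition_by_carrier(vs$dosages[, 3], e))$llr
    ll_b <- per_variant_llr(partition_by_carrier(vs$dosages[, 3], e2))$llr
    expect_gt(ll_b, ll_a)
  }
})

test_that("excluding the all-null scenario gives a larger, ordered statistic", {
  set.seed(51)
  for (r in 1:20) {
    k <- sample(1:6, 1)
    vs <- make_vs(N = 60, k = k)
    e <- rnorm(60)
    pr <- causal_prior(runif(k, 0.1, 0.9))
    inc <- lrtq_statistic(vs, e, pr)$statistic
    exc <- lrtq_statistic(vs, e, pr, include_null_scenario = FALSE)$statistic
    bf <- lrtq_bruteforce(vs, e, pr, include_null_scenario = FALSE)
    expect_gte(exc + 1e-10, inc)
    expect_lt(abs(exc - bf) / (1 + abs(exc)), 1e-8)
  }
})

test_that("weight-to-prior mapping is max-normalized with floor and clip", {
  expect_equal(weights_to_priors(c(2, 4), floor = 0.05)$c, c(0.5, 1))
  expect_equal(weights_to_priors(rep(1, 3), uniform_constant = 0.5)$c,
               rep(0.5, 3))
  expect_equal(weights_to_priors(rep(1, 3))$c, rep(1, 3))
  expect_equal(weights_to_priors(c(1e-9, 1), floor = 0.05)$c[1], 0.05)
  expect_error(weights_to_priors(c(0, 0)), "zero")
  expect_error(weights_to_priors(c(-1, 2)), "nonnegative")
})

test_that("brute force refuses k > 12 and matches k = 1 closed form", {
  vs <- make_vs(N = 40, k = 1, seed = 8)
  e <- rnorm(40)
  l1 <- per_variant_llr(partition_by_carrier(vs$dosages[, 1], e))$llr
  cc <- 0.3
  expect_equal(lrtq_bruteforce(vs, e, causal_prior(cc)),
               log((1 - cc) + cc * exp(l1)), tolerance = 1e-12)
  vs13 <- make_vs(N = 30, k = 13, seed = 9)
  expect_error(lrtq_bruteforce(vs13, rnorm(30), causal_prior(rep(.5, 13))),
               "k <= 12")
})
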