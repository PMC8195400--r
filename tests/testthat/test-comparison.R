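# Comparison tests: reductions to simple cases, hand-checked formulas,
# degenerate-input guards, and the Monte-Carlo oracle for the
# moment-matched SKAT tail approximation.

test_that("burden test reduces to simple regression for one variant", {
  vs <- make_vs(N = 120, k = 1, seed = 1)
  set.seed(2)
  e <- rnorm(120) + 0.5 * vs$dosages[, 1]
  r <- burden_test(vs, e, weights = 1)
  lmfit <- summary(lm(e ~ vs$dosages[, 1]))
  expect_equal(r$p_value, lmfit$coefficients[2, 4], tolerance = 1e-10)

  vs0 <- vs
  vs0$dosages[] <- 0L
  expect_warning(r0 <- burden_test(vs0, e), "zero variance")
  expect_equal(r0$p_value, 1)
})

test_that("burden loses power under mixed effect signs at equal |beta|", {
  set.seed(3)
  hits_same <- 0
  hits_mixed <- 0
  for (r in 1:150) {
    vs <- make_vs(N = 300, k = 6, maf = rep(0.03, 6))
    beta_same <- rep(1, 6)
    beta_mixed <- c(1, -1, 1, -1, 1, -1)
    e0 <- rnorm(300)
    p_same <- burden_test(vs, e0 + vs$dosages %*% beta_same)$p_value
    p_mixed <- burden_test(vs, e0 + vs$dosages %*% beta_mixed)$p_value
    hits_same <- hits_same + (p_same < 0.05)
    hits_mixed <- hits_mixed + (p_mixed < 0.05)
  }
  expect_gt(hits_same, hits_mixed + 10)
})

test_that("CMC collapses to a carrier t-test and guards degenerate input", {
  vs <- make_vs(N = 200, k = 5, seed = 4)
  carriers <- rowSums(vs$dosages) > 0
  set.seed(5)
  e <- rnorm(200)
  e[carriers] <- e[carriers] + 2 * sd(e)
  expect_lt(cmc_test(vs, e)$p_value, 1e-4)
  # matches a pooled-variance two-sample t-test done directly
  direct <- t.test(e[carriers], e[!carriers], var.equal = TRUE)$p.value
  expect_equal(cmc_test(vs, e)$p_value, direct, tolerance = 1e-12)
  vs0 <- vs
  vs0$dosages[] <- 1L
  expect_warning(r0 <- cmc_test(vs0, e), "constant")
  expect_equal(r0$p_value, 1)
})

test_that("WSS is reproducible and sensitive to a planted burden", {
  vs <- make_vs(N = 150, k = 5, seed = 6)
  set.seed(7)
  e <- rnorm(150)
  r1 <- wss_test(vs, e, n_perm = 500, seed = 9)
  r2 <- wss_test(vs, e, n_perm = 500, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0.01)  # null data
  e_sig <- e + rowSums(vs$dosages)
  expect_lt(wss_test(vs, e_sig, n_perm = 500, seed = 9)$p_value, 0.01)
})

test_that("VT with a single distinct MAF equals a burden permutation test", {
  # one threshold: the VT max over thresholds is the plain |cor| statistic,
  # checked against an explicit R permutation loop with the same statistic
  set.seed(8)
  G <- matrix(rbinom(400, 2, 0.04), 100, 4)
  G[1, 1] <- 1  # keep every column polymorphic
  vs <- vs_from(G, maf = rep(0.04, 4))
  e <- rnorm(100) + 0.6 * rowSums(G)
  r <- vt_test(vs, e, n_perm = 2000, seed = 10)
  score <- rowSums(G)
  obs <- abs(cor(score, e))
  set.seed(99)
  perm <- replicate(2000, abs(cor(score, sample(e))))
  p_oracle <- (1 + sum(perm >= obs - 1e-12)) / 2001
  se <- sqrt(max(p_oracle, 1e-4) * (1 - p_oracle) / 2000)
  expect_lt(abs(r$p_value - p_oracle), 3 * se + 2e-3)
})

test_that("VT picks low-MAF thresholds when causal variants are rarest", {
  set.seed(11)
  chosen_low <- 0
  trials <- 0
  for (r in 1:40) {
    maf <- c(0.01, 0.012, 0.015, 0.03, 0.04, 0.045)
    G <- matrix(rbinom(400 * 6, 2, rep(maf, each = 400)), 400, 6)
    if (!all(colSums(G) > 0)) next
    trials <- trials + 1
    # signal only in the three rarest variants
    e <- rnorm(400) + 2 * rowSums(G[, 1:3])
    cors <- vapply(sort(unique(maf)), function(t) {
      x <- rowSums(G[, maf <= t, drop = FALSE])
      if (var(x) == 0) return(0)
      abs(cor(x, e))
    }, 0)
    chosen_low <- chosen_low + (which.max(cors) <= 3)
  }
  # optimal threshold falls among the causal (rare) half far more often
  # than the 3/6 chance rate
  expect_gt(chosen_low / trials, 0.75)
})

test_that("ACAT combination matches the tangent formula by hand", {
  p <- c(0.01, 0.5, 0.9)
  # independent arithmetic
  expected <- 0.5 - atan(mean(tan((0.5 - p) * pi))) / pi
  r <- acat_o(c(a = 0.01, b = 0.5, c = 0.9))
  expect_equal(r$p_value, expected, tolerance = 1e-12)
  expect_equal(acat_o(c(0.5, 0.5, 0.5))$p_value, 0.5, tolerance = 1e-12)
  # heavy tail: the combination tracks the smallest component
  comb <- acat_o(c(1e-6, 0.4, 0.6))$p_value
  expect_lt(comb, 10 * 1e-6 * 3)
  expect_gt(comb, 1e-7)
  expect_error(acat_o(c(0.5)), "at least two")
  expect_warning(acat_o(c(1, 0.5)), "clipped")
})

test_that("ACAT-V reduces to the single-variant p-value at k = 1", {
  vs <- make_vs(N = 150, k = 1, seed = 12)
  set.seed(13)
  e <- rnorm(150) + 0.4 * vs$dosages[, 1]
  r <- acat_v(vs, e)
  direct <- summary(lm(e ~ vs$dosages[, 1]))$coefficients[2, 4]
  expect_equal(r$p_value, direct, tolerance = 1e-9)
})

test_that("SKAT reduces to the single-variant score test at k = 1", {
  vs <- make_vs(N = 200, k = 1, seed = 14)
  set.seed(15)
  e <- rnorm(200)
  r <- skat_test(vs, e)
  g <- vs$dosages[, 1]
  res <- e - mean(e)
  s2 <- sum(res^2) / 199
  z <- sum(g * res) / sqrt(s2 * sum((g - mean(g))^2))
  expect_equal(r$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-6)
  expect_true(r$approximate)
})

test_that("moment-matched SKAT tail agrees with Monte-Carlo mixture draws", {
  set.seed(16)
  for (r in 1:3) {
    vs <- make_vs(N = 300, k = 8)
    e <- rnorm(300) + 0.35 * vs$dosages[, 1]
    res <- skat_test(vs, e)
    lam <- res$details$lambda
    draws <- colSums(lam * matrix(rchisq(length(lam) * 50000, df = 1),
                                  nrow = length(lam)))
    p_mc <- mean(draws >= res$statistic)
    if (p_mc >= 1e-3 && res$p_value >= 1e-3) {
      expect_lt(abs(log10(res$p_value) - log10(p_mc)), 0.15)
    }
  }
})

test_that("SKAT-O interpolates between SKAT and burden behaviour", {
  set.seed(17)
  vs <- make_vs(N = 250, k = 6)
  e <- rnorm(250)
  r <- skat_o(vs, e)
  expect_true(r$approximate)
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
  # omnibus p bounded by the best marginal and its Bonferroni correction
  expect_gte(r$p_value, min(r$details$p_rho) - 1e-12)
  expect_lte(r$p_value, min(1, 11 * min(r$details$p_rho)) + 1e-12)
  # same-direction burden signal: the burden end of the grid fits better
  # than the pure SKAT end
  e_b <- rnorm(250) + 0.8 * rowSums(vs$dosages)
  rb <- skat_o(vs, e_b)
  expect_lt(rb$p_value, 0.01)
  expect_lt(rb$details$p_rho[11], rb$details$p_rho[1])
})
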