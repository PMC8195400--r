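# Genotype and phenotype simulators, and the type-I / power harnesses.

test_that("simulated regions match the configured spectrum and count", {
  cfg <- region_config(n_individuals = 400)
  set.seed(1)
  ks <- numeric(300)
  dos_mean <- c()
  mafs <- c()
  for (i in 1:300) {
    vs <- simulate_region(cfg)
    ks[i] <- n_variants(vs)
    if (i <= 50) {
      dos_mean <- c(dos_mean, colMeans(vs$dosages))
      mafs <- c(mafs, vs$maf)
    }
  }
  expect_true(all(ks >= 1))
  # Poisson(33.1) mean within 3 SE over 300 draws
  expect_lt(abs(mean(ks) - 33.1), 3 * sqrt(33.1 / 300))
  expect_true(all(mafs < 0.05 & mafs > 0))
  # binomial expectation: dosage mean tracks 2 * maf
  expect_lt(abs(mean(dos_mean - 2 * mafs)), 0.002)
  expect_gt(cor(dos_mean, mafs), 0.95)
  # seed reproducibility
  expect_identical(simulate_region(cfg, seed = 5)$dosages,
                   simulate_region(cfg, seed = 5)$dosages)
})

test_that("null phenotype has variance 2 and no genotype term", {
  x <- simulate_null_phenotype(100000, seed = 2)
  expect_gt(var(x), 1.96)
  expect_lt(var(x), 2.04)
  expect_lt(abs(mean(x)), 0.02)
  expect_identical(simulate_null_phenotype(50, seed = 3),
                   simulate_null_phenotype(50, seed = 3))
})

test_that("alternative effect sizes follow a * |log10 MAF| with mixed signs", {
  G <- matrix(rbinom(2000 * 2, 2, 1 / 2000), 2000, 2)
  G[1, ] <- 1L
  vs <- vs_from(G, maf = rep(1 / 2000, 2))
  sim <- simulate_alt_phenotype(
    vs, phenotype_sim_config(a = 1.5, causal_ratio = 1), seed = 4)
  expect_equal(abs(sim$causal$beta), rep(1.5 * log10(2000), 2),
               tolerance = 1e-12)
  expect_equal(abs(sim$causal$beta), rep(4.95, 2), tolerance = 0.005)
  sim03 <- simulate_alt_phenotype(
    vs, phenotype_sim_config(a = 0.3, causal_ratio = 1), seed = 4)
  expect_equal(abs(sim03$causal$beta), rep(0.99, 2), tolerance = 0.001)
  # a = 0 reduces exactly to the null model
  sim0 <- simulate_alt_phenotype(
    vs, phenotype_sim_config(a = 0, causal_ratio = 1), seed = 4)
  expect_true(all(sim0$causal$beta == 0))
  # signs are mixed over repeated draws
  set.seed(5)
  vs_many <- make_vs(N = 100, k = 40)
  signs <- simulate_alt_phenotype(
    vs_many, phenotype_sim_config(a = 1, causal_ratio = 1))$causal$beta
  expect_gt(sum(signs > 0), 5)
  expect_gt(sum(signs < 0), 5)
})

test_that("at least one causal variant is always planted", {
  vs <- make_vs(N = 50, k = 3, seed = 6)
  sim <- simulate_alt_phenotype(vs, phenotype_sim_config(causal_ratio = 0.03),
                                seed = 7)
  expect_gte(nrow(sim$causal), 1)
})

test_that("type-I harness returns calibrated rates with binomial CIs", {
  tab <- estimate_type1_error(methods = c("cmc", "burden"), n_reps = 250,
                              alphas = c(0.05, 0.0001),
                              region = region_config(n_individuals = 300,
                                                     target_mean_rare_variants = 15),
                              seed = 11)
  r <- tidy(tab)
  expect_setequal(r$method, c("CMC", "Burden"))
  at05 <- r[r$alpha == 0.05, ]
  expect_true(all(at05$ci_lo <= at05$estimate & at05$estimate <= at05$ci_hi))
  # analytic tests on null data: within 3 binomial SE of nominal
  expect_true(all(abs(at05$estimate - 0.05) < 3 * sqrt(0.05 * 0.95 / 250)))
  expect_true(all(r$unstable[r$alpha == 1e-4]))
  expect_false(any(at05$unstable))
})

test_that("unequal carrier variance does not inflate the LRT-q null rate", {
  # robustness setting: carriers of 'causal' variants get variance-2
  # covariates but no mean shift (a = 0), violating the pooled-variance
  # assumption under the null
  region <- region_config(n_individuals = 300,
                          target_mean_rare_variants = 15)
  n_reps <- 400
  rej <- 0
  for (i in seq_len(n_reps)) {
    p <- lrtq:::with_seed(lrtq:::derive_seed(21, i), {
      vs <- simulate_region(region)
      sim <- simulate_alt_phenotype(
        vs, phenotype_sim_config(a = 0, causal_ratio = 0.1,
                                 unequal_variance_mode = TRUE))
      run_rv_methods(vs, sim$phenotype, "lrtq", n_perm = 500)
    })
    rej <- rej + (p[["lrtq"]] < 0.05)
  }
  expect_lt(abs(rej / n_reps - 0.05), 3 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("power harness output is tidy and p-value storage is complete", {
  tab <- estimate_power(methods = c("burden", "cmc"), a_grid = c(0, 1.5),
                        causal_ratios = 0.1, n_reps = 60,
                        region = region_config(n_individuals = 200,
                                               target_mean_rare_variants = 10),
                        seed = 13)
  r <- tidy(tab)
  expect_equal(nrow(r), 4)
  expect_true(all(r$power >= 0 & r$power <= 1))
  expect_true(all(r$ci_lo <= r$power & r$power <= r$ci_hi))
  expect_equal(nrow(tab$pvalues), 60 * 2 * 2)
  # the a = 0 boundary of the grid is the null model
  p0 <- r[r$a == 0, ]
  expect_true(all(p0$power < 0.2))
  pl <- autoplot(tab)
  expect_s3_class(pl, "ggplot")
})
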