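---
title: "Rare-variant association testing for gene expression with lrtq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant association testing for gene expression with lrtq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lrtq)
library(dplyr)
```

## The problem

Expression quantitative trait locus (eQTL) studies routinely find common
variants that regulate nearby genes, but rare variants (minor allele
frequency below 5%, or 1% in the strict definition) are much harder:
any single rare variant is carried by a handful of individuals, so
single-marker tests have essentially no power at eQTL sample sizes.
Set-based tests that aggregate all rare variants in a window around a
gene's transcription start site (TSS) recover power, but the classical
aggregation schemes are linear (weighted sums of per-variant scores), which
costs power when causal variants push expression in both directions and
when most variants in the window are not causal at all.

`lrtq` implements a likelihood ratio test for quantitative traits that
addresses both issues. Per variant $i$, samples split into $m_i$
non-carriers with expression $X_i$ and $n_i$ carriers with expression
$Y_i$ (carrier = at least one minor allele; dominant coding). Under
normality with a shared, per-model profiled variance, the per-variant
evidence is a likelihood ratio between the two-mean and the common-mean
model, which has the closed form

$$\ell_i = \tfrac{N}{2}\,\log\!\frac{SS_0}{SS_1},$$

with $SS_0$ the total sum of squares about the grand mean and $SS_1$ the
pooled within-group sum of squares. $\ell_i \ge 0$, is zero when there
are no carriers, and depends only on the magnitude of the carrier shift,
not its direction — so effects of either sign contribute.

Each variant has a prior causal probability $c_i \in (0,1]$, derived from
functional annotation (CADD- or LINSIGHT-style scores, MAF, TSS
distance). Writing $V = (v_1,\dots,v_k)$ for an unknown causal
configuration with $P(V) = \prod_i c_i^{v_i}(1-c_i)^{1-v_i}$, the test
statistic marginalizes the likelihood over all $2^k$ configurations and
compares against the all-null configuration. Because variants are assumed
independent, the $2^k$-term sum factorizes, giving the $O(kN)$ form

$$\Lambda = \sum_{i=1}^{k} \log\bigl[(1-c_i) + c_i e^{\ell_i}\bigr].$$

The aggregation is deliberately *nonlinear* in the per-variant evidence:
a variant with large $\ell_i$ dominates its own term regardless of the
other variants, while variants with no evidence contribute nothing even
with a large prior. `lrtq_bruteforce()` implements the literal $2^k$
enumeration as a reference oracle (capped at $k \le 12$), and the test
suite checks the two agree to relative error below $10^{-8}$ across
hundreds of random instances.

Significance comes from a permutation test: the (already
covariate-adjusted) phenotype vector is permuted across samples,
genotypes and priors fixed, and
$p = (1 + \#\{\Lambda_{perm} \ge \Lambda_{obs}\})/(1 + B)$ — never
exactly zero. Permuting the phenotype preserves any genotype correlation
and is the standard permutation null in eQTL work.

```{r quick-example}
set.seed(1)
vs <- simulate_region(region_config(n_individuals = 500))
sim <- simulate_alt_phenotype(vs, phenotype_sim_config(a = 1.5,
                                                       causal_ratio = 0.1))
res <- lrtq_test(vs, sim$phenotype, seed = 7)
glance(res)
head(arrange(tidy(res), desc(llr)))
```

## Design choices in the core statistic

Several details of the estimator are open design territory; the choices
made here, and why:

* **Profile-MLE closed form for $\ell_i$.** Both models share a single
  variance parameter estimated by maximum likelihood (divisor $N$, not
  $N-1$), which is the standard realization of a pooled-variance
  assumption and makes $\ell_i$ available in closed form. The test suite
  validates it against a generic numerical likelihood maximizer to
  $10^{-8}$.
* **Weight-to-prior mapping.** Annotation weights are mapped to priors by
  max-normalization with a floor: $c_i = \mathrm{clip}(w_i/\max_j w_j,
  0.05, 1)$. This makes priors scale-free (only weight ratios matter)
  and keeps every variant minimally in play. A uniform weight vector is
  special-cased: the harnesses use the constant prior $c_i = 0.5$, the
  conventional noninformative operating point; $c_i = 1$ (the raw
  max-normalized image of uniform weights) would assert certainty that
  every variant is causal, which contradicts the premise that only a
  few percent of rare variants are. Permutation calibration is unaffected
  by the choice; only power ordering across priors changes.
* **All-null configuration.** The scenario sum includes $V = 0$ by
  default. The alternative convention ("at least one causal variant",
  excluding $V=0$ and renormalizing) is available via
  `include_null_scenario = FALSE`; it is a monotone transform of the same
  statistic for a fixed prior, so permutation p-values are essentially
  unchanged. Including it only shrinks $\Lambda$ toward zero.
* **Inert zero-carrier variants.** Variants with no carriers contribute
  $\ell_i = 0$ and stay in the set rather than being dropped, so $k$ (and
  the prior vector) is stable across permutations.
* **Numerical stabilization.** $\log[(1-c)+ce^{\ell}]$ is computed as
  $\ell + \log[c + (1-c)e^{-\ell}]$ so large $\ell_i$ never overflow, and
  $SS_1$ is floored at $10^{-12} SS_0$ so perfectly separating carriers
  yield a large finite statistic instead of infinity.
* **Degenerate inputs.** A constant phenotype gives $\ell_i = 0$ for all
  variants at the statistic level (and permutation $p = 1$);
  `per_variant_llr()` on its own treats zero total variance as an input
  error, since there is nothing to estimate.

## Adaptive permutations

Permutation testing dominates the cost of a transcriptome-wide scan, and
most genes are null. `adaptive_permutation_pvalue()` therefore runs a
two-stage scheme: 1,000 screening permutations, early stop if the interim
p-value exceeds 0.05 (futility), otherwise continue to 100,000. Null
genes cost 1,000 permutations; promising genes get p-value resolution of
$10^{-5}$. The acceptance suite verifies that adaptive and fixed
permutation p-values agree within three binomial standard errors and make
the same calls at $p<0.01$ on at least 95% of null genes.

## Comparison tests

The package re-implements the standard rare-variant tests behind the same
`(variants, phenotype, ...) -> rv_test` interface, following their
published definitions, with quantitative-trait adaptations where the
originals are case-control tests:

* **Burden** — weighted dosage sum per sample, slope t-test.
* **CMC** — collapse to a carrier indicator, pooled-variance two-sample
  t-test.
* **WSS** — Madsen–Browning frequency weights
  $w_i = 1/\sqrt{N q_i(1-q_i)}$, rank-based score statistic, permutation
  p-value.
* **VT** — burden z-score maximized over all distinct MAF thresholds
  (ties collapse), two-sided (maximum absolute correlation), permutation
  p-value. Two-sidedness and the permutation count are declared defaults,
  not inherited ones.
* **ACAT-V / ACAT-O** — Cauchy combination of single-variant p-values /
  of component tests (default components VT, ACAT-V, SKAT-O); p-values
  clipped to $[10^{-15}, 1-10^{-15}]$ to keep the tangent finite.
* **SKAT / SKAT-O** — variance-component score statistic with the null
  mixture of chi-squares approximated by Liu-type moment matching
  (results carry `approximate = TRUE`); SKAT-O searches the
  $\rho$-grid $\{0, 0.1^2, \dots, 1\}$ and handles the minimum-p null by
  one-dimensional integration over the shared burden component, with the
  reported p-value clamped between the best marginal p and its Bonferroni
  bound. Exact characteristic-function inversion is deliberately out of
  scope; the moment-matched tail is checked against 50,000-draw
  Monte-Carlo mixture sampling in the 0.001–0.5 range where calibration
  matters.

## The simulation study

`simulate_region()` replaces coalescent haplotype simulation with an
LD-free site-frequency-spectrum generator: variant count
$\sim$ Poisson(33.1) for the 5-kb design (19.8 for the 3-kb variant),
population MAFs with density $\propto 1/x$ truncated to
$[2\times10^{-5}, 0.05)$ (the lower end corresponding to a 50,000
haplotype pool), genotypes Binomial(2, MAF). Two things follow from this
choice. First, the core statistic assumes variant independence anyway and
null calibration is insensitive to LD, so type-I error estimates are
directly meaningful. Second, absolute power values under real LD
structure are **not** reproduced — power comparisons across methods on
this generator are qualitative (orderings), not numeric targets.

The null phenotype is $E_j = A_j + \varepsilon_j$ with both terms
standard normal (variance 2 in total); the alternative adds
$\beta^\top G_j$ over $s = \max(1, \mathrm{round}(\text{causal ratio}
\cdot k))$ causal variants with $|\beta_i| = a\,|\log_{10}\mathrm{MAF}_i|$
and a 50% chance of a negative sign. At $N = 1000$ and a 5% MAF cutoff
this yields maximum effect sizes 0.99–4.95 for $a \in \{0.3, \dots,
1.5\}$. Robustness variants: $a \sim N(1,1)$ per causal variant, and an
unequal-variance mode in which carriers of causal variants receive a
variance-2 covariate term (violating the pooled-variance assumption).

The harnesses run at desk scale by default — 10,000 replicates for
type-I error (rejection rates at $\alpha \in \{0.05, 0.01\}$ with exact
binomial CIs; the $\alpha \le 10^{-3}$ rows are flagged unstable at this
scale since fewer than ten rejections are expected), 2,000 for power —
with the full published scale available by raising `n_reps`. Replicate
seeds derive from the master seed by a counter scheme, so replicates are
order-independent and grid cells share genotype draws (nearly paired
power comparisons).

```{r type1-demo}
tab <- estimate_type1_error(methods = c("lrtq", "burden"), n_reps = 300,
                            region = region_config(n_individuals = 300,
                                                   target_mean_rare_variants = 15),
                            n_perm = 1000, seed = 42)
tidy(tab)
```

## The eGene discovery pipeline

`eqtl_map()` chains the stages a tissue-level analysis needs:

1. **QC'd genotypes** (`read_genotypes_with_qc()`): autosomal sites,
   VQSR-failing sites removed, calls with GQ < 20 marked missing, sites
   with > 5% missing calls removed, remaining missing calls imputed as
   homozygous reference (defensible precisely because the variants are
   rare), multiallelic records split per alternate allele, and a MAF
   filter $0 < \mathrm{MAF} < 5\%$ computed after imputation. Every
   removal is counted by reason and the accounting identity
   (input = survivors + removals) is tested.
2. **Windowing** (`assign_variants_to_windows()`): a variant belongs to a
   gene when within 20 kb of its TSS (closed interval, 1-based) or inside
   the gene body when gene bounds are provided — the latter is an
   interpretation choice, flagged in the function documentation.
3. **Normalization** (`residualize_and_int()`): OLS residuals on the
   supplied covariates (genotype PCs, PEER factors, sex, platform — the
   pipeline consumes PEER factors, it never computes them), then the
   rank-based inverse normal transform with the Blom offset $c = 3/8$
   (the offset is unstated in common descriptions; Blom is the
   conventional choice), ties by average rank.
4. **Per-gene tests** with any method and one of eight weighting schemes
   (uniform, inverse MAF, inverse TSS distance `1/(1+d)`, CADD, LINSIGHT,
   and the three products MAF×TSS, MAF×CADD, MAF×CADD×TSS); missing
   annotation values get the scheme's minimum observed weight, counted in
   a warning.
5. **eGene calling** (`call_egenes()`): Benjamini–Hochberg q-values at
   FDR 5% by default. Storey's $\pi_0$-adjusted variant is available
   behind a flag since large eQTL consortia conventionally use q-values;
   with unstated FDR methodology, BH is the safer default and the two are
   documented rather than silently chosen. A fixed p-value threshold mode
   (e.g. $10^{-4}$) supports sensitivity analyses in which FDR across a
   heterogeneous p-value mixture would be misleading, such as re-testing
   after `regress_out_top_eqtl()` removes the strongest common eQTL
   within 20/50/100 kb of the TSS (ties break to the lowest genomic
   position).

Downstream summaries: `tissue_sharing_fraction()` (shared eGenes over the
smaller per-tissue count), `tissue_specificity_bins()` (1 / 2–4 / >4
tissues, with matched-count selection of top common-variant eGenes via
`top_egenes_by_q()`), `expression_outlier_zscores()`
($\log_2(\mathrm{TPM}+1)$, per-gene Z-scores, covariate residualization,
re-standardization — Z-scores rather than rank normalization precisely to
avoid shrinking outliers — and $|Z| > 2$ outlier flags, thresholds 1–10
supported), `outlier_rv_enrichment()` (relative risk of carrying a
proximal rare variant for outliers vs non-outliers, Wald CI on the log
scale) and `disease_enrichment()` (Fisher's exact test on the eGene ×
disease-database 2×2 table).

## The synthetic fixture

`generate_fixture()` writes a complete small dataset — VCF with GT:GQ
calls, expression and covariate tables, annotations, a TSS BED and a
truth table — with the statistical structure of the simulation study:
200 genes 100 kb apart, 300 samples, ~30 rare variants per window, and
5 planted rare-variant eGenes at $a = 1.5$, causal ratio 10%. Design
choices worth stating:

* Population MAFs are floored at $1/(2N)$: a cohort-ascertained variant
  set only contains variants someone carries.
* Planted causal variants are drawn among variants with at least 3
  carriers *and* in-sample frequency safely below the rarity cutoff.
  Both conditions keep the planted truth meaningful: a causal variant
  with no carriers puts no signal in the data, and one whose realized
  frequency drifts above 5% is removed by QC before testing, silently
  deleting the signal it explains.
* The VCF carries mild QC noise (~0.5% low-GQ calls, ~0.2% missing
  calls) plus one high-missingness decoy site and one VQSR-failing decoy
  site, so the QC chain is exercised end to end.

What the fixture does **not** emulate: linkage disequilibrium, population
structure, expression count noise (expression is Gaussian on a log-like
scale), shared eQTL architecture across tissues, or annotation scores
that correlate with causality. A pipeline that passes the planted-signal
test therefore demonstrates correct mechanics and calibrated error
control on idealized data, not performance on real cohorts.

## Problem sizes and determinism

The shipped test-suite and acceptance settings are 10,000 replicates for
type-I error, 2,000 for power and for permutation-uniformity checks, 500
genes for the adaptive-vs-fixed comparison, and five fixture seeds for
planted-signal recovery; these sizes put three-binomial-SE bands well
inside scientific relevance while keeping a desk run short. All
randomness flows through R's RNG — including the compiled Fisher–Yates
shuffle in the permutation core — so any seed reproduces results
bit-for-bit, and functions that take a `seed` argument restore the
caller's RNG state.

## Known limitations

* Variant independence is assumed throughout; no LD correction is
  applied. LD pruning, if desired, is a preprocessing step outside the
  package.
* SKAT/SKAT-O p-values are moment-matched approximations; far tails
  (below ~$10^{-4}$) should not be over-interpreted.
* The adaptive scheme's smallest attainable p-value is $1/(B_{max}+1)$;
  genome-scale FDR at very small q-values needs `max_perm` raised
  accordingly.
* The dichotomous-trait ancestor of this test, Bayesian posteriors over
  causal configurations, and cross-tissue meta-analysis are out of scope.
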