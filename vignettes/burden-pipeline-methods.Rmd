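---
title: "Methods: rare coding-variant burden association with whole-genome regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare coding-variant burden association with whole-genome regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ultrarare protein-coding variants — each seen in a handful of carriers —
can have large effects on complex traits such as adult cognitive function,
but no single variant carries enough carriers to test on its own. The
standard remedy is the burden test: per sample, count qualifying rare
alleles in a unit (a gene, a gene set, or the whole exome) and regress the
phenotype on that count. `cogburden` implements this pipeline end to end:
variant functional classification, burden construction, two-step
whole-genome regression for gene discovery in the presence of
polygenicity and relatedness, Firth-fallback phenome-wide scanning,
random-effects meta-analysis across cohorts, and joint modelling of
polygenic scores with rare-variant carrier status. Because the biobank
data such analyses are built on are access-controlled, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
methods assume, so every stage is testable and its operating
characteristics (calibration, power, recovery of injected effects) are
measurable.

# Variant classification and burden units

Variants arrive annotated (consequence, LoF confidence, MPC missense
deleteriousness score, gene-level pLI, in-cohort MAF); computing those
annotations is out of scope. Classification is a total function of the
annotation:

* **PTV** — stop-gain, frameshift or splice-disrupting consequence with a
  high-confidence LoF call. Low-confidence LoF falls to "other".
* **Missense tiers** — tier 1: MPC > 3; tier 2: 2 < MPC <= 3; tier 3: all
  remaining missense. A missing MPC cannot exceed a threshold, so it is
  tier 3.
* **Synonymous** — its own class (the negative control in exome-wide
  scans).

Strata by LoF intolerance use pLI >= 0.9 ("high") vs < 0.9 ("low");
missing pLI forms an "unknown" stratum that is excluded from stratified
burdens but contributes to unstratified ones, so nothing is silently
misclassified. All boundary conventions are strict as stated: MAF
< 1e-5, MPC > 3, 3 >= MPC > 2, pLI >= 0.9, and a minimum of 10 carriers
per tested gene. Missing genotypes contribute 0 to burden sums — carriers
are defined by observed alternate alleles, which is conservative in the
ultrarare regime.

The rarity filter is stated as an in-cohort frequency (MAF < 1e-5 in a
~450k cohort). At synthetic cohort sizes that bound is vacuous (a
singleton already exceeds it), so the generator parameterizes carriers
directly, records the realized in-cohort MAF, and analysis-scale filters
use the equivalent minor-allele-count form `mac_to_maf(5, n)` — the MAC <
5 cutoff whose MAF equivalent (2.06e-5 at n = 121,570) is the recognized
alternative formulation. This keeps the filter's behaviour meaningful at
any n.

# Two-step whole-genome regression

Gene-based tests on biobank-scale cohorts must absorb polygenic
background and sample relatedness without fitting one mixed model per
gene. The two-step approach does this once per phenotype:

**Step 1 (stacked block ridge).** Common variants passing QC (call rate
>= 90%, HWE p >= 1e-15, MAF >= 1%) are standardized (mean-imputed,
centred by 2p, scaled by sqrt(2p(1-p))) and cut into within-chromosome
blocks (default 1,000 variants). For each block, ridge predictors are fit
across a shrinkage grid with k-fold cross-validation (default 10),
retaining out-of-fold predictions. Penalties are parameterized as assumed
heritabilities: lambda = M(1-h2)/h2 over h2 in {0.01, 0.1, 0.25, 0.5,
0.75}, M the total variant count — the standard stacked-ridge
construction. For each left-out chromosome c, the block predictions from
all *other* chromosomes are combined by a second, cross-validated ridge
("stacking"), giving the leave-one-chromosome-out (LOCO) genetic
prediction. Using out-of-fold level-0 predictions as level-1 features
prevents the stack from overfitting. The exclusion contract — column c is
invariant to any change of chromosome-c genotypes — holds by
construction and is verified exactly by a permutation test.

**Step 2 (offset test).** Each gene's burden is tested by OLS of
`INT(phenotype) - LOCO[, chrom(gene)]` on the burden plus the covariates,
with a two-sided t-test on the burden coefficient and a +-1.96 SE
confidence interval. With a zero offset this reduces identically to the
plain covariate-adjusted linear burden test. The step-2 SE is the
ordinary OLS standard error of the offset regression; this is documented
rather than claimed to reproduce any external tool's numerical output.
Binary traits are analysed by (Firth-fallback) logistic regression
without a LOCO offset, matching how the quantitative and binary arms of
the original analyses were run. The vectorized `burden_scan()` performs
step 2 for thousands of genes via a single QR of the covariate design and
Frisch–Waugh projections of the sparse burden matrix.

# Phenotype preparation

Quantitative phenotypes are rank-based inverse-normal transformed:
`z = qnorm((r - 3/8) / (n + 1/4))` with average ranks for ties. The rank
offset is configurable ({3/8, 1/2, 0}); Blom's 3/8 is the default as the
most common choice in genetics pipelines, and ties take average ranks so
the transform is deterministic and permutation-invariant. Covariates are
sex, age, age^2, sex:age, sex:age^2, 20 principal components and
recruitment-centre indicators (first level as reference); samples with
any missing covariate are flagged for complete-case exclusion. Two
orders of operations coexist deliberately: association tests use
INT-then-adjust (covariates inside the regression); descriptive carrier
summaries use residualize-then-INT. Both are exposed explicitly rather
than hidden behind one default. Outlier exclusion for quantitative
phenome-wide traits is a single pass at 5 SD from the mean (no
re-iteration), applied before the INT; a constant vector (SD 0) retains
everything.

# Association statistics

* **Linear**: OLS with t-based p and CI.
* **Logistic**: ML fit; Wald CI and p on the log-OR; separation and
  non-convergence are flagged so callers can fall back to Firth.
* **Firth**: Newton iterations on the Jeffreys-penalized score
  `U*(b) = X'(y - mu + h(1/2 - mu))`, h the hat diagonal, until the score
  norm drops below 1e-6 (at most 100 iterations, large steps damped).
  Estimates exist and are finite under complete separation; on a 2x2
  table with a zero cell the estimate coincides with the half-corrected
  log-OR. Wald p is the default; a penalized-likelihood-ratio p is
  available (the choice is genuinely open in the field; Wald is what a
  Wald-CI-reporting pipeline implies).
* **Multiple testing**: Bonferroni thresholds are alpha/n_tests computed
  from the actual number of tests run per phenotype; FDR q-values are
  Benjamini–Hochberg. The genomic inflation factor is the median of the
  implied chi-square(1) statistics over its null median (~0.455).
* **Meta-analysis**: inverse-variance-weighted random effects with the
  DerSimonian–Laird tau^2 truncated at zero; with tau^2 = 0 this reduces
  to fixed effects. CIs for logistic, Firth and meta use the normal 1.96
  multiplier; the linear test uses the exact t quantile.

# Phenome-wide scanning

One gene's burden is tested against a catalogue of phenotypes: binary
phenotypes need >= 100 cases, are tested by logistic regression, and any
with p < 0.01 are re-tested with Firth regression, whose result replaces
the ML row; quantitative phenotypes need >= 100 observations, are
outlier-filtered at 5 SD and INT-transformed. The phenome-wide threshold
is alpha over the catalogue size by default — matching the convention
that defines the threshold before case-count filtering — with the
tests-actually-run version also reported.

# PRS and joint modelling

Polygenic scores are weighted allele sums over the intersection of
weight and genotype variants, with ref-oriented effect alleles flipped
(`2 - dosage`), strand-ambiguous (A/T, C/G) and allele-mismatched weight
variants dropped with a count logged, and missing dosages contributing
the variant mean. Weight *estimation* (PRS-CS and kin) is out of scope;
weights are consumed as input. The joint model regresses the INT
phenotype on the standardized PRS (so effects are per PRS SD), PTV
carrier status and damaging-missense (MPC > 2) carrier status — both
carrier definitions restricted to LoF-intolerant genes (pLI > 0.9 in
this analysis; the >= variant used elsewhere is configurable, mirroring
the two printed conventions) and rare variants — plus covariates.
Partial R^2 per predictor is (SSE_reduced - SSE_full)/SSE_reduced; plain
partial R^2 is the default, with the adjusted variant left to the
reader since its formula is not pinned down in the field's reports.
Additivity is checked by PRS x carrier interaction terms, and PRS
quantile groups (20%, 2%, or top-10% vs rest) are summarized by the
median standardized residualized phenotype per group x carrier stratum.

# The synthetic-cohort generator

`sim_config()` + `simulate_cohort()` generate:

* **Common genotypes**: Hardy–Weinberg dosages at MAFs U(0.01, 0.5)
  (matching the QC floor), in contiguous chromosome blocks; optional
  sibling pairs built by explicit Mendelian transmission from simulated
  parents, giving the ~0.5 genotype correlation that makes relatedness
  testable.
* **Rare variants**: per gene, Binomial(n, carrier_rate) carriers sampled
  without replacement, one singleton heterozygous variant per carrier
  (the ultrarare regime), class labels drawn from `class_mix`, MPC scores
  consistent with the tier, gene-level pLI with a configurable
  high-pLI fraction, and realized in-cohort MAF recorded. The default
  carrier rate 1/1,900 is the rate observed for a LoF-tolerant gene in a
  ~450k adult cohort; the default class mix (7.1% PTV / 59.4% missense /
  33.5% synonymous, missense split 2/8/90% across tiers 1–3) follows the
  relative abundance of rare coding variants in large exome studies, with
  the tier split a package choice since tier counts are not published.
* **Phenotypes**: liability = covariate effects + polygenic component
  (variance h2, computed from the common genotypes when present so
  siblings share it) + sum of per-gene burden effects + Gaussian noise
  scaled so the total variance is 1; configurations whose systematic
  variance exceeds 1 are rejected. Binary traits threshold the centred
  liability at `qnorm(1 - prevalence)`. For replication-style analyses
  where a target odds ratio must be recovered exactly,
  `simulate_binary_logistic()` generates the outcome from a logistic
  model with the log-OR injected directly, because a liability-threshold
  parameterization has no closed-form mapping to a target OR.

What the generator does **not** emulate: linkage disequilibrium,
haplotype structure, imputation error, genuinely population-stratified
allele frequencies, informative missingness, or phenotype measurement
artefacts. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under the assumed generative model,
not that any particular biological result would replicate on real data.

# Problem sizes, numerics, and limitations

The packaged analyses and checks use desk-scale problem sizes chosen to
make sampling error small relative to the tolerance being checked:
calibration uses 2,000 null genes on a n = 5,000 cohort (h2 = 0.3, 500
sibling pairs; type-I error compared against the binomial 95% band);
effect recovery uses n = 100,000 with ~200 carriers for the quantitative
case (matching the carrier count at which the headline gene effects were
estimated) and ~3,000 set carriers for the odds-ratio case; oracle
equivalence runs 100 random small instances per statistic. The analysis
drivers under `analysis/` use a 20,000-sample cohort with 400 genes.

Numerical choices: ridge systems are solved by Cholesky-backed `solve()`
on crossproducts (blocks are small by construction); the burden scan
works in the covariate-orthogonal complement via one QR, which is exact
OLS; Firth Newton steps are damped at max |step| = 5; monomorphic
variants standardize to zero columns; BH monotonicity comes from the
step-up formulation. Degenerate inputs fail loudly: zero-variance
burdens, rank-deficient covariate designs (offending columns named),
constant vectors passed to the INT, single-chromosome LOCO requests, and
binary outcomes with one class.

Known limitations: step 2's OLS-with-offset SE ignores the sampling
variability of the step-1 predictions (as does the method it mirrors);
the Wald logistic test is slightly conservative at very low carrier
counts (hence the Firth fallback); DerSimonian–Laird tau^2 is noisy with
two studies, so a heterogeneous pair can meta-analyse to a *larger* p
than its stronger member — visible in the replication driver — which is
a property of the estimator, not a defect; and the exome-wide burden
assumes one gene per variant (canonical transcript), so variants in
overlapping genes are not double-counted.
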