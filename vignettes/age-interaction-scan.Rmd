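---
title: "Genome-wide SNP-by-age interaction scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide SNP-by-age interaction scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpage)
```

## The scientific problem

Genetic effects on cardiometabolic risk factors need not be constant over
the life course: a variant that raises LDL-C strongly in the forties may
show a much weaker association in the sixties, through biology
(age-modulated expression), survivorship, or treatment. A genome-wide
interaction study (GWIS) tests, for every variant, the coefficient of a
variant-by-age product term. This package implements that scan for five
continuous risk factors — ApoB (g/L), LDL-C (mmol/L), natural-log TG
(mmol/L), SBP (mmHg), BMI (kg/m²) — together with the preprocessing,
multiple-testing structure, lead-variant selection, look-up testing and
stratified estimation that surround it, and a synthetic cohort generator
that makes the whole chain testable with known truth.

## The models

For individual $i$ with trait $y_i$, dosage $g_i \in [0,2]$, age $a_i$
(years), sex and ten genetic principal components $PC_{1..10}$:

**Interaction model**
$$y_i = \beta_0 + \beta_G g_i + \beta_{age} a_i +
  \beta_{G\times age}\, g_i a_i + \beta_{sex} sex_i +
  \sum_k \gamma_k PC_{ki} + \varepsilon_i$$

**Marginal model** — the same design without the product term; its $g$
coefficient is the conventional GWAS test.

Both are ordinary least squares; all five traits are analysed as
continuous Gaussian outcomes. The Wald statistic
$\hat\beta_{G\times age}/\widehat{se}$ is referred to the $t$
distribution with residual degrees of freedom — indistinguishable from the
normal at biobank sample sizes but exact at the sizes used in tests.
$\beta_{G\times age}$ is reported in trait units per effect allele per
year; age enters uncentred so the per-year scale is preserved.
$\beta_{G\times age}$, its SE and p-value are invariant to shifting age by
any constant (a tested property); only $\beta_G$'s interpretation moves
(its value at age 0 versus at the centring point). Model-based standard
errors are the default; HC0 heteroscedasticity-robust sandwich errors are
available behind `se_type = "robust"` and are cross-checked against the
sandwich package in the test suite.

### The streaming fast path

`scan_block()` fits all variants of a block against one trait reusing a
single design skeleton, swapping the $g$ and $g\cdot a$ columns per
variant. It is the same QR factorisation as the per-variant functions, so
equality (to relative $10^{-10}$, against an independent brute-force
normal-equation solve) is a tested contract, not an approximation.
Degenerate variants — monomorphic, collinear — become flagged rows; they
never abort a scan.

## Phenotype preparation

The fixed stage order is: average duplicate SBP readings → medication
corrections → log-TG → winsorization → complete-case filter.

* **Medication corrections.** Statins lower LDL-C roughly
  multiplicatively, so measured LDL-C of statin users is divided by 0.7;
  no correction for ApoB or TG among statin users. Antihypertensive users
  get +10 mmHg added to the mean SBP. Both corrections are exactly
  invertible, and a round-trip test confirms that applying them to
  simulated treated measurements recovers the untreated values when the
  simulator uses the matching effect sizes.
* **Winsorization.** Values beyond 6 SD of the mean are set exactly to
  the 6-SD bound. Mean and SD are computed once, on the non-missing
  values, before any clipping — a single-pass rule, so re-applying the
  original bounds is an exact no-op.
* **Order choices.** Whether winsorization should precede or follow the
  corrections is genuinely open; the default corrects first, so that the
  +10 mmHg shift cannot carry a value across a clip bound computed on
  uncorrected data, and `winsorize_after_correction = FALSE` flips the
  order. The 6-SD rule is applied on the analysis scale (log for TG),
  again configurable in principle by transforming first or not.

Age groups are $[40,50)$, $[50,60)$ and $[60,70]$; the closed top edge
gives age exactly 70 a defined home.

## Multiple testing and lead selection

The genome-wide interaction threshold is $5\times10^{-8}$ Bonferroni-split
across the five traits: $10^{-8}$ per trait. Lead variants are selected by
greedy LD clumping: sort by ascending p (ties: larger $|\beta|$, then
position), take the best remaining row as a lead, absorb every remaining
row with $r^2 \ge 0.1$ into its clump; only rows below the significance
threshold seed clumps. All retained leads are therefore mutually below
$r^2 = 0.1$, an invariant asserted on every run (`max_lead_r2()`), and the
greedy output is verified in tests against an exhaustive pairwise-
constraint oracle. LD is computed in-sample as the squared Pearson
correlation of dosage vectors; a precomputed reference-panel matrix can be
substituted. No physical-distance window limits clump membership by
default. Genes are mapped positionally within an inclusive 10 kb of the
variant position, with BED input converted to 1-based inclusive
coordinates at the boundary.

**Look-up stage.** Strict genome-wide interaction testing is
under-powered for weak interactions, so the second route starts from the
marginal GWAS: clump marginal hits at $5\times10^{-8}$, then test each
marginal lead's interaction term at $0.05/m_t$ where $m_t$ is that
trait's number of marginal leads. Thresholds are monotone decreasing in
$m_t$ by construction.

## Stratified estimation

Within each age group, trait is regressed on genotype-category indicators
(heterozygote and effect-allele homozygote against the non-effect
homozygote), adjusting for sex and PCs — age is not a covariate within a
bin. Under additivity the homozygote contrast is twice the heterozygote
contrast, a tested consequence. With $\beta_G > 0$ and
$\beta_{G\times age} < 0$ the per-bin contrast
$\beta_G + \beta_{G\times age}(\bar a_b - c)$ decreases strictly across
bins — the attenuation signature the stratified view is designed to show.
For log-scale traits the exponentiated contrast is reported as a
fold-change with Wald CI (normal quantile), rendered to two decimals.
Dosages are rounded to hard calls for categorical coding (ties at 0.5
round up; counts logged).

## The synthetic cohort generator

The generator emulates a middle-aged population cohort: ages uniform on
40–70, 54.2% women, genotypes in Hardy–Weinberg proportions at the
specified allele frequency, optional LD via a first-order Gaussian-copula
chain per haplotype (marginal frequencies preserved exactly; adjacent
$r^2$ rises monotonically with $\rho$ — the simplest structure with a
tunable, checkable decay), linear age and sex effects per trait, genetic
effects $\beta_G + \beta_{G\times age}(a - c)$ per causal variant, TG
generated on the log scale and exponentiated, ten standard-normal PC
columns with optional small trait effects, and Gaussian noise. Trait
levels and dispersions default to values typical of published
middle-aged cohort baseline tables (e.g. LDL-C 3.6 ± 0.85 mmol/L, SBP
138 ± 18 mmHg, log-TG SD ≈ 0.53 back-computed from a TG IQR of about
1.05–2.14 mmol/L via IQR/1.349); age slopes are chosen to reproduce the
gentle rise of these traits across the 40–70 range.

Medication is assigned by a logistic model in age and the untreated trait
value, calibrated so statin use climbs from roughly 4% in the forties to
roughly 28% in the sixties (antihypertensives ~6% to ~32%) — the steep
age gradient that makes the corrections consequential — and then masks
the measurement: measured LDL-C is the untreated value × 0.7 for statin
users, measured SBP is untreated − 10 mmHg for treated individuals. The
joint distribution of treatment and phenotype in real cohorts is not
publicly documented beyond such margins; the logistic form is a stand-in,
not an estimate.

The age-centring constant $c$ of the genetic effects defaults to 0
(effects defined at age 0), with `age_center = "mean"` available;
$\beta_{G\times age}$ is invariant to this choice and $c$ is recorded in
the truth table so recovery tests are well-posed.

**What the generator does not emulate:** realistic human LD maps,
relatedness, genuine population structure (PCs are synthetic covariates,
not eigenvectors of the genotypes), imputation uncertainty beyond a
simple beta-jitter dosage option, non-Gaussian trait tails, and
informative missingness. Passing tests therefore demonstrate the
statistical machinery is correct under its stated model, not that real
biobank data meet that model.

## Numerical and design choices

* OLS via Householder QR with pivoting; rank deficiency is an error
  naming the offending column, monomorphic dosage vectors are rejected
  before fitting.
* Missing dosages are mean-imputed per variant by default (standard for
  imputed genotype data), `na_action = "drop"` available; missing trait
  or covariate rows are dropped per trait.
* The MAF filter removes variants with MAF strictly below 0.001; a
  variant at exactly 0.001 is kept. The boundary convention is printed in
  output headers because scan tools differ here.
* Exactly $r^2 = 0.1$ counts as linked during clumping (the retained-lead
  set satisfies $r^2 < 0.1$ strictly); exactly 10 kb counts as mapped.
* Quantiles (medians, IQRs) use linear interpolation between order
  statistics (R type 7), stated so the descriptive tables are exactly
  reproducible.
* Seeds are mandatory for every stochastic stage; a missing seed is an
  error, never a silent default. The genotype and phenotype streams use
  offset seeds so one genotype draw can carry replicate phenotypes.

## Problem sizes in the validation suite

The test and acceptance workloads run at desk scale, chosen to make each
statistical property measurable with comfortable margins: oracle
equivalence on 100 variants × 500 samples; type-I error on 5,000 null
variants at n = 2,000 (binomial SE ≈ 0.3% around the nominal 5%);
CI-coverage and bias recovery over 200 replicates at n = 20,000 with
interaction magnitudes up to 0.002 per allele per year; clumping oracle
checks on 200-variant LD blocks at n = 5,000 across three seeds; full
pipeline determinism on a 1,500-individual cohort. The streaming
structure extends to larger panels; genome-scale throughput engineering
is out of scope.

## Known limitations

Continuous-trait OLS only (no GLMs for binary outcomes, no mixed models
or relatedness correction); in-sample LD rather than an external
reference panel by default; positional gene mapping only (no functional
annotation); no dose- or class-specific medication corrections; the
simulator's medication model is a plausible stand-in rather than a
calibrated estimate.
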