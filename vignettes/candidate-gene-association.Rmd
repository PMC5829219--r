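---
title: "Methods: candidate-gene case-control association and genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene case-control association and genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candgene)
```

## Scope and scientific setting

`candgene` re-implements, as a reusable and tested pipeline, the analysis
of a candidate-gene resequencing case-control study of non-alcoholic
fatty liver disease (NAFLD): post-caller variant quality control,
consensus deleteriousness scoring, per-gene carrier-burden enrichment,
per-SNP association under genotypic/dominant/recessive penetrance
models, covariate-adjusted logistic modelling with forward-Wald
selection and bootstrap adjustment, a weighted 4-SNP genetic risk score
(GRS), and an analytic power calculator for one-stage genetic
association designs. The study design it mirrors compares 218
ultrasound-defined NAFLD cases with 227 healthy controls at four index
SNPs — PNPLA3 rs738409 (risk allele G), TM6SF2 rs58542926 (T), GCKR
rs1260326 (T) and MBOAT7 rs641738 (T) — with metabolic covariates (age,
sex, BMI, HOMA-IR, triglycerides) and a Hamaguchi steatosis grade
(0–6) per case.

Because individual-level data of such studies are typically not
released, the package ships a synthetic cohort generator with the
statistical structure the analysis assumes; everything downstream is
exercised both on published genotype counts (which are sufficient
statistics for the unadjusted contingency analyses) and on synthetic
cohorts (for the adjusted, regression-level machinery).

## The statistical model

**Contingency layer.** Genotype counts per group are arranged as
`(aa, aA, AA)` with `A` the risk allele. A penetrance model collapses
the 2×3 table to 2×2: dominant (exposed = aA + AA) or recessive
(exposed = AA). Association is tested with the *uncorrected* Pearson
chi-square — no Yates continuity correction anywhere, because the
uncorrected statistic reproduces every published check value (6.39,
11.2, 4.693, 3.487, 14.6, 11.7) while the corrected one does not. Odds
ratios use the Woolf log-interval,
$\exp(\ln \widehat{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$,
which reproduces the published intervals; a zero cell triggers the
Haldane–Anscombe 0.5 correction and the comparison is flagged
non-estimable (the way published tables print a dash). Hardy–Weinberg
equilibrium is tested per group with a 1-df chi-square against expected
counts at the sample allele frequency.

**Regression layer.** Case status is modelled by maximum-likelihood
logistic regression (IRLS, log-likelihood tolerance 1e-8, at most 100
iterations), with right-skewed covariates (HOMA-IR, triglycerides)
entering on the log scale. Forward-Wald selection adds, at each step,
the candidate with the smallest score-test (Rao) p-value below the
entry threshold (default 0.05) and removes entered terms whose Wald
p-value exceeds the removal threshold (default 0.10) — the defaults of
the statistical software tradition this procedure comes from, both
configurable. Model adequacy is summarized by the Hosmer–Lemeshow
deciles-of-risk test (default 10 groups, df = groups − 2, sparse groups
merged and flagged) and Nagelkerke's
$R^2 = R^2_{CS} / (1 - e^{2\,\ell_0/n})$ with
$R^2_{CS} = 1 - e^{2(\ell_0 - \ell_1)/n}$. Multiple-comparison
adjustment of regression p-values uses a subject-level bootstrap
(default B = 1000): percentile confidence intervals, and a two-sided
p-value from the position of zero in the bootstrap coefficient
distribution with add-one smoothing. Which exact bootstrap p variant
the original analysis used is not stated; the percentile form is
implemented and labelled as such. Runs with more than 10% of
non-convergent replicates abort. Gene–covariate interactions are Wald
tests on a product term fitted alongside both main effects; an aliased
design (e.g. a binary term interacted with itself) is an error rather
than a silent drop.

**Carrier burden.** Per gene, subjects carrying at least one
functional variant are compared between groups by the same 2×2
chi-square/Woolf machinery. When several genes are tested the pipeline
reports Bonferroni-adjusted p-values; the original analysis reports
that significance was lost "after correction" without naming a method,
so Bonferroni over the tested genes is our documented interpretation
(configurable in principle by adjusting the returned raw p-values
differently).

**GRS.** The unweighted score is the plain risk-allele count (0–8 over
4 SNPs in theory; the study observed a maximum of 7 because only two
TM6SF2 homozygotes existed, and none among cases). The weighted score
is $\sum_i \beta_i d_i$ with external per-allele weights
(0.2653, 0.2711, 0.0649, 0.0575 for PNPLA3, TM6SF2, GCKR, MBOAT7 —
Dallas Heart Study effect sizes, treated as fixed inputs). Tertile
boundaries default to the published cut points (T1 ≤ 0.1775 <
T2 ≤ 0.3877 < T3); the source legend prints both 0.3877 and 0.3887 for
the upper boundary — 0.3877 is adopted because it appears in the
interval definition, and any boundaries can be passed explicitly.
Whether the original boundaries were computed on the whole cohort or
controls only is not stated; `recompute_tertile_boundaries()` uses the
supplied score vector, so either convention is available. Subjects
missing any panel genotype are excluded from GRS analyses (no
imputation), with a logged count.

**Power.** The analytic calculator solves the baseline penetrance
$f_0$ from the prevalence constraint $K = \sum_g P(g)\,f_g$ under HWE
genotype probabilities and genotype relative risks $(1, r, 2r{-}1)$
(additive) or $(1, r, r^2)$ (multiplicative), derives case/control
genotype distributions by Bayes ascertainment,
$P(g \mid \text{case}) = P(g) f_g / K$, and computes the
normal-approximation power of the two-sided 1-df allelic (2N-allele)
two-proportion comparison, pooled variance under the null and unpooled
under the alternative. This is the computation family of the
GAS/CaTS-style calculators and reproduces the published design values:
87% at (K = 0.30, p = 0.03, r = 2.0, 218/227, α = 0.05) and ~100% at
p = 0.30. "OR ≈ 2.0" in the design statement is treated as r = 2.0 on
the relative-risk scale. A Cochran–Armitage trend variant is available
for the Monte-Carlo check, and `min_detectable_rr()` inverts the power
function; the inverse solutions at 80% power are 1.90 (low-frequency)
and 1.35 (common) after rounding.

## The synthetic cohort generator

`simulate_cohort()` draws subjects from a source population and samples
retrospectively (rejection sampling) until the case/control quotas are
met, aborting after 1000 × (n_cases + n_controls) draws if the
prevalence makes the quotas unreachable.

* **Genotypes** are drawn per SNP under HWE at the specified risk-allele
  frequency. The four panel SNPs are kept independent: the only joint
  statement available from the source cohort (55% of GCKR TT carriers
  also carry PNPLA3 G) does not identify a correlation strength, so no
  LD structure is fabricated.
* **Disease** follows a logistic model whose log-odds are
  `logit(prevalence)` plus additive per-allele log-OR terms and centred
  covariate terms, the conventional generative counterpart of the
  logistic analyses applied downstream (the source analysis never states
  its generative model).
* **Covariates**: age ~ Normal(52, 10), BMI ~ Normal(27, 3.5), fasting
  glucose, insulin and triglycerides log-normal with medians between the
  reported case and control medians (88 mg/dL, 8 U/L, 105 mg/dL);
  HOMA-IR is derived exactly as glucose × insulin / 405. Skewed
  covariates act on the log scale with effects 0.90 (log HOMA-IR) and
  0.70 (log TG); age 0.03/yr, male sex 0.30, BMI 0.15/kg·m⁻² — moderate
  values producing case–control covariate contrasts of the direction
  and rough magnitude seen in metabolic cohorts.
* **Severity**: cases receive Hamaguchi grades 1–6 with 76.3% at grade
  ≥ 3 and 32.6% severe (grade 5–6), matching the reported composition;
  controls are grade 0.
* **Defaults**: frequencies 0.335 / 0.07 / 0.42 / 0.41 and per-allele
  ORs 1.6 / 2.5 / 1.4 / 1.25 for rs738409 / rs58542926 / rs1260326 /
  rs641738, prevalence 0.30. These are the study conditions; tests do
  not move them.

One integer seed drives a single pseudo-random stream; identical specs
and seeds give byte-identical subject tables.

What the generator deliberately does **not** emulate: raw reads or
sequencing error (QC metrics in `simulate_vcf()` fixtures are drawn
directly, not derived from alignments), linkage disequilibrium,
covariate–covariate correlation beyond what the shared disease model
induces, measurement error in ultrasound grading, and population
structure. Passing tests therefore demonstrate the *statistical
machinery* is correct under the assumed model — not that the model
captures every feature of real cohorts.

```{r generator-example, eval = FALSE}
spec <- cohort_spec(n_cases = 218, n_controls = 227, seed = 1)
subjects <- simulate_cohort(spec)
report <- run_study(run_config(subjects, seed = 1))
report$association
```

## Variant QC and consensus scoring

The post-caller filter keeps a call iff depth DP ≥ 30, genotype quality
GQ ≥ 30, alternate allele fraction (percent scale, as callers in this
tradition report it) inside the heterozygous window [33, 50] or the
homozygous window [70, 100], and the strand support is balanced. All
thresholds are inclusive exactly as printed. "Balanced" strand support
is not defined by the source; the default requires the rarer strand to
carry at least 20% of the alternate observations
(`strand_balance_min = 0.2`, a config knob), and a call with positive
allele fraction but no recorded alternate observations on either strand
fails the strand rule. Rejected records list their failed rules in
stable DP, GQ, AF, STRAND order, and filtering is idempotent on the
kept set. Population MAF classes partition [0, 0.5]: rare (< 0.01),
low-frequency ([0.01, 0.05)), common (≥ 0.05). "Functional" status
rests on the annotation class alone (nonsense, frameshift,
splice-region, missense), taken from the input annotation field — no
recomputation from gene models.

The consensus scorer aggregates the categorical verdicts of five
deleteriousness predictors (SIFT, PolyPhen-2, PROVEAN, SNPs&GO,
MutationTaster roles): 0 for neutral, 1 for possibly damaging (a
PolyPhen-2 category; rejected for the other tools), 2 for damaging,
summed to a 0–10 collective score; a variant is *damaging* when at
least three of five tools give a full damaging verdict. The
intermediate possibly-damaging category does not count towards that
consensus — it has its own intermediate code in the scoring map, so
counting it as deleterious would double-define it. Consequently a
damaging consensus implies a collective score of at least 6 (an
invariant the tests enumerate exhaustively over all 48 admissible
verdict combinations). The aggregator is exposed but deliberately not
wired into the burden test, whose "functional" definition is
annotation-based.

## Numerical choices and degenerate inputs

* No continuity correction in any chi-square (see above);
  `pearson_chi2()` errors on a zero margin. `snp_association()` handles
  the degenerate cases cohorts actually produce: a genotype column empty
  in both groups is dropped (df adjusts); a recessive collapse with no
  homozygotes anywhere is returned non-estimable rather than as an
  error, so a pipeline run over many SNPs does not die on a rare allele.
* Woolf intervals use z = 1.96; zero cells get the 0.5 correction and a
  non-estimable flag.
* Logistic fits flag separation (boundary fitted values together with an
  exploding standard error) as non-convergence with a warning, never
  silent output; aliased designs are errors.
* Hosmer–Lemeshow merges groups produced by tied fitted values and
  reports df < 1 as non-informative instead of fabricating a p-value.
* Tertile intervals are closed on the right of each boundary
  (T1 includes 0.1775; T2 includes 0.3877), matching the published
  interval definition.
* Missing genotypes: complete-case per SNP in contingency analyses (group
  totals may differ per SNP) and complete-case across the panel for the
  GRS.
* Bootstrap p-values use add-one smoothing, so they are never exactly 0
  and are conservative at small B.

## Problem sizes used by the test suite

The suite validates calibration claims at sizes chosen to make
Monte-Carlo bands meaningful while keeping a default test run fast:
type-I error of the collapse → chi-square pipeline on 1,000 null
cohorts of 218/227 (band 0.05 ± 0.015); coefficient recovery on a
single 3,000/3,000 cohort at published effect sizes (each term within
2 SE); empirical-vs-analytic power at 1,000 replicates for the two
published designs and at 400 replicates across a 3×3
(frequency × relative risk) grid; bootstrap calibration over 30 null
datasets at B = 120. The analytic power value is a normal
approximation: its exact-test counterpart at the low-frequency design
is about 2 points higher (0.89 vs 0.87 at large replicate counts),
which is the known accuracy of this approximation family at low allele
frequencies — the Monte-Carlo checks size their replicate counts so the
comparison tests the implementation, not that approximation's last
percentage point.

## Known limitations

* Covariate-adjusted odds ratios of the source study (its Tables 3/4,
  adjusted GRS tertile ORs, median GRS values) are not reproducible
  without the unreleased individual-level data; the package validates
  that layer by parameter recovery and calibration on synthetic cohorts
  instead.
* The generator's logistic disease model and the power module's
  relative-risk penetrance model are different parameterizations; the
  power module's Monte-Carlo oracle therefore samples from the
  ascertained genotype distributions of its own penetrance model, and
  per-allele "OR ≈ 2" design statements are interpreted on the RR scale
  there, as calculator tradition does.
* The secondary Sanger-retest rule of the source pipeline (dropping
  calls with AF < 33 *and* DP < 20 among moderate-quality variants) is
  subsumed by the primary filter here; only the primary filter is
  implemented.
* The consensus scorer consumes categorical verdicts; it does not run
  any predictor.
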