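---
title: "Extreme-phenotype modifier-gene discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme-phenotype modifier-gene discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modifierscan)
```

## The problem

Ultra-rare Mendelian diseases often show striking phenotypic variability
between patients carrying identical causal mutations — even between
siblings. One explanation is modifier genes: common or rare variation
elsewhere in the genome that alters disease severity without causing the
disease. In a recessive tubulopathy such as familial hypomagnesemia with
hypercalciuria and nephrocalcinosis (FHHNC), the clinically decisive trait
is the speed of progression to kidney failure, quantified as the annual
decline of the estimated glomerular filtration rate (eGFR,
mL/min/1.73m²/yr).

With cohorts of a few dozen patients, a genome-wide association scan is
hopeless. The design implemented here boosts power in two ways:

1. **Extreme-phenotype sampling.** Patients are stratified at the tails of
   the progression trait (FAST: decline ≥ 10 mL/min/1.73m²/yr; noFAST:
   everyone else), and the gene scan contrasts the extremes.
2. **Gene-level rare-variant tests plus knowledge-driven prioritization.**
   Variants are aggregated per gene with SKAT-O, and the resulting
   candidates are filtered through kidney-expression evidence and
   GWAS-catalog trait matches before per-variant risk assessment.

`modifierscan` implements the full pipeline — stratification, variant
filtering, SKAT-O, prioritization, Fisher/odds-ratio risk analysis,
overrepresentation analysis — together with a synthetic-cohort generator
with planted modifier effects, so every stage is testable without access
to patient data.

## Phenotype stratification

Each patient's eGFR series is summarized by its ordinary least-squares
slope against time in years. Classification uses the annual *decline*
(`-slope`):

* decline ≥ `fast_cutoff` (default 10) → **fast** → group FAST;
* `stable_epsilon` < decline < 10 → **moderate** → noFAST;
* decline ≤ `stable_epsilon` → **slow** (stable renal function) → noFAST.

`stable_epsilon` defaults to 1 mL/min/1.73m²/yr. The boundary between
"no decline" and slight decline has no canonical value; 1 unit/yr is well
below measurement noise in clinical eGFR series, and the choice cannot
move a patient across the FAST/noFAST boundary, which is the only split
the downstream statistics use.

Patients with a single eGFR measurement cannot be regressed. Rather than
imputing a slope, they are classified only through an explicit override
table (`class_overrides.tsv`), mirroring how a clinician would assign a
class from the last follow-up value; without an override they are excluded
with a warning.

## Variant input and filtering

The pipeline consumes a snpEff-annotated multi-sample VCF (`ANN` INFO
field, `GT:DP` FORMAT). Multi-allelic records are split into biallelic
ones, `./.` becomes missing (never zero), and each record keeps the first
`ANN` entry matching its alternate allele. Filtering retains variants of
predicted impact MODERATE or HIGH with depth ≥ 10 reads in at least one
sample — the coverage convention uses `FORMAT/DP`; whether the original
analysis counted total or allele-supporting reads is not documented, and
`DP` is the conservative, always-available choice. An explicit effect-term
list (missense, splice region/donor/acceptor, stop-loss, stop-gain) can be
enforced as a cross-check.

## The gene-level test

For gene $g$ with dosage columns $g_j$, weights $w_j$ and null-model
residuals $r = y - \hat\mu$ (intercept-only logistic fit by default):

$$Q_\rho = (1-\rho)\sum_j w_j^2 (g_j^\top r)^2 + \rho\Big(\sum_j w_j g_j^\top r\Big)^2,$$

which interpolates between the SKAT variance-component statistic
($\rho = 0$) and the squared burden score ($\rho = 1$). Each $Q_\rho$ is
a quadratic form whose null distribution is a weighted mixture of
$\chi^2_1$ variables with weights given by the eigenvalues of the
$\rho$-specific projected kernel. The unified SKAT-O p-value for
$T = \min_\rho p_\rho$ is obtained by decomposing the statistic into the
common burden direction (a $\chi^2_1$ variable) plus an orthogonal
mixture, and integrating the conditional rejection probability over the
burden variable.

Defaults, all configurable through `skato_config()`:

* **Weights** `dbeta(MAF, 1, 25)` at the sample MAF — the standard
  rare-variant upweighting. The original tooling's weights are not
  documented, so this is a declared assumption.
* **ρ grid** `{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}` — the standard
  8-point grid.
* **Missing dosages** are mean-imputed per variant before testing, which
  keeps kernels well-defined without dropping samples.
* **Untestable genes** (all dosages constant) are reported separately,
  never assigned a p-value.

### Numerical choices

* Per-ρ tail probabilities invert the characteristic function numerically
  (Imhof-type integration, vectorized, relative tolerance 1e-8); the Liu
  moment-matching approximation is the recorded fallback when inversion
  fails or leaves [0, 1].
* Eigenvalues below `1e-10 × max` are truncated to zero.
* Inside the one-dimensional min-p integration, the conditional CDF and
  the per-ρ quantiles use a saddlepoint approximation (Liu-seeded); a pure
  inversion there would cost two orders of magnitude more for no material
  accuracy gain, and the final value is clamped to
  $[T, \min(1, K\,T)]$ (the min-p lower bound and the Bonferroni upper
  bound over the $K$ grid points).
* $\rho = 1$ is handled as $1 - 10^{-4}$ inside the integration, where
  the burden constraint becomes a hard cutoff on the conditioning
  variable.

### Small cohorts: analytic vs permutation

With ~30 samples and a 6/24 split, the binary score vector is visibly
non-Gaussian, and *any* analytic p-value based on the asymptotic score
distribution can differ from the exact label-permutation null by a few
hundredths. Internal validation shows the implemented integration agrees
with brute-force simulation of its own Gaussian score model to about 0.01
at moderate p, while the Gaussian model itself sits 0.01–0.05 from the
permutation distribution at these sizes — and for very discrete
configurations (few cases, rare variants) the gap can reach ~0.25. For that reason
`skato_config(method = "permutation")` — an exact min-p permutation test,
vectorized over permutations — is the reference method at cohort scale and
is what the calibration and power simulations use. The analytic method
remains the right tool for ranking and for larger cohorts.

## Prioritization cascade

Gene-scan candidates pass through, in order: (1) raw p < 0.01 ("round 1"
significance; the scan's BH-adjusted values are reported but not used as
the gate, since at this cohort size nothing survives genome-wide
correction); (2) kidney expression with both RNA and protein evidence;
(3) a GWAS-catalog match: any catalog association mapping to the gene, at
association p < 1e-6, with a trait in the curated disease-trait list. A
second round repeats (3) without the expression filter, and an explicit
include list (the claudin family, reflecting the disease's tight-junction
biology) admits significant genes regardless of expression or trait
evidence. Matching joins on mapped-gene symbols case-insensitively — the
only key the scan results and catalog share — rather than on coordinates.
All annotation inputs are static files, never live database queries, so
runs are reproducible.

## Per-variant risk analysis

Within prioritized genes, every variant is tested in two genotype
contrasts: hom-alt vs hom-ref, and het vs hom-ref (the third genotype's
carriers are excluded from the 2×2 in each mode). The two-sided Fisher
exact p sums hypergeometric probabilities of tables at most as likely as
the observed one (the `fisher.test` convention; the analysis this
reproduces used the same function, and sidedness was not otherwise
documented). Odds ratios use the Haldane–Anscombe correction — 0.5 added
to every cell — **only** when some cell is zero; applying it always would
bias nonzero-cell estimates away from the classical value (a configurable
choice). The risk allele is ALT when OR > 1 and REF when OR < 1, tying
each variant to the phenotype group its carrier genotype is enriched in.

Both modes are pooled into a single BH family by default (the original
family definition is not documented; pooling is the conservative reading),
and selection keeps p < 0.05, q < 0.15, OR ≠ 1. Genotype-distribution
comparisons across groups (e.g. FAST vs noFAST vs a reference population)
use the exact r×c Fisher test, switching to Monte-Carlo sampling (1e5
tables, with reported standard error) when full enumeration is infeasible.
Counts printed only as percentages are reconstructed by largest-remainder
apportionment, which guarantees exact totals; such reconstructions are
treated as derived fixtures, not ground truth, since printed percentages
round inconsistently.

The per-patient risk-allele burden counts, for each patient, the selected
variants whose risk genotype they carry (dosage 2 for ALT-risk
homozygous tests, dosage 0 for REF-risk ones, dosage 1 for het-mode
tests), summarized per group as min, max and the fraction inside a query
interval.

## Overrepresentation analysis

Candidate genes are tested against GMT gene-set collections with the
upper-tail hypergeometric test over a declared background universe, BH
adjustment across sets, and a reporting cutoff of adjusted p < 0.25. The
gene-ratio column is overlap / term size — the stated definition in the
analysis this package reproduces — though some ecosystems use
overlap / query size instead. A term contains exactly its listed genes; no
ontology-graph propagation is performed.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 6 FAST vs 24 noFAST
patients by default, Hardy–Weinberg genotypes per variant, and a logistic
phenotype model
$P(\mathrm{FAST} \mid \text{dosages}) = \mathrm{logit}^{-1}(\beta_0 + \sum_v \beta_v d_v)$,
with per-genotype penetrance available for non-additive (e.g. recessive)
modifiers — both additive and recessive patterns occur among reported
modifier variants. Group quotas are filled by case-control rejection
sampling from the joint model, so planted odds ratios carry over to the
sampled cohort. eGFR trajectories are drawn per class (fast slopes
truncated to decline ≥ 10, slow to ≤ 1), with Gaussian measurement noise
(default sd 5) over a 5-year follow-up of 4–8 visits and eGFR floored at
1.

Deliberate simplifications, hence what passing tests do *not* show about
real data: variants are drawn independently (no linkage disequilibrium —
the per-gene and per-variant tests do not model LD, and independence makes
the simulation oracles exact); there is no population structure or
relatedness, although real cohorts contain sibling pairs whose
exchangeability violation no stage corrects for; and the MAF spectrum
(0.5 × Beta(1, 5), truncated to [0.01, 0.5] by default) is an assumption,
as the source analysis reports no site-frequency spectrum. Sequencing is
not simulated at read level; depths are negative-binomial draws around the
reported exome coverage.

## Simulation sizes used in the checks

The shipped verification suites use: 1,000 null genes and 1,000 null
variants (n = 30, 6/24 split) for type-I-error calibration with the
permutation method (2,000 permutations); 100 replicates of a planted
recessive modifier with genotype counts 5/1/0 (FAST hom-alt/hom-ref/het)
vs 0/11/13 (noFAST) for recovery; and 20 random instances (n ≤ 50, ≤ 6
variants) for analytic-vs-permutation comparison at 1e5 permutations.
The acceptance script scales the recovery run to 40 replicates.

## Known limitations

* No covariate-rich or mixed-model null (kinship, population structure).
* X-chromosome dosages are treated like autosomal ones.
* The analytic SKAT-O p is asymptotic; at n ≈ 30 use the permutation
  method for calibrated inference.
* The prioritization cascade inherits whatever ascertainment biases its
  annotation tables carry; enrichment results on prioritized genes are
  functional annotation, not independent evidence.
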