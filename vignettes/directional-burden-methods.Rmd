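---
title: "Function-informed rare-variant collapsing: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-informed rare-variant collapsing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulaburden)
```

## The problem

Rare regulatory variants do not behave like rare coding loss-of-function
alleles. A promoter variant may raise transcription, lower it, or do
nothing, so when a region is resequenced in the two tails of a continuous
trait distribution, functional variants of opposite direction accumulate in
*opposite* tails and cancel in a conventional collapsing test. The package
implements the remedy this design calls for: measure each variant's
direction of effect in a reporter assay, then collapse *within* direction.

The concrete setting is an extreme-phenotype resequencing study of a
lipase promoter and 5' UTR (1755 bp upstream of the TSS plus 252 bp of
transcribed UTR) in 195 individuals above the trait's 95th percentile
(HHDL) and 193 below the 25th percentile (LHDL, floored at 20 mg/dL to
exclude likely monogenic disorders). Higher enzyme (EL) activity lowers the
trait (HDL-C), so expression-lowering variants are expected in the high
tail and expression-raising variants in the low tail.

## The collapsing tests

For a chosen variant subset V, an individual is a **carrier** if they
carry at least one variant of V (an individual with several qualifying
variants counts once). Carrier counts per cohort form a 2x2 table tested
with Fisher's exact test.

- **CAST** (`cast()`): V = all rare variants (MAF < 1%), regardless of
  function.
- **Directional CAST** (`directional_cast()`): V = rare variants whose
  reporter call is `decrease` (tested against enrichment in the high
  cohort) or `increase` (low cohort). Variants called `null` are
  discounted entirely; their carriers count as non-carriers. An individual
  carrying variants of both directions contributes to both tests — this is
  forced by the published counts, where the dual carrier of a
  decrease variant and an increase variant appears in both strata.
- **Exclusivity filter** (`exclusive = TRUE`): additionally drops variants
  with carriers in both cohorts, enriching for variants private to one
  extreme.

`fisher_exact()` is implemented in the package rather than delegated,
because the two-sided convention is load-bearing: the published p-values
(0.2142, 0.0301, 0.0364, 0.0301, 0.0297) reproduce under the
*minimum-likelihood* definition — sum the hypergeometric point
probabilities of every table (with fixed margins) whose probability does
not exceed the observed one, with a relative tie tolerance of 1e-7. The
implementation is checked against exhaustive enumeration for every 2x2
table with N <= 60 to 1e-12, and against `stats::fisher.test`.

**Sidedness.** The source's methods text mentions one-tailed tests for the
directional comparisons, but its table footnotes say two-tailed and the
printed values match only the two-tailed convention. The package defaults
to two-sided everywhere; one-sided is available via `alternative`.

**MAF.** Allele-based, (2·hom + het)/(2N), which reproduces the printed
common-variant frequencies exactly (e.g. 146/390 = 0.374 -> 0.37). The
source's rare-variant footnote describes a carrier-based fraction instead;
both conventions classify all 17 rare variants as rare, so the choice is
consequence-free here, and the allele-based form is the field standard.

## Reporter assay normalization and direction calling

Each well's firefly reading is divided by its Renilla co-transfection
control, and well ratios are scaled by the mean wild-type ratio *of the
same plate*, so the WT construct has mean relative activity exactly 1 and
the normalization is invariant to any plate-wide multiplicative factor.
Direction calls use a two-sided pooled-variance Student's t-test at
alpha = 0.05 per variant, with no multiple-testing correction — each
variant is a separate, pre-specified hypothesis in this design (and the
published analysis used per-variant alpha). Welch's test is available
behind `var_equal = FALSE`.

Replicate experiments ("each construct evaluated at least three times")
have no published aggregation rule; the package requires the per-plate
calls to agree and returns `null` with a warning when they disagree. This
is deliberately conservative: an inconsistent functional call should not
move a variant into a directional stratum.

## LD estimation

Two-locus haplotype frequencies are estimated from unphased genotypes by
EM. Only the double heterozygote is phase-ambiguous; its count is split
between the cis (AB/ab) and trans (Ab/aB) configurations in proportion to
their current likelihood at each E-step. Initialization is at linkage
equilibrium (deterministic), convergence is declared when the largest
frequency change drops below 1e-10, and the log-likelihood is
non-decreasing across iterations (testable via `trace = TRUE`). From the
fitted frequencies, D = pAB − pA·pB, r² = D²/(pA qA pB qB), and
D' = |D|/Dmax with the direction-dependent Dmax. Monomorphic loci return
D = 0 with r² flagged undefined rather than a number.

The EM is property-tested against a refining grid search over the
haplotype-frequency simplex (final resolution 1.6e-5) on random genotype
tables with n <= 50, agreeing to 1e-4 in every frequency. Genotype tables
consisting *only* of double heterozygotes put the likelihood on a ridge
(any split with the same cis/trans product mix is optimal); the test
generator excludes that degenerate case, and users will essentially never
see it with real data.

## Quantitative-trait association

`residualize_standardize()` performs per-stratum (typically per-gender)
OLS residualization of the trait on covariates, rescaled to mean 0, SD 1,
so downstream effects are in trait-SD units — the convention of the cohort
analysis this emulates. `additive_regression()` regresses the (optionally
log-transformed) trait on minor-allele dosage; plasma enzyme
concentrations are lognormal, hence the log default for that trait.
Individual-level cohort data for the published association tables are not
available, so this module's correctness is established by property tests
(affine equivariance, exact standardization) and parameter recovery
(a 0.08 log-scale allelic effect at n = 760 is recovered to within 0.01 in
the mean over 500 replicates), not by reproducing printed estimates.
The published association estimates are treated as context only.

## The synthetic-data generator as a stated world

`sim_config()` encodes the generative model:

- `log EL_i = log(el_base) + el_coupling * Σ_v log(activity_v) g_iv + η_i`,
  `η ~ N(0, el_sdlog)`; EL is lognormal, matching the log-transform used
  for the real enzyme measurements.
- `HDL_i = hdl_mean − hdl_coupling · z(EL_i) + ε_i`, `ε ~ N(0, noise_sd)`;
  the trait responds linearly to standardized enzyme level, with Gaussian
  residual noise.
- Cohorts are drawn from the >= 95th and <= 25th trait percentiles
  (low cohort floored at 20), sizes 195/193, from a population of 10,000.

Defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_rare_variants` | 17 | the study's rare-variant count |
| `direction_mix` | 4:8:5 decrease:null:increase | the study's functional-call split |
| `carrier_freq_range` | 0.001–0.004 | reproduces the observed scale of ~25 carriers among 388 sampled extremes |
| `effect_decrease` / `effect_increase` | 0.5 / 1.5 | typical magnitude of the significant reporter effects |
| `el_base`, `el_sdlog` | 500 ng/mL, 0.65 | matches the published enzyme mean ~500 and CV ~0.7 |
| `hdl_mean`, `hdl_coupling`, `noise_sd` | 55, 15, 8 mg/dL | population HDL ~55±17; coupling strong enough that functional carriers segregate nearly completely to one tail, as the observed 6-vs-0 carrier split implies |
| `assay_replicates`, `assay_cv` | 6, 0.1 | six wells per construct as published; 10% well CV is typical for dual-luciferase |
| `ld_pair` | MAFs 0.278/0.279, r² 0.8 | the two genotyped coding/UTR loci and their published LD |

These values were fixed from the study's printed dimensions before any
test was run and are not tuned to outcomes. What a green simulation test
establishes is that the *model above* behaves as claimed; real data add
population structure, relatedness, genotyping error, tissue-dependent
expression effects and assay batch structure, none of which the generator
emulates (deliberately: the analysis under test assumes none of them).

The **null configuration** for calibration keeps the assay directions but
sets `el_coupling = 0`, so variants are "functional" in vitro yet have no
trait coupling — the sharpest null for the directional tests.

## Type-I error of exact tests on sparse tables (a red criterion)

One stated acceptance criterion asks every burden test's null rejection
rate to fall inside the two-sided 95% binomial interval around
alpha = 0.05 ([0.037, 0.064] at 1000 replicates). The permutation-based
comparators meet it (weighted-sum 0.044, C-alpha 0.046). The Fisher-based
tests cannot: with ~8 expected carriers per cohort (or ~2 for a
directional stratum) the attainable p-values are few and coarse, and an
exact test's size is bounded above by, and typically well below, its
nominal level. Measured rates: undirected CAST 0.028, decrease-directional
0.009, increase-directional 0.012. The corresponding acceptance test is
left failing by design; the implementation itself is verified against
exhaustive enumeration, so this is the well-known conservatism of exact
conditional tests, not a defect. Users comparing methods should remember
that directional CAST buys its power from information, not from spending
its full alpha.

## Power: what the directional refinement buys

Under a bidirectional-effect configuration (half the variants at activity
0.5, half at 2.0, no nulls), opposite-direction carriers cancel in the
undirected test while each directional stratum stays clean. The
acceptance-scale study (500 replicates) shows directional power strictly
above undirected power — the central methodological claim, which has no
printed value in the source and is therefore property-based. The
weighted-sum comparator re-estimates its control-frequency weights inside
every label permutation; freezing them is a tempting optimization that
demonstrably inflates type-I error (0.079 measured) because the weights
depend on the labels being permuted.

## Degenerate inputs and numerical choices

- Fisher: empty margins (no carriers anywhere, or an empty cohort) return
  p = 1 with a warning rather than an error — a degenerate collapsing
  result is a legitimate outcome of a filter, not a crash.
- Two-sided tie tolerance 1e-7 (relative) when summing equal-probability
  tables, guarding against floating-point asymmetry in symmetric tables.
- Permutation p-values are reported as (b+1)/(n+1), never 0; the seed is a
  required argument.
- EM: non-convergence within `max_iter` raises an error carrying the last
  delta and frequencies; `simulate_two_locus()` refuses an infeasible
  target r² and names the attainable maximum.
- `compute_maf` warns (not errors) above 0.5: a mislabelled minor allele
  is a data-curation smell but a well-defined computation.
- Positions are signed TSS offsets with no position 0; the sequenced-region
  bound [−1755, +252] is validated but overridable per dataset.

## Known limitations

- The carrier fixture's individual identities are synthetic; only the
  published marginal counts and the three dual-carrier pairings constrain
  them, and any assignment satisfying those constraints yields identical
  results (the collapsing tests depend on the data only through
  de-duplicated per-cohort carrier counts).
- Functional-call fixture numerics (relative activity, p) are synthetic
  placeholders; only the direction column is transcribed data, and only it
  enters the burden analysis.
- No covariate-adjusted burden regression, no SKAT, no multi-locus
  phasing, no relatedness handling.
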