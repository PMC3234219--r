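# regulaburden

Function-informed rare-variant collapsing (burden) analysis for regulatory
regions, for studies that resequence the phenotypic extremes of a
continuous trait.

## The problem and who this is for

Rare coding loss-of-function variants segregate cleanly with phenotypic
extremes, so collapsing them into a single carrier count per cohort — the
cohort allelic sums test (CAST) — works well. Rare *regulatory* variants do
not: some raise expression, some lower it, many do nothing, and variants of
opposite direction accumulate in opposite trait tails and cancel in an
undirected test. This package is for statistical geneticists analyzing
extreme-phenotype resequencing data of promoters/UTRs together with
reporter-assay functional calls. It provides:

- **Burden tests**: CAST; direction-stratified CAST (collapse only
  experimentally `decrease`- or `increase`-calling variants, discounting
  `null` calls); an exclusivity filter (drop variants carried in both
  cohorts); frequency-weighted rank-sum and C-alpha comparators with
  permutation nulls.
- **Reporter assay**: dual-luciferase plate normalization
  (firefly/Renilla, scaled to the same-plate wild-type mean) and
  per-variant direction calls by pooled-variance t-test.
- **LD**: two-locus EM haplotype-frequency estimation from unphased
  genotypes, reporting D, D′, r².
- **Association**: per-stratum trait residualization/standardization and
  additive (per-minor-allele) regression with optional log transform.
- **Synthetic studies**: a generator for extreme-phenotype cohorts with
  bidirectional regulatory variants, lognormal enzyme levels, reporter
  plates and a two-locus pair at target r², plus `power_study()` for
  power/type-I work.

## The statistic at the core

For a variant subset V, let an individual be a carrier if they carry ≥ 1
variant of V (counted once however many they carry). With a carriers among
n₁ individuals in cohort 1 and c among n₂ in cohort 2, the test is
Fisher's exact test on [a, n₁−a; c, n₂−c]: the point probability of k
carriers in cohort 1 given the margins is hypergeometric,

    P(k) = C(n1, k) C(N − n1, K − k) / C(N, K),   K = a + c,  N = n1 + n2,

and the two-sided p sums P(k) over all k with P(k) ≤ P(a) (the
minimum-likelihood convention, which reproduces the published values).
Directional CAST takes V = {rare variants with reporter call =
decrease} (or increase); the exclusive variant additionally requires all
carriers of each variant to come from a single cohort.

## Worked example

The bundled fixtures transcribe the motivating study's variant catalog
(22 regulatory variants, 17 rare), per-cohort carrier structure (16
high-tail and 9 low-tail carriers, including three dual-variant carriers)
and reporter direction calls (4 decrease, 5 increase, 8 null among the
rare variants):

```r
library(regulaburden)
report <- reproduce_lipg()
print(report, digits = 4)
#>                           test direction exclusive carriers_high carriers_low
#> 1                         CAST       any     FALSE            16            9
#> 2             directional CAST  decrease     FALSE             6            0
#> 3             directional CAST  increase     FALSE             1            7
#> 4 directional CAST (exclusive)  decrease      TRUE             6            0
#> 5 directional CAST (exclusive)  increase      TRUE             0            5
#>   n_variants_used p_value
#> 1              17 0.21425
#> 2               4 0.03006
#> 3               5 0.03645
#> 4               4 0.03006
#> 5               4 0.02966
```

Read: collapsing *all* rare variants shows nothing (16 vs 9 carriers,
p = 0.214). Restricting to expression-lowering variants puts all 6
carriers in the high-trait cohort (p = 0.030); expression-raising variants
concentrate 7-to-1 in the low cohort (p = 0.036); the exclusivity filter
sharpens the increase stratum to 0 vs 5 (p = 0.030). Direction information,
not sample size, is what turns a null result into a signal.

A synthetic study exercises every other stage, e.g. LD between a simulated
pair genotyped at MAFs 0.278/0.279 with target r² = 0.8 in 761
individuals, and an enzyme-trait association at n = 760:

```r
study <- simulate_study(sim_config(seed = 7))
s <- ld_stats(em_haplotype_freq(study$pair_table))
sprintf("r2 = %.3f, Dprime = %.3f", s$r2, s$D_prime)
#> "r2 = 0.807, Dprime = 0.919"

d <- simulate_genotype_trait(760, 0.278, -0.08, seed = 7)
additive_regression(d$genotype, d$trait, transform = "log")
#> additive regression (log scale): beta = -0.08942 (se 0.0368), p = 0.0155, n = 760
```

A command-line front end is installed under the package's `exec/`
directory (`reproduce`, `burden`, `ld`, `simulate`, `power` subcommands),
and `run_pipeline(input_dir, out_dir)` chains catalog → assay → burden
(→ ld, assoc) over a directory of TSV inputs, writing a digest manifest.

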