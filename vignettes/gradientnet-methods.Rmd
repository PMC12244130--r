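---
title: "Methods: gradient grouping, R² subgrouping and network assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient grouping, R² subgrouping and network assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(gradientnet)
```

## The model

The pipeline treats a gene's expression along the funiculus (FUN) →
chalazal seed coat (CSC) → distal seed coat (DSC) axis as a three-point
profile of relative in-vivo mRNA concentrations. Two modelling assumptions
carry all of the downstream statistics:

* **Area normalization.** With equal RNA-isolation efficiency and fixed
  section thickness, concentration ∝ signal / tissue area. FUN and CSC
  areas are taken as equal and the DSC area as `area_ratio` (default 26.8)
  times larger, so only the DSC signal is rescaled:
  `dsc_norm = dsc_raw / area_ratio`. The ratio is a measured, approximate
  constant and therefore configurable; the default reproduces the source
  analysis. Normalization precedes every correlation computation.
* **Proportional co-expression.** Genes driven by the same upstream
  regulators are modelled as scalar multiples of a shared base profile.
  For three-point profiles the natural test statistic is the squared
  Pearson correlation R² of the ordered triples — identical to the
  coefficient of determination of a simple linear regression *with*
  intercept (the spreadsheet trendline default the original analysis
  used). No p-values are attached: with n = 3 there is one residual degree
  of freedom and a p-value would be meaningless, so the threshold
  criterion R² ≥ 0.90 is used directly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `area_ratio` | 26.8 | DSC : FUN(=CSC) tissue area ratio (dimensionless) |
| `low_signal_threshold` | 10 | raw-signal floor; a gene is dropped iff FUN **and** CSC are strictly below it |
| `tie_epsilon` | 0 | relative band for calling a FUN→CSC gradient flat |
| `r2_min` | 0.90 | all-pairs within-subgroup co-expression threshold |
| `linkage` | complete | all-pairs (`complete`) vs seed-gene (`reference`) admission rule |
| `sign_constraint` | any | optionally require positive slopes within a subgroup |

The low-signal filter is a strict `<` on *raw* signals (value 10 stays),
matching the stated rule; it is applied before regulon matching, which is
harmless because both are per-gene predicates. `tie_epsilon = 0` mirrors a
manual sign comparison; a small relative value (e.g. 0.05) is recommended
for noisy data so near-ties are reported as flat rather than classified by
noise.

## The subgrouping algorithm is a reconstruction

The original subgroup assignment was manual. This package formalizes it as
a deterministic greedy complete-linkage agglomeration: seed with the
lexicographically smallest unassigned gene; repeatedly admit the
unassigned gene with the highest minimum R² to the current members,
provided that minimum is ≥ `r2_min` (ties broken by smallest gene ID);
close when no gene qualifies; repeat. Consequences worth knowing:

* Every emitted subgroup satisfies the all-pairs constraint by
  construction, and each closed subgroup is maximal: no gene left
  unassigned at closing time could have been admitted. The test suite
  verifies both against an exhaustive subset-enumeration oracle on
  instances of up to 8 genes.
* The output is invariant to input row order; only gene IDs break ties.
* Whether the published criterion was all-pairs or against a single
  reference gene is not recoverable; both are implemented (`linkage`).
  The all-pairs reading is the default because leave-one-out group sums —
  the published validation — cohere better when every pair is constrained.
* Zero-variance (flat) profiles have undefined correlation and are
  excluded before clustering, with a report, rather than silently scored 0.
* Subgroup letters are assigned by decreasing size, ties by smallest
  member ID, so labels are stable across runs.

Group identities G1 = (auxin-down, gradient-up) and G4 = (auxin-up,
gradient-up) are anchored by the published gene tables; the semantics of
the two down-gradient groups are not stated anywhere, so G2 = (down, down)
and G3 = (up, down) are a documented package choice (`group_map`
argument).

## Leave-one-out validation

For a subgroup with members M and excluded gene g, the statistic is
R²(Σ_{m ∈ M∖{g}} profile(m), profile(g)). For exactly proportional
members this is 1 for any g (sums of proportional vectors stay
proportional); with two members it degenerates to the plain pairwise R².
The published analysis chose its excluded genes "arbitrarily"; the
pipeline always excludes the lexicographically smallest member so reruns
are reproducible.

## The network rules

Auxin enters through the two AFB co-receptor groups. The AFB partition is
derived from the data (down-gradient AFBs form the AFB1 group,
up-gradient AFBs the AFB5 group); if any AFB profile is flat the canonical
partition (TIR1/AFB1/AFB4 vs AFB2/AFB3/AFB5) is used with a warning and
`derived_from_data = FALSE`. Edge logic: auxin-*down* groups are
*repressed* by the AFB group with the *opposite* gradient; auxin-*up*
groups are *activated* by the AFB group with the *matching* gradient. ABA
and brassinosteroid regulation is attributed to fixed upstream pathway
nodes (ABI3/4/5, BES1/BZR1 — configurable `pathway_map`), one signed edge
per (pathway node, regulon hit), with the regulon's identity kept as edge
evidence. Germination roles (positive/negative/unknown) are consumed from
an annotation table — shipped as a transcription of the published
30-gene subgroup tables — and never inferred. Edges are emitted per gene;
gene→gene edges never arise from these rules.

## The synthetic generator: what it does and does not emulate

`simulate_dataset()` plants subgroups as `c_g · base_s · exp(ε)` with
`ε ~ N(0, σ)`, `σ = √log(1 + noise_cv²)` — multiplicative log-normal
noise, chosen for positive support and direct CV parameterization, which
is the standard first-order model for microarray signal noise. The DSC
column is emitted *raw* (26.8 × the intended normalized value) so the
normalization step is genuinely exercised. Background genes draw three
signals independently; a configurable fraction sits below the low-signal
filter. All randomness flows from one seed; outputs are byte-identical
across reruns.

One deliberate deviation from a naive reading of the design: the
base-profile collinearity bound (default pairwise base R² ≤ 0.5) is
enforced **within each planted (auxin label, gradient) cell**, not
globally. Centred three-point profiles span a two-dimensional plane, so at
most four directions can be mutually at R² ≤ 0.5 — and only at exact 45°
spacing; a global bound is geometrically infeasible for the default 12
subgroups. Since clustering only ever happens inside one gradient group,
the within-cell bound is exactly what planted-partition recovery needs.
Structured genes are generated clear of the low-signal filter (base
signals ≥ 30, proportionality constants ≥ 0.5) so that at low noise the
recovered partition can equal the planted one exactly.

Defaults state a world shaped like the source compendium: 12 subgroups of
~10 genes (≈ 118 auxin-regulated genes), 5% signal CV (a moderate
microarray noise level; the real level is unknown and not estimated),
unstructured background of 400 genes with 10% planted under the filter.

What a green test does **not** establish: the generator has no
probe-level artifacts, no shared-regulator correlation between subgroups,
no developmental-stage structure, and its noise level is an assumption —
so recovery results certify the algorithmic machinery, not the biological
findings of any particular dataset.

`simulate_germination()` draws a per-pair dish propensity from a beta
distribution (mean `wt_mean`, sd `dispersion`), shifts the mutant dish by
`effect`, and draws binomial counts — the paired design the paired t-test
assumes. Under the null this reproduces the nominal 5% type-I error
(measured 0.053 over 2,000 seeded replicates in the acceptance suite).

## Numerical and degenerate-input choices

* R² is reported at full precision; comparisons against printed values
  round half-up to two decimals, as printed.
* Paired t: all-zero differences → t = 0, p = 1; zero variance with
  nonzero mean → t = ±∞ with a degeneracy flag and p = 0. Equality with
  the closed form `mean(d)/(sd(d)/√n)` is asserted to 1e-10.
* No multiple-testing correction across genotypes by default (matching
  the source analysis); a Bonferroni option exists.
* Tissue-resolved rows missing any signal are rejected outright — a
  three-point correlation with two points is meaningless, so no
  imputation.
* The run manifest records a timestamp; byte-identical-rerun guarantees
  therefore cover every data output but not `manifest.json` itself.

## Known limitations

* Three data points per gene: the R² criterion has essentially no
  statistical power against chance proportionality; it is a screening
  heuristic, which is why leave-one-out sums and downstream experimental
  validation matter.
* The printed correlation values of the source analysis depend on its
  supplementary expression table, which is not redistributable here; the
  acceptance suite therefore validates the computational path on a
  synthetic stand-in with the same shape (4 groups, 12 subgroups, 118
  genes, 6 AFB loci) rather than asserting those printed numbers.
* Multi-probe loci are assumed pre-collapsed to one row per locus.
* The greedy partition is one deterministic solution to an
  underdetermined manual procedure; alternative orderings could split
  borderline genes differently (the `linkage` and `sign_constraint`
  options expose the main axes of that freedom).
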