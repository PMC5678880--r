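---
title: "Mining hypoxia-classification rules from a three-marker IHC panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hypoxia-classification rules from a three-marker IHC panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyporules)
```

## The problem and the model

Neuroblastoma tumors can be labelled hypoxic or normoxic by a microarray
expression signature, but that label needs frozen tissue. This package asks
how well three immunohistochemistry markers scored on routine paraffin
sections — HIF-1α and PDK1 (induced under hypoxia) and PHD3 (repressed under
prolonged hypoxia) — can stand in for it, and expresses the answer as
association rules: statements of the form *IF HIF1A=high AND PHD3=low THEN
HYPOXIA=high*, each scored by how often it fires and how often it is right.

The analysis treats the expression-derived cluster label as ground truth; it
is carried in the cohort table, never recomputed. Each tumor contributes one
*transaction* over eight items (`HIF1A=high/low`, `PDK1=high/low`,
`PHD3=high/low`, `HYPOXIA=high/low`), with exactly one polarity per marker.
Both polarities are first-class items so that rules about *low* expression
(the normoxic block) are mined on the same footing as rules about high
expression.

## From pathology scores to binary states

A pathologist scores each marker as a percentage-positivity bin; bins
collapse to three levels — `<1%`/`1–20%` = L, `21–50%` = M,
`51–70%`/`71–100%` = H — and L/H dichotomize directly to low/high. Medium
scores are genuinely ambiguous and are resolved by staining intensity. The
package's default policy is strong/moderate → high, weak → low; only the
direction "intensity decides" is inherent to the scoring scheme, the cut
between moderate and weak is a package choice, exposed in
`resolve_binary()` and bypassed entirely whenever an explicit
`medium_resolution` is recorded.

The packaged 25-tumor cohort has six medium cells, and the per-tumor
intensities behind them were never recorded. Rather than guess,
`resolve_by_consistency()` enumerates all $2^6 = 64$ high/low assignments
of those cells and keeps the ones whose induced counts reproduce the
occurrence pairs of all fourteen benchmark rules exactly. Exactly one
assignment survives, and the fixture hard-codes it as explicit
`medium_resolution` values. The derivation is re-run in the test suite, so
the fixture stays auditable: change one printed count and the search
reports the nearest misses instead of an answer.

## Mining and the five metrics

`apriori_frequent_itemsets()` is a from-scratch level-wise APRIORI
implementation: size-$k$ candidates are joined from frequent $(k-1)$-sets
sharing a prefix, pruned by support anti-monotonicity, and counted exactly
against the 0/1 transaction matrix. At the package's scale (tens of
transactions, eight items) correctness, not speed, is the design goal; the
miner is property-tested against exhaustive subset enumeration on random
databases. The default `min_count = 1` keeps every co-occurrence pattern so
that every rule's counts are exact.

For a rule $A \to B$ with counts $(N, n_A, n_B, n_{AB})$:

* **confidence** $= n_{AB}/n_A$;
* **coverage** $= n_{AB}/n_B$ — the fraction of consequent-positive tumors
  the rule captures (consequent recall). This is *deliberately not* the
  antecedent-support quantity that "coverage" often means in the rule-mining
  literature: the recall definition is the one consistent with every printed
  value in the benchmark table (e.g. 0.82 = 14/17, 0.65 = 11/17), and it is
  documented loudly because the same word means something else elsewhere;
* **lift** $= (n_{AB}/n_A)/(n_B/N)$, 1 under independence;
* **leverage** $= n_{AB}/N - (n_A/N)(n_B/N)$, 0 under independence;
* **conviction** $= n_A(N-n_B) / (N\,(n_A-n_{AB}+1))$ — a smoothed variant
  with a Laplace-style +1 in the denominator. The classical formula (without
  the +1) is infinite for every confidence-1 rule, which would make four of
  the fourteen benchmark values impossible; the smoothed variant reproduces
  all fourteen, including the finite values on confidence-1 rules (5.44,
  4.76, 4.8, ...). The classical form remains available via
  `variant = "classical"` and the test suite asserts the divergence as a
  negative control.

Metrics are computed in double precision directly from the integer counts;
at these magnitudes every ratio is exact (or within $10^{-12}$ of the exact
rational), far inside the two-decimal reporting precision. Rendering
(`render_metric()`) rounds half-up at two decimals and strips trailing
zeros — half-up because the benchmark table prints 3.125 as 3.13, while
IEEE/banker's rounding would give 3.12.

## Rule selection

`select_rules()` takes, per consequent polarity, the union of the top-`k`
rules by lift and the top-`k` by conviction (default `k = 7`), recording
for each selected rule which criterion admitted it. Ties are broken by
smaller antecedent, then lexicographic item order.

One parameter here deserves its own paragraph: the antecedent support
floor (`min_support = 0.15`, i.e. at least 4 of 25 tumors). Without any
support filter, an antecedent matching a *single* tumor trivially reaches
confidence 1 and therefore ties the maximal lift; on the packaged cohort
the rule {HIF1A=high, PDK1=low, PHD3=low} (one tumor) ties lift 3.13 with
the genuine multi-marker rules, and no tie-break can rank a four-way tie
out of a top-7 list. Every APRIORI front end has a minimum-support
parameter for exactly this reason. The floor value is the package's
declared choice, made once and validated end to end: any absolute floor
between 4 and 7 yields the same fourteen rules on the packaged cohort,
and 0.15 sits at the bottom of that plateau. Setting `min_support = 0`
shows the degenerate one-off rules explicitly (the test suite does).

With three binary markers there are exactly $2^3 - 1 = 7$ polarity-
consistent antecedents per consequent, so `k = 7` returns a 14-rule report
on the fixture. Rules for the high-hypoxia consequent are labelled first.
Within a block the report orders rules by antecedent size then marker
order — a deterministic convention; the benchmark table's own ordering of
the two-marker rules differs between its two halves, so no single sort
reproduces it, and all end-to-end comparisons in the tests join on the
(antecedent set, consequent) pattern rather than on position.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, so every stage is testable without external data and parameter
recovery can be demonstrated:

* latent hypoxia ~ Bernoulli(`prevalence`) per tumor;
* each marker takes its hypoxia-concordant state (HIF1A high, PDK1 high,
  PHD3 *low*) with probability `se` in hypoxic tumors, and its
  normoxia-concordant state with probability `sp` in normoxic ones,
  conditionally independently given the latent status;
* binary states are re-encoded as bins (high → uniform over
  `51–70%`/`71–100%`, low → uniform over `<1%`/`1–20%`), except that with
  probability `medium_fraction` the score is emitted as the ambiguous
  `21–50%` bin carrying only an intensity grade (strong/moderate for high,
  weak for low), exercising the intensity-resolution path.

Defaults mirror the packaged cohort, chosen once from it: `n_tumors = 25`,
`prevalence = 8/25`, per-marker `se`/`sp` equal to the fixture's observed
concordance rates (HIF1A 1 / 14⁄17, PDK1 7⁄8 / 15⁄17, PHD3 1 / 15⁄17), and
`medium_fraction = 6/75`. Conditional independence given hypoxia is the
minimal joint model under which multi-marker rules outperform single
markers, as they do in the real cohort; it is an assumption, not an
estimate. For the single-marker rule {marker = concordant} → {hypoxia
high}, the population confidence is the positive predictive value
$\pi\,se / (\pi\,se + (1-\pi)(1-sp))$ and the lift is PPV/$\pi$;
`recovery_experiment()` runs the full pipeline over replicate cohorts
(seeds derived as base seed + replicate index) and summarizes recovery of
these closed forms.

What the generator does *not* emulate: inter-marker dependence beyond the
latent class, pathologist scoring drift, missing marker scores, clinical
covariates, or any spatial/staining structure. Passing recovery tests
therefore shows the pipeline is statistically correct under its own model,
not that three markers suffice in new clinical material.

## Numerical and degenerate-input choices

* Empty transaction table → empty itemset table (not an error);
  `min_count` below 1, invalid probabilities, infeasible counts → typed
  parameter errors.
* A medium score with neither resolution nor intensity is an
  unresolved-score error naming the tumor and marker, raised at
  dichotomization, before any mining.
* Metric preconditions ($n_A \ge 1$ for confidence/lift/conviction,
  $n_B \ge 1$ for coverage/lift) are enforced; the smoothed conviction is
  total and finite wherever defined.
* `read_cohort()` rejects unknown vocabulary strings rather than coercing;
  ASCII-hyphen bins are the single accepted alias and are normalized on
  read.
* Simulation restores the caller's RNG state; identical spec + seed gives
  an identical cohort.

## Problem sizes in the test suite

The suite cross-checks the miner against brute-force enumeration on 240
random databases of up to 12 transactions × 8 items, the metrics against
direct arithmetic on 1200 random feasible count quadruples, and recovery
on simulated cohorts of up to 10,000 tumors (two seeds) plus replicate
experiments of 5–10 cohorts of 500–800 tumors. The full-table fixture
check, the 64-assignment audit and the fixture pipeline all run in well
under a second.

## Known limitations

* The cohort is small (25 tumors); the rule metrics are descriptive, and no
  significance testing or multiple-testing correction is performed — none
  is part of the benchmarked analysis.
* The hypoxia label is taken from the upstream expression signature; errors
  in that label propagate untouched.
* The selection's support floor and the intensity cut for medium scores are
  declared conventions validated on one cohort; both are arguments, not
  constants, so sensitivity to them is one function call away.
* Mining is binary only: no ordinal three-level mining, no continuous
  percentage modelling, no imputation of missing scores.
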