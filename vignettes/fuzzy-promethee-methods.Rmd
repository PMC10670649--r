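---
title: "Fuzzy-PROMETHEE for diagnostic-test evaluation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-PROMETHEE for diagnostic-test evaluation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpromethee)
```

This vignette is the package's account of its science: the model it
implements, the parameters that matter, the choices made where the
method leaves room, and what the shipped synthetic study can and cannot
demonstrate.

## The decision problem

Ranking diagnostic tests — the built-in replica concerns 16 techniques
for diagnosing urinary tract infections (UTIs) — is a multi-criteria
problem. Some criteria are measured percentages (sensitivity,
specificity, positive and negative predictive values); some are
physical or economic quantities to be *minimized* (specimen volume,
cost, time to first result); some are capabilities (point-of-care use,
direct-from-sample applicability, antimicrobial susceptibility
testing); and some are inherently vague expert judgements (efficiency,
practicality for patients and personnel, pathogen-identification
limitations). Fuzzy-PROMETHEE handles this mix by eliciting the vague
inputs on a linguistic scale backed by fuzzy numbers, collapsing them to
crisp values, and then running the PROMETHEE outranking machinery.

## From words to numbers: the fuzzy layer

The five-level scale maps labels to triangular fuzzy numbers (TFNs):

```{r scale}
defuzzify(uti_linguistic_scale())
```

A TFN $(a, b, c)$ has membership rising linearly from $a$ to the mode
$b$ and falling to $c$. We defuzzify with the Yager index — the centroid
of the membership surface, which for a triangle is $(a+b+c)/3$. The
centroid is the natural "centre of weight" reading of a triangular
judgement, is monotone in each support point, lies inside $[a, c]$, and
returns $x$ exactly for a crisp $(x, x, x)$. Alternative defuzzifiers
(mean of maxima, etc.) and fuzzy arithmetic beyond this collapse are
deliberately out of scope: in this workflow fuzziness enters only
through the elicited weights and the vague-valued cells, both of which
are collapsed before any pairwise comparison.

Criterion weights elicited on the same scale are defuzzified and then
normalized to sum to one. The source method leaves normalization
implicit, but the preference index below is stated to live in $[0, 1]$,
which holds exactly when $\sum_k w_k = 1$; we therefore normalize by
default and expose `normalize = FALSE` for experimentation only.
Linguistic *cell* values are defuzzified with the same centroid, on the
grounds that the same scale is used to simplify vague criteria.

## The outranking core

For alternatives $a_t, a_{t'}$ and criterion $k$ with values $f_k$, the
signed difference is $d_k = f_k(a_t) - f_k(a_{t'})$, with the sign
flipped for minimized criteria. The flip is the universal PROMETHEE
convention; the source description is silent about direction handling,
but without it a cheaper test would be *penalized* on cost. Which of the
15 replica criteria are minimized is likewise not recorded anywhere we
can consult, so the package documents its own defaults (specimen
volume, cost, result time minimized; everything else maximized) as
assumptions.

The default preference function is Gaussian:
$$P(d) = \begin{cases} 0 & d \le 0 \\ 1 - e^{-d^2 / 2s^2} & d > 0,\end{cases}$$
with $s$ the **population** standard deviation (divisor $n$) of the
criterion's column across the alternatives being compared. The Gaussian
ramp discounts tiny differences smoothly — the stated reason it was
chosen for the UTI study. Design choices around $s$:

* *Estimator.* Population vs sample sd is not specified at the source;
  at $n = 16$ they differ by about 3%, and since $s$ only rescales
  differences *within* a criterion the choice barely moves rankings. We
  default to population sd and expose `sd_type = "sample"`.
* *Recomputation.* $s$ is re-estimated from the surviving columns after
  any criterion omission — automatic here because $s$ is per-column,
  but stated so that users who override `s` globally know the contract.
* *Degenerate* $s = 0$ (a criterion on which all alternatives agree):
  every preference on that criterion is 0. This is the pointwise limit
  of the Gaussian form and avoids a division by zero; such a criterion
  cannot discriminate, so contributing nothing is the only consistent
  behaviour.

The other five standard families (usual, U-shape, V-shape, level,
linear) are implemented from the classical PROMETHEE catalogue and
selected per criterion via `pf =` with explicit thresholds; only the
Gaussian family is used by the replica design.

The preference index aggregates over criteria,
$\pi(a_t, a_{t'}) = \sum_k w_k P_k(d_k)$, and flows average over
opponents: leaving flow $\Phi^+ = \frac{1}{n-1}\sum_{t'} \pi(a_t, a_{t'})$,
entering flow $\Phi^- = \frac{1}{n-1}\sum_{t'} \pi(a_{t'}, a_t)$, net flow
$\Phi_{net} = \Phi^+ - \Phi^-$. Because each ordered pair contributes
once positively and once negatively, $\sum_t \Phi_{net}(a_t) = 0$
identically — the suite checks this to $10^{-10}$ across hundreds of
seeded studies.

PROMETHEE I classifies pairs from $(\Phi^+, \Phi^-)$: preference when
one alternative is at least as good on both flows and strictly better
on one; indifference when both flows are equal; incomparability when
the flows disagree (higher strength *and* higher weakness). PROMETHEE II
ranks by $\Phi_{net}$ descending. Flow equality between real numbers
needs a tolerance the source does not give: we compare with an absolute
`epsilon`, default $10^{-9}$ — far below meaningful flow differences,
far above accumulated rounding at these problem sizes. Ties share a
competition rank (1, 2, 2, 4); the published study has no ties, so any
convention is compatible, and competition ranking keeps ranks
interpretable ("how many alternatives beat me").

The unicriterion decomposition
$\varphi_k(a_t) = \frac{1}{n-1}\sum_{t'}[P_k(a_t,a_{t'}) - P_k(a_{t'},a_t)]$
is the standard per-criterion profile (the source plots such profiles
but gives no formula); it satisfies
$\sum_k w_k \varphi_k(a_t) = \Phi_{net}(a_t)$ exactly, which the tests
assert, and drives `plot_profile()`.

## The synthetic study generator

The 16 × 15 expert decision matrix behind the published UTI ranking was
never released, so `simulate_decision_matrix()` generates matrices with
the study's *structure* — per-criterion classes, directions and the
elicited fuzzy weight scheme — without claiming to reproduce its
numbers (that reproduction is impossible by construction and is not
attempted). Generator defaults, chosen once as field-realistic:

* **percentage** criteria (sensitivity, specificity, PPV, NPV): drawn
  as $50 + 50\,\mathrm{Beta}(6, 2)$, i.e. confined to $[50, 100]$ with
  a typical value near 87% — diagnostic tests in routine use rarely
  report performance below chance or above the high nineties.
* **cost_like / time_like** criteria: lognormal (median 20 units,
  $\sigma_{\log} = 0.8$; median 60 minutes, $\sigma_{\log} = 1$) —
  positive and right-skewed, as cost and turnaround distributions are.
* **linguistic5** criteria: uniform draws over the five scale labels,
  then defuzzified (optionally kept as labels to exercise the CSV
  parsing path).
* **binary** capabilities: Bernoulli(1/2).

A `noise` multiplier scales all dispersions. Generation is a pure
function of `(criteria, alternatives, seed, noise)` and restores the
caller's RNG state.

What passing tests on these matrices show — and what they do not: the
pipeline's *algebraic* properties (zero-sum flows, oracle agreement,
affine invariance, dominance recovery, omission consistency) hold on
data of realistic shape; nothing is thereby shown about the original
expert judgements, whose correlations between criteria (a cheap test is
often also fast and point-of-care) the independent-column generator
does not emulate. The published flow tables are retained verbatim in
`uti_reported_flows()` as the study's only numeric anchor; the package
checks their internal arithmetic ($\Phi_{net} = \Phi^+ - \Phi^-$ row by
row, zero column sums) rather than regenerating them.

Two anomalies in those tables are worth recording. First, four of the
32 printed rows (two per table) have $\Phi^+ - \Phi^-$ off by one unit
in the fourth decimal from the printed $\Phi_{net}$ — last-digit
rounding in the original report; all rows agree within $10^{-4}$.
Second, the omission ranking differs considerably from the headline
ranking (flow magnitudes about 30-fold larger, Microfluidics first
instead of sixth) even though the accompanying note calls the ranking
robust; with the decision matrix unpublished this cannot be reconciled,
so the package reports ranking stability quantitatively (Kendall
$\tau$, rank displacements) and makes no binary robustness claim.

## Numerical and degenerate-input policy

* Validation rejects incomplete or non-finite cells (with row/column
  coordinates), unordered TFN triples, negative or all-zero weight
  vectors, and omission of every criterion.
* `plant_dominant_alternative()` sets a row to the per-criterion best
  and nudges the first positively weighted criterion by a margin of
  $10^{-9}\max(1, |v|)$ — enough to break exact ties in the weak-
  dominance argument, invisible at reporting precision. Planting is
  refused when another row already attains every per-criterion best,
  since dominance would no longer be unique.
* Reports round half-even to 4 decimals for display (matching the
  published tables' convention) while JSON payloads carry full
  precision; CSV/JSON writers are byte-stable for identical inputs.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full 16 × 15 replica
(500 seeds for the zero-sum sweep, 200 for dominance recovery), 100
random 6 × 4 problems against a naive triple-loop oracle at
$10^{-12}$, and assorted 2–8 alternative toys for closed-form cases.
These sizes give exhaustive coverage of the method's combinatorics at
interactive runtimes; the algorithms are $O(n^2 K)$ and comfortably
handle the dozens-by-dozens matrices typical of health-technology
assessment.

## Known limitations

* No GAIA-plane visualisation, PROMETHEE III–VI variants, group
  aggregation, or weight-stability intervals.
* Fuzziness is collapsed before comparison; interval-valued or type-2
  extensions are out of scope.
* The replica's criterion directions and generator classes are
  documented assumptions, not recovered facts; users with access to
  real evaluations should supply their own matrix and criteria config.
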