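# fpromethee

Fuzzy-PROMETHEE outranking analysis for diagnostic-test evaluation, built
tidyverse-style: data frames in, tibbles out, `tidy()`/`glance()` on the
fitted object, `autoplot()` for figures.

## The problem

Choosing a diagnostic test — here, among 16 techniques for diagnosing
urinary tract infections (UTIs), from dipstick nitrite and leucocyte
esterase through culture, PCR, MALDI–TOF–MS, biosensors and
microfluidics — means trading off many criteria at once: sensitivity,
specificity, predictive values, cost, turnaround time, point-of-care
capability, practicality, and more. Some of those criteria are
measurable percentages; others ("efficiency", "practicality") are vague
expert judgements. This is a multi-criteria decision analysis (MCDA)
problem with fuzzy inputs, and the package implements the standard
fuzzy-PROMETHEE answer to it.

## The method

Expert judgements and criterion weights are elicited on a five-level
linguistic scale mapped to triangular fuzzy numbers (TFNs), from Very
Low (0, 0, 0.25) to Very High (0.75, 1, 1). A TFN (a, b, c) is collapsed
to a crisp value by the Yager index — the centroid of its triangular
membership surface, (a + b + c)/3 — and the crisp weights are normalized
to sum to one.

For each ordered pair of alternatives (a_t, a_t') and each criterion k,
the signed difference d_k = f_k(a_t) − f_k(a_t') (sign flipped for
minimized criteria such as cost and result time) is mapped to a
preference degree by the Gaussian preference function

    P(d) = 0                        for d ≤ 0
    P(d) = 1 − exp(−d² / 2s²)       for d > 0,

where s is the population standard deviation of the criterion column.
The weighted sum over criteria gives the preference index
π(a_t, a_t') = Σ_k w_k P_k(d_k) ∈ [0, 1]. Averaging π over the n − 1
opponents yields the leaving flow Φ⁺ (strength), the entering flow Φ⁻
(weakness), and the net flow Φnet = Φ⁺ − Φ⁻, which always sums to zero
over alternatives. PROMETHEE I builds a partial order from (Φ⁺, Φ⁻)
— preference, indifference, or incomparability — and PROMETHEE II ranks
completely by Φnet. A unicriterion decomposition
φ_k(a_t) = (1/(n−1)) Σ_{t'} [P_k(a_t, a_t') − P_k(a_t', a_t)] localises
each alternative's strengths and weaknesses per criterion, with
Σ_k w_k φ_k = Φnet exactly. A criterion-omission sensitivity analysis
re-runs the pipeline without chosen criteria (weights renormalized,
spreads re-estimated) and reports Kendall's τ plus per-alternative rank
displacements.

The expert 16 × 15 decision matrix behind the original UTI study was
never published; the package therefore ships (i) the study *design*
(criteria, directions, linguistic weight terms) as a built-in replica,
(ii) a seeded synthetic matrix generator with the study's statistical
structure, and (iii) the study's published flow tables for arithmetic
cross-checks.

## Worked example

```r
library(fpromethee)

design <- uti_study_design()              # 16 tests x 15 criteria, fuzzy weights
m      <- simulate_decision_matrix(seed = 3)  # synthetic expert evaluations
fit    <- promethee(m, design$criteria)
fit
#> Fuzzy-PROMETHEE analysis: 16 alternatives x 15 criteria
#> Complete ranking (net flow, 4 decimals):
#>    1  Biosensor                                       0.2320
#>    2  Microfluidics                                   0.1652
#>    3  Nucleic acid-based techniques (Multiplex PCR)   0.1469
#>    4  Real-time microscopy systems                    0.0692
#>    ...
#>   16  Immunologically based assay                    -0.2477
```

Each line is one diagnostic technique with its net outranking flow under
this synthetic matrix: positive means the test is, on balance, preferred
to the field; the flows sum to zero by construction. `tidy(fit)` returns
the ranking as a tibble, `glance(fit)` a one-row summary:

```r
glance(fit)
#> # A tibble: 1 × 5
#>   n_alternatives n_criteria     epsilon net_flow_sum n_incomparable_pairs
#> 1             16         15 0.000000001    -5.55e-17                   21
```

`net_flow_sum` is the zero-sum invariant (machine epsilon);
`n_incomparable_pairs` counts pairs PROMETHEE I cannot order because one
test has both the larger strength and the larger weakness.
`autoplot(fit)` draws the ranking, `plot_profile(fit)` the per-criterion
strength/weakness bars.

Dropping the two least-weighted criteria (specimen volume and specimen
type) probes ranking stability:

```r
sensitivity_analysis(m, design$criteria, drop = c("C1", "C2"))
#> Criterion-omission sensitivity: dropped {C1, C2}
#> Kendall tau (baseline vs perturbed ranking): 0.9333
#> Alternatives that changed rank: 7 of 16
```

A τ of 1 would mean an unchanged order; here the omission nudges seven
tests by small amounts.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "fpromethee.R", package = "fpromethee")` with
subcommands `simulate`, `rank`, `sensitivity` and `profile`.

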