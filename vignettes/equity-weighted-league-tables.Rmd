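---
title: "Methods: equity-weighted cost-effectiveness league tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equity-weighted cost-effectiveness league tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equileague)
```

## The procedure

`equileague` operationalizes a priority-setting procedure for health benefit
packages in settings without disaggregated burden data: an expert panel
scores each disease condition on an ordinal 1–4 equity scale (4 = condition
predominantly affecting the poor and rural residents), and the scores are
turned into multiplicative equity weights on intervention health benefits.
The stages, in order:

1. **Mean scores.** For each condition, the arithmetic mean of the
   non-missing expert scores. Missing ratings are simply excluded from the
   mean rather than imputed: an abstention carries no information about the
   condition, and the remaining raters still identify the panel average.
2. **Categorization.** Conditions are sorted by mean score descending and
   split into three contiguous blocks — high, medium, low — of near-equal
   size (see *Numerical choices* for ties).
3. **MCH reassignment.** Conditions predominantly affecting women of
   reproductive age or under-five children (the MCH flag in the metadata)
   that landed in medium or low are raised to the minimum mean score of the
   high category. The intent is a bounded correction: maternal and child
   conditions should rank at least at the bottom of the high group, but not
   above conditions the panel itself scored higher on the
   poverty/residence attributes. The floor is recomputed from the data on
   every run, never hard-coded.
4. **Standardization.** The post-reassignment scores are min–max rescaled
   onto $[1, 2]$: $w = 1 + (s - s_{\min})/(s_{\max} - s_{\min})$. The map is
   affine and order-preserving; its endpoints encode the panel's
   value judgement that health gains to the worst-off count exactly twice.
5. **Adjustment and re-ranking.** Each intervention inherits the weight of
   its condition (multi-condition interventions: unweighted mean by
   default). Multiplying the health-benefit denominator of the
   cost-effectiveness ratio by $w$ is equivalent to
   $\mathrm{CER}_{adj} = \mathrm{CER}/w$, so
   $\mathrm{CER}_{adj} \in [\mathrm{CER}/2, \mathrm{CER}]$ always. League
   tables are ranked ascending (lower cost per DALY averted = better) by
   both the raw and adjusted CER, and `compare_rankings()` summarizes the
   difference (top-k entrants/exits, per-intervention rank change, Kendall
   tau-b).

## Assumptions

- The ordinal scores are treated as interval-scaled when averaged — the
  standard, if debatable, practice for Likert-type Delphi output. All
  downstream quantities are monotone transforms of those means.
- The panel is treated as exchangeable: the mean is invariant to expert
  order, and no expert weighting, consensus statistic or round structure is
  modelled. Multi-round score sheets should be pooled (row-concatenated)
  upstream before aggregation.
- GBD level-2 group averages are unweighted means of condition means:
  a group summary of panel opinion, not a burden-weighted quantity.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `range` (standardization) | `c(1, 2)` | weight, dimensionless | max/min = 2 encodes "gains to the worst-off count double"; configurable for other trade-offs |
| `cutpoints` (categorize) | `NULL` (tertiles) | score scale 1–4 | the procedure describes only "three groups"; thresholds allow a policy-set alternative |
| `mode` (intervention weights) | `"mean"` | mean, max, min | no stated rule for interventions spanning conditions; the unweighted mean is neutral, max/min give pro-equity/conservative variants |
| `top_k` (comparison) | 30 | interventions | the size of the published league-table head |
| `expert_noise_sd` (generator) | 0.7 | latent score scale | reproduces the broad cross-expert disagreement real panels show (scores spread over several levels for some conditions) |
| `missing_rate` (generator) | 0 | probability | complete panels are the reference condition; raise it to stress missing-data handling |
| `mch_fraction` (generator) | 0.15 | probability | ~38 of 253 conditions flagged, consistent with a few dozen MCH conditions of which ~20 land in medium/low |
| `cer_log_mean`, `cer_log_sd` | log(100), 1.5 | log US$/DALY | right-skewed CERs spanning roughly $5–$2,000, the shape of published league tables |

## What the synthetic generator emulates — and what it does not

`gen_panel()` draws a latent mean per condition uniformly on
`latent_mean_range` (default 1.1–3.8, mirroring the realized span of panel
averages), then models each expert's rating as latent mean + Gaussian noise,
rounded to the nearest integer and clipped to $[1, 4]$. This
latent-Gaussian ordinal model was chosen over a free multinomial because it
has two closed-form handles the tests exploit: with zero noise and integer
latent means the pipeline is exactly invertible (equity weights are an
affine transform of the latent means), and with noise the discretized
response distribution is an explicit four-point distribution computed from
Gaussian tail probabilities, giving an independent oracle for the
rounding/clipping bias that `recovery_experiment()` measures.

It does **not** emulate: expert heterogeneity by profession or region,
within-panel correlation (moderator-led discussion, anchoring on presented
burden data), condition-specific polarization (bimodal score splits), or
any round-to-round feedback. Passing tests therefore demonstrate that the
*procedure* is implemented correctly and is recoverable under a plausible
noise model — not that a real panel's scores are unbiased or stable.

## Numerical choices

- **Ties at category boundaries.** Conditions with tied means must share a
  category, so the ideal tertile boundaries cannot always be used. Among
  all boundary placements that respect ties, `categorize()` picks the one
  minimizing the total deviation of block sizes from the ideal split
  (remainder conditions to the earlier blocks), breaking remaining
  equalities by moving boundaries *down* so a tied run joins the higher
  category. On means $(3,3,3,2,1,1)$ the tie-respecting placements allow
  boundaries only after positions 0, 3, 4 or 6, and sizes $(3,1,2)$ are the
  unique minimizer — the three 3s share the high category. In the fully
  degenerate case (all means equal) every condition lands in high, which
  keeps the MCH floor well-defined.
- **Degenerate standardization.** If all post-reassignment scores are
  identical there is no equity differentiation; every weight is set to the
  range minimum (1) and a classed warning is raised rather than dividing by
  zero.
- **Rank ties.** Both league rankings break ties lexicographically on the
  intervention id, so outputs are byte-for-byte reproducible. Kendall
  tau-b (tie-corrected, via `stats::cor`) is used for the rank correlation
  because adjusted CERs can tie; it is a diagnostic the package adds, not
  part of the original procedure.
- **Rounding.** All means and weights are carried at full double precision;
  rounding to two decimals happens only in display.
- **Seeding.** Every stochastic routine takes its seed from the
  configuration object; `recovery_experiment()` derives replicate seeds as
  `seed + rep` and holds the latent means fixed across replicates so
  per-condition bias/RMSE are well-defined.

## Design decisions where the procedure is under-specified

- **Shape of the three groups.** Near-equal tertiles were adopted as the
  simplest reading of "sorted descending, split into three groups"; a
  score-threshold mode (`cutpoints`) is provided for panels that prefer
  substantive cut scores.
- **Order of operations.** MCH reassignment happens *before*
  standardization, so reassigned conditions receive exactly the weight of
  the high-category minimum, and the weight range is anchored by the
  post-reassignment extremes.
- **Multi-condition interventions.** No rule is stated for an intervention
  spanning several conditions; the unweighted mean of the linked weights is
  the default, with `max`/`min` switches, and the choice is recorded in the
  run manifest.
- **Missing scores.** Permitted and excluded from means; a condition rated
  by nobody is a validation error, not a silent drop.

## Problem sizes in the test suite

The suite exercises the full study dimensions where they matter — the
synthetic default is a 28 × 253 panel with 300 interventions, and the
acceptance tests run a deterministic stand-in worksheet at exactly that
scale — while property loops (tie handling, rank oracles, permutation
invariance) use panels of 5–40 conditions and league tables of up to 12
rows, with the exhaustive Kendall oracle applied to all table sizes up to 8.
The Monte-Carlo recovery experiment uses 200 replicates at 28 and 56
experts. The whole suite completes in well under a minute on a single CPU.

## Known limitations

- The package reproduces the *mechanism* of the exercise; it ships no real
  panel data, so published headline values can only be checked on synthetic
  stand-ins constructed to the same scale.
- Equity here is a single composite judgement (wealth × residence, with an
  MCH correction); the four underlying attributes are not modelled
  separately, and no inequality-aversion parameterization (e.g.
  Atkinson-type) is offered.
- Financial risk protection, budget impact and the wider multi-criteria
  composite that a full benefit-package process uses are out of scope:
  CERs are inputs, never estimated.
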