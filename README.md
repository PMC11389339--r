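# equileague

Equity-weighted cost-effectiveness league tables from Delphi panel scores.

## The problem

When a country designs a health-insurance benefit package it typically ranks
candidate interventions in a *league table* by their cost-effectiveness ratio
(CER — cost per unit of health benefit, e.g. US$ per DALY averted) and fills
the package from the top. Ranking on CER alone, however, ignores *who* gains:
two interventions with the same CER may serve very different populations. When
no disaggregated data on the distribution of disease burden by wealth or
residence exist, an expert panel (Delphi technique) can score each disease
condition on an ordinal 1–4 equity scale — 4 for conditions predominantly
affecting the poor and rural residents, 1 for conditions at least as common
among the better off — and those scores can be converted into explicit equity
weights on health benefits.

`equileague` implements that full procedure for analysts running or auditing
such an exercise:

1. **Aggregation** — per-condition mean scores over the panel (missing
   ratings excluded), per-condition score distributions, and unweighted
   averages by GBD level-2 cause category.
2. **Equity scoring** — conditions sorted by mean score descending and split
   into three near-equal categories (high / medium / low; tied means never
   straddle a boundary); conditions predominantly affecting women or
   children (MCH flag) that fall in medium/low are lifted to the *minimum
   mean score of the high category*; the post-reassignment scores are then
   min–max standardized to weights

   *w* = 1 + (*s* − *s*<sub>min</sub>) / (*s*<sub>max</sub> − *s*<sub>min</sub>)  ∈ [1, 2],

   so the most pro-poor condition carries twice the weight of the least.
3. **League tables** — each intervention inherits its condition's weight
   (mean/max/min across multiple linked conditions), its health-benefit
   denominator is multiplied by the weight — equivalently
   CER<sub>adj</sub> = CER / *w*, so a weight of 2 halves the CER and a
   weight of 1 leaves it unchanged — and interventions are re-ranked.
   `compare_rankings()` reports which interventions enter/exit the top-k and
   the Kendall tau-b correlation between the two rankings.
4. **Synthetic data** — a seeded generator (latent-Gaussian ordinal response
   model) emulating a 28-expert × 253-condition panel with right-skewed
   log-normal CERs, so the whole pipeline is testable without any external
   data.

## Worked example

```r
library(equileague)

cfg <- synth_config(seed = 1)          # 28 experts, 253 conditions, 300 CERs
panel <- gen_panel(cfg)
interventions <- gen_interventions(cfg, colnames(panel$scores))

summaries <- mean_scores(panel$scores)
range(summaries$mean_score)
#> [1] 1.178571 3.785714

equity <- build_equity_table(panel$scores, panel$meta)
min(equity$raw_mean[equity$category == "high"])   # MCH reassignment floor
#> [1] 2.857143
sum(equity$mch_flag & equity$category %in% c("medium", "low"))
#> [1] 26

league <- build_league(intervention_equity(interventions, equity))
compare_rankings(league, k = 30)
#> <rank_comparison> top-30: 3 entered, 3 exited; Kendall tau = 0.929
```

The panel's average scores span 1.18–3.79 on the 1–4 scale; the weakest
condition still inside the high category averages 2.86, and the 26 MCH
conditions that the panel left in medium/low are lifted to that value before
standardization. After adjustment, 3 interventions enter the top 30 (and 3
drop out) relative to the unadjusted CER ranking; the two rankings remain
strongly concordant (tau ≈ 0.93).

The head of the adjusted league table shows the mechanics — I257 overtakes
I120 because its weight (1.95) nearly halves its CER:

```r
head(league[order(league$rank_adjusted), ], 3)
#>   intervention_id   cer equity_weight adjusted_cer rank_cer rank_adjusted
#> 1 I251             1.69          1.64         1.03        1             1
#> 2 I257             2.53          1.95         1.30        3             2
#> 3 I120             1.69          1.27         1.33        2             3
```

File-based workflows use `read_score_sheet()` / `read_condition_meta()` /
`read_interventions()` and `run_pipeline()`, which writes six artifacts
(condition and group summaries, equity table, league table, rank comparison,
JSON run manifest). A thin command-line front end with subcommands
`synth | score | equity | league | report | all` lives at
`inst/cli/equileague.R`.

## Package layout

- `R/` — panel I/O, aggregation, equity scoring, league tables, synthetic
  generator, pipeline orchestration.
- `tests/testthat/` — unit, property and acceptance tests (independent
  brute-force oracles for ranking, tie handling and the ordinal response
  model).
- `vignettes/equity-weighted-league-tables.Rmd` — the methods vignette:
  model, assumptions, parameter choices, limitations.
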