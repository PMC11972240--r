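# patchleave

Predicting patch-leaving decisions in visual foraging from the spatial
organization of search and from Marginal-Value-Theorem intake rates.

## What it is for

In visual foraging tasks, an observer collects targets scattered among
distractors on a display (a *patch*) and may abandon it at any time,
paying a travel cost before the next one. Two families of signals have
been proposed to predict the moment of departure:

* **Intake rates.** The Marginal Value Theorem (MVT) says to leave when
  the instantaneous intake rate drops to the average rate — when the
  ratio RIAIR = (instantaneous rate)/(average rate) falls below 1.
  Sustained values below 1 indicate overharvesting.
* **Search organization.** Collection paths degrade before departure.
  Four classic indicators quantify this from the pick coordinates:
  *best-r* (the larger absolute Pearson correlation between collection
  order and either screen coordinate), the *mean inter-target distance*
  (px), the *PAO* — percentage above the optimal path,
  `PAO = (actual/optimal − 1) × 100`, where the optimal path is the
  shortest open Hamiltonian path through the collection locations (a
  TSP variant solved exactly up to 13 points, by a never-undercutting
  heuristic beyond) — and the *intersection rate* of non-consecutive
  scan-path segments.

`patchleave` is aimed at researchers in visual cognition and foraging
who have per-pick event logs (time, coordinates, item kind) and want to
ask: which signal best predicts the stay/leave decision, at what
threshold, and does combining them help? The package

1. reads/writes a documented CSV event-log dialect and converts trials
   into labeled stay/leave decisions (one per collected target from the
   third onward; the last pick before departure is the leave decision);
2. computes the four organization indicators and the RIAIR
   incrementally over the "trial so far";
3. standardizes the indicators, checks dimensionality with Horn's
   parallel analysis, and builds PCA-loading-weighted and unweighted
   composites,
   `C_w = w_br·z_br − w_itd·z_itd − w_pao·z_pao − w_int·z_int`;
4. evaluates every predictor with ROC curves (AUC = Mann–Whitney
   concordance, exactly), Youden-optimal thresholds, and DeLong or
   Hanley–McNeil confidence intervals;
5. combines two predictors into a single compound AND/OR leaving
   criterion via the maximum-likelihood ROC combination; and
6. simulates foraging sessions (static or moving items, parameterized
   collection strategies and quitting rules) with ground truth, so the
   whole pipeline is testable without human data.

## Worked example

Simulate two cohorts of MVT-rule foragers differing in search
discipline, then run the full pipeline per condition:

```r
library(patchleave)

design <- list(
  list(arena = arena_config(set_size = 80, speed = 0),
       agent = agent_config(disorder = 0.1, leave_rule = rule_mvt(1),
                            min_picks = 6),
       n_trials = 40, condition = "organized"),
  list(arena = arena_config(set_size = 80, speed = 44),
       agent = agent_config(disorder = 0.6, leave_rule = rule_mvt(1),
                            min_picks = 6),
       n_trials = 40, condition = "disorganized")
)
sim <- simulate_session(design, seed = 2026)
res <- run_pipeline(sim$log, seed = 2026)
res
#> <patchleave_result> 2 strata, 18 predictor rows
#> # A tibble: 18 × 5
#>    stratum      predictor                            auc sensitivity specificity
#>    <chr>        <chr>                              <dbl>       <dbl>       <dbl>
#>  1 organized    best_r                             0.626       0.7         0.572
#>  2 organized    mean_itd_px                        0.551       0.65        0.503
#>  3 organized    pao_pct                            0.606       0.725       0.497
#>  4 organized    intersection_rate                  0.565       0.2         0.931
#>  5 organized    composite_weighted                 0.632       0.65        0.642
#>  6 organized    composite_unweighted               0.624       0.625       0.642
#>  7 organized    riair                              0.817       1           0.579
#>  8 organized    combined composite_weighted + ria… 0.864       0.975       0.642
#>  9 organized    combined composite_unweighted + r… 0.860       0.975       0.637
#> 10 disorganized best_r                             0.776       0.6         0.844
#> ...
```

The agents quit by the MVT rule, so the RIAIR is the strongest single
predictor in both strata (AUC 0.82/0.80) — and combining it with the
composite organization score improves prediction further (AUC
0.86/0.91), mirroring the logic the pipeline was built to test. Each
row also carries the AUC confidence interval and the Youden-optimal
threshold or compound rule (e.g.
`composite_weighted < 0.629 AND riair < 0.9865` for the disorganized
stratum) in `res$results`.

The per-stratum composite fits are available too:

```r
res$composites[["organized"]]$pca
#> <pca_result> first component explains 64.3% of variance (n = 40)
#> eigenvalues: 2.572 0.783 0.425 0.220
#> loadings:
#>            best_r       mean_itd_px           pao_pct intersection_rate
#>             0.858            -0.609            -0.918            -0.789
```

`write_results(res, "out/")` emits the results table, optional curve
dumps, and a provenance JSON. A thin command-line wrapper with
`simulate` and `pipeline` subcommands is installed at
`inst/cli/patchleave`.

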