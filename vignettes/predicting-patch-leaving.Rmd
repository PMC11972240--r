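---
title: "Predicting patch-leaving decisions from search organization and intake rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting patch-leaving decisions from search organization and intake rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchleave)
```

## The problem

In visual foraging tasks an observer collects targets scattered among
distractors on a display (a *patch*) and is free to abandon it at any
moment, paying a travel cost before the next patch appears. When should
they leave? Classic optimal-foraging theory answers with the Marginal
Value Theorem (MVT): leave when the instantaneous intake rate falls to
the average rate, i.e. when their ratio (the RIAIR) drops to 1. A
complementary idea is that the *spatial organization* of the search
degrades before departure: collection paths become longer, more
erratic, and more self-crossing as the patch depletes and the remaining
targets get harder to find.

`patchleave` implements the full analysis pipeline for testing both
accounts on event logs of timed, located item selections: it computes
the organization indicators and intake rates incrementally over the
"trial so far", condenses the indicators into composite scores, and
evaluates every predictor of the stay/leave decision with ROC curves,
including a maximum-likelihood combination of two predictors into a
compound AND/OR leaving criterion. Because the human datasets this
methodology was developed on are not openly available, the package
ships an agent-based foraging simulator that generates event logs with
the same statistical structure and known ground truth, so every stage
of the pipeline is testable end to end.

## Decisions and the trial-so-far series

Every collected target is one decision: the last pick before departure
is a *leave* decision, all earlier ones are *stay* decisions. The
predictors attached to the decision at the $n$-th pick are computed
from the first $n$ picks only (the trial-so-far prefix). The series
starts at $n = 3$, the smallest prefix on which all four organization
indicators are defined, so a trial with $N$ collected targets
contributes $\max(0, N - 2)$ decisions, exactly one of them labeled
leave. Distractor selections are excluded from the decision series and
from all organization coordinates; they enter only the optional
points-based intake rates.

On moving displays the coordinates used everywhere are the item
positions *at the collection instants*, which is what a touchscreen
log records.

## Organization indicators

For picks at $(x_i, y_i)$, $i = 1 \dots n$, in collection order:

* **best-r** — the larger of $|\mathrm{cor}(i, x_i)|$ and
  $|\mathrm{cor}(i, y_i)|$ (Pearson). Reading-like or columnwise sweeps
  give values near 1. A coordinate with zero variance contributes 0
  rather than an undefined correlation; if both are constant the value
  is 0 and the row is flagged degenerate.
* **mean ITD** — the mean Euclidean distance between consecutive
  picks, in pixels.
* **PAO** — the percentage by which the actual path exceeds the
  shortest possible path through the same locations:
  $\mathrm{PAO} = (L_{\mathrm{actual}} / L_{\mathrm{opt}} - 1) \times 100$.
  $L_{\mathrm{opt}}$ is the length of the shortest *open* Hamiltonian
  path with both endpoints free — the path variant of the Traveling
  Salesman Problem. Anchoring the optimal path at the first pick is a
  defensible alternative reading and is exposed as `anchor_first`; the
  free-endpoint path is the default because it is the canonical lower
  bound on travel. When all picks coincide, $L_{\mathrm{opt}} = 0$ and
  the ratio is undefined: the value is returned as flagged `NA` and
  excluded downstream.
* **intersection rate** — the number of pairs of non-consecutive path
  segments that intersect (proper crossings, endpoint touches, and
  collinear overlaps each count once per pair; segments sharing a pick
  are skipped via the $j \ge i + 2$ rule), divided by the number of
  segments $n - 1$. Some reports use "intersections per target"; the
  `per_target` option divides by $n$ instead.

best-r, PAO and the intersection rate are translation-invariant, PAO
and the intersection rate also rotation- and scale-invariant, and the
mean ITD scales linearly with the display — properties the test suite
checks directly.

### Solving the optimal path

The optimal path is re-solved from scratch at every prefix $n$. Up to
`exact_cap = 13` points the solver is exact Held–Karp dynamic
programming over subsets ($O(2^n n^2)$, microseconds in compiled code
at that size). Beyond the cap a heuristic takes over:
nearest-neighbor construction from every start, each tour refined by
2-opt (segment reversal) and or-opt (relocation of segments of length
1–3, both orientations) until no move improves. The heuristic is a
valid path, so it can never undercut the exact optimum, and on random
7-point instances it matches the optimum on more than 99% of cases —
both properties are asserted in the acceptance tests. The cap of 13
keeps the exact solve below a millisecond while covering the large
majority of prefix sizes that occur in trials of realistic length.

## Intake rates and the RIAIR

With pick times $t_1 < t_2 < \dots$ (and $t_0 = 0$, the trial onset),
the instantaneous rate at pick $i$ is $v_i / (t_i - t_{i-1})$ and the
average rate is $\sum_{j \le i} v_j / t_i$; the RIAIR is their ratio.
In the default `items` mode $v_i = 1$, so the RIAIR depends only on the
pick times and is invariant under uniform time rescaling; a `points`
mode uses the logged score deltas (+2 per target, −1 per distractor)
for sensitivity analyses. The between-patch travel cost is session
metadata and is excluded from the average rate by default — the
within-trial ratio is the literal MVT reading — with `include_travel`
available for the alternative. The record at pick 1 (whose previous
event is the onset) exists but never enters ROC decision sets, which
start at $n = 3$.

## Composite organization scores

The four indicators are condensed into a single score in three steps,
fitted separately within each analysis stratum (by default each
condition, optionally crossed with age group):

1. **Standardization.** Each indicator is z-scored against the
   population of *all* trial-so-far instances in the stratum (not just
   end-of-trial values); the reference means and SDs are recorded for
   audit. Flagged-degenerate rows are excluded from the reference
   statistics.
2. **Dimensionality.** Horn's parallel analysis on the end-of-trial
   values (one row per trial, keeping observations independent):
   observed correlation-matrix eigenvalues are reduced by the mean
   excess over 1 of eigenvalues from random standard-normal data of the
   same shape (500 replicates, seeded and reproducible), and the
   leading run of adjusted eigenvalues above 1 is retained. PCA on the
   same table gives the first-component loadings (eigenvector scaled by
   $\sqrt{\lambda_1}$, oriented so best-r loads positively) and the
   variance share $100\,\lambda_1 / 4$.
3. **Composition.** The weighted composite is
   $$C_w = w_{br} z_{br} - w_{itd} z_{itd} - w_{pao} z_{pao} - w_{int} z_{int},$$
   with $w$ the *magnitudes* of the first-component loadings: the sign
   structure is fixed by the formula itself (lower mean ITD, PAO and
   intersection rate mean higher organization; best-r reads directly),
   so signed loadings would apply direction twice, and the overall
   component orientation is arbitrary anyway. The unweighted composite
   sets all $w = 1$. Whether one uses loadings or raw eigenvector
   coefficients only rescales $C_w$ by a positive constant, which
   leaves every ROC result unchanged. Higher values of either composite
   mean more organized search, and both average exactly zero over their
   standardization population.

## ROC analysis

The positive class is *leave*: sensitivity is the proportion of leave
decisions predicted correctly, specificity the proportion of stay
decisions. Curves place thresholds at midpoints between adjacent
distinct predictor values (with infinite sentinels), so the AUC of the
curve equals the Mann–Whitney concordance probability exactly — the
test suite checks this identity against brute-force pair counting on
hundreds of random datasets. Default polarities encode the science:
leaving is predicted by *low* composite, best-r and RIAIR and by *high*
mean ITD, PAO and intersection rate; `polarity = "auto"` picks the
direction with AUC ≥ 0.5. The optimal threshold maximizes Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$, with ties broken toward the
more sensitive point (stable under input reordering). Per-predictor
AUC intervals use the DeLong placement-value variance; combined curves
(below) use the Hanley–McNeil standard error, which needs only the AUC
and the class sizes. No smoothing is applied anywhere in computation.

## Combining two predictors

The composite tends to predict leaving well (sensitivity) and the
RIAIR staying (specificity), which motivates a compound criterion. For
each pair of operating points — one per curve, thinned to at most 201
thresholds each to bound the sweep — the two binary tests define four
joint outcomes. Under class-conditional independence their likelihood
ratios are determined by the two sensitivities and specificities, and
sweeping a threshold over those likelihood ratios yields the achievable
compound points, which are always of the form single-predictor, AND, or
OR rules. The combined curve is the upper-left Pareto envelope of all
achievable points, each annotated with its realizing rule (e.g.
`composite < -0.1 OR riair < 0.5`).

Two numerical choices matter here. First, the envelope is integrated
as a *staircase* (trapezoid rule over the achievable step function,
with explicit step corners): interpolating straight lines across
dominated points would credit the combination with operating points no
deterministic rule can reach, and would make combining with a useless
predictor appear to help. With the staircase, combining any curve with
an uninformative one reproduces the informative curve's AUC exactly,
and the combined AUC can never fall below either parent's. Second,
because the printed compound rules are data-level statements, an
`empirical` mode is also provided that evaluates AND/OR rules directly
on the stored predictor values over the threshold grid, with no
independence assumption; it is the mode of choice when the two
predictors' errors may be correlated.

## The simulator

`simulate_trial()` and `simulate_session()` generate event logs with
the statistical structure the analysis assumes, under the task
conditions the pipeline is meant for: a 1400 × 1500 px arena; set sizes
of 40–180 items; a target proportion drawn uniformly in [0.20, 0.30]
per trial; item speeds of 0, 44 or 88 px/s with directions redrawn at
intervals uniform in [0.5, 2] s and reflection at the walls; and a 2 s
travel cost recorded as session metadata. Agents collect targets by
nearest-neighbor, scanner (reading order with positional noise), or
random strategies, with a `disorder` parameter mixing in uniform-random
picks; pick time is $(0.3\,\mathrm{s} + d / 1000\,\mathrm{px\,s^{-1}})$
scaled by lognormal noise (log-SD 0.2) — a simple Fitts-like model
whose only purpose is that intake slows as targets deplete and
distances grow. Quitting rules: strict MVT (`rule_mvt(theta)`, leave at
the first pick past the minimum whose RIAIR falls below `theta`),
giving-up time, fixed count, and random. Ground truth (configs, seeds,
per-pick rule evaluations) is returned alongside every log, and
identical seeds give byte-identical logs.

The simulator reproduces what the analysis needs — organized-to-
disorganized collection gradients, declining intake with depletion,
parameterized quitting — and nothing more. It does not model human
reaction-time distributions, memory load, target-type confusions, or
developmental differences, so a passing recovery test shows the
pipeline's statistical machinery is sound, not that any psychological
claim about real foragers is true.

## What the tests establish

The test suite and the acceptance script verify, among other things:
exact agreement of ROC AUCs with Mann–Whitney counting; the heuristic
path solver never undercutting and almost always matching the exact
solver; perfect and chance-level predictors hitting AUC 1 and ~0.5;
strict-MVT agents producing leave decisions with recomputed RIAIR ≤ 1
and a pooled Youden-optimal RIAIR threshold within 0.2 of 1 (30 agents
× 40 trials); parallel analysis retaining exactly one component for
four noisy proxies of a latent factor, with the weighted composite
recovering the factor at $|r| > 0.9$; combination never hurting for
independent informative predictors across 20 seeds; and mean composite
scores strictly rank-ordered by agent disorder across five levels of
$\varepsilon$ (30 trials per level). Problem sizes were chosen so the
whole suite runs in about a minute on one CPU while leaving the
stochastic checks comfortable margins.

## Known limitations

* Decisions are pooled within a stratum without participant random
  effects; the non-independence of decisions from the same trial or
  forager is acknowledged, not modeled.
* The per-pair likelihood-ratio sweep under independence and the
  empirical AND/OR grid are two defensible readings of two-test
  combination; both are implemented, and they can differ when the
  predictors' errors are dependent.
* The exact optimal path is capped (by default) at 13 points; beyond
  that, PAO rests on a strong but inexact heuristic that can only bias
  PAO downward, and in practice agrees with the exact solution on
  \>99% of small instances.
* Horn's retention decision sits exactly at its boundary for pure
  noise data, so retaining 0 vs 1 component there is a coin flip; the
  package reports the adjusted eigenvalues so the margin is visible.
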