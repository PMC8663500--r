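---
title: "Rating patients and tasks in web-based cognitive rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating patients and tasks in web-based cognitive rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabElo)
```

## The model

Web-based cognitive rehabilitation platforms confront a matching problem:
the benefit of a training task depends on the ratio between the patient's
current skill and the challenge the task poses, and neither is directly
observable. rehabElo treats this as a paired-comparison problem. Every
execution of a task is a *match* between two rated players — the patient
and the task — decided by the 0–100 compliance result the platform
reports after the execution. Rating both sides with an Elo-family system
then yields, after a handful of sessions, a skill estimate for each
patient *and* an empirical difficulty for each task configuration, on the
same scale.

Given ratings $\theta_i$ and $\theta_j$, the expected score of player
$i$ is the logistic

$$E_{ij} = \frac{1}{1 + 10^{(\theta_j - \theta_i)/400}},$$

and the plain Elo engine updates $\theta_i \leftarrow \theta_i +
K\sum_j (R_{ij} - E_{ij})$ over all of $i$'s matches in a rating period,
where $R_{ij} \in \{0, \tfrac12, 1\}$ is the observed score. Three
extensions are provided:

* **Glicko** attaches a *rating deviation* (RD) to every player — the
  standard error of the rating. Opponents with uncertain ratings move you
  less; playing shrinks your RD; at the onset of every period each RD is
  inflated to $\min(\sqrt{RD^2 + c^2}, 350)$, so inactivity slowly
  restores uncertainty. The engine inflates every state it is handed,
  not only idle players: one period elapses for everyone. The update is
  the published closed form with $q = \ln 10 / 400$.
* **Glicko-2** adds a per-player *volatility* $\sigma$, the expected
  drift of true strength between periods. The update runs on the
  internal scale $\mu = (\theta - \theta_0)/(400/\ln 10)$ and solves for
  the new volatility with a bracketed Illinois iteration (tolerance
  $10^{-6}$, at most 100 iterations; non-convergence raises a numerical
  error with diagnostics rather than returning silently).
* **Stephenson** augments the Glicko update with three tunables: a
  per-game addition $h$ to the prior rating variance, a per-game bonus
  $b$ for simply playing, and a pull of $\lambda$ percent toward the mean
  pre-period opponent rating. The cited formulations of this system are
  not fully specified in the literature we could reproduce, so the
  package defines it by exactly these three augmentations; with
  $h = b = \lambda = 0$ it degenerates to Glicko *bit-for-bit*, which is
  asserted in the test suite at relative tolerance $10^{-9}$.

All engines use **batch rating-period semantics**: within a period every
update is computed from pre-period opponent states, so permuting matches
inside a period cannot change the result. This is Glicko's definition
and the only semantics under which two players with identical records in
identical periods provably end identical — a property the feasibility
leaderboard (two undefeated players sharing one rating) visibly relies
on.

### Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `initial_rating` | 2200 | starting rating of every player (patients and tasks) |
| `initial_deviation` | 300 | starting RD, rating points |
| `k_factor` | 27 | Elo step size per unit of surprise |
| `c_inflation` | 15 | RD growth per period, rating points |
| `tau` | 0.5 | Glicko-2 volatility constraint |
| `initial_volatility` | 0.06 | Glicko-2 starting $\sigma$ |
| `h_param`, `b_param`, `lambda_param` | 10, 0, 2 | Stephenson extras |
| `deviation_cap` | 350 | upper bound on any RD |

These are the conventional defaults of Elo-family implementations on the
chess-like 2200/400 scale and are the values under which the
feasibility leaderboard in this package reproduces the published one
(undefeated players near 2565, the task near 1999 after losing 282 of
400). No K optimisation is attempted; K stays at its default throughout.

## From executions to matches

`score_execution()` maps a compliance result to a score. The cohort rule
is: result $\le 39$ — the task wins; $40 \le$ result $\le 64$ — draw;
result $\ge 65$ — the patient wins. The bands are stated on integers;
non-integer results falling strictly inside $(39,40)$ or $(64,65)$ are
resolved by a configurable `boundary_policy` (default: draw, the
conservative choice). The feasibility rule has no draw band: above 50
wins, below 50 loses, and exactly 50 — an event the band definition never
mentions — defaults to a loss for the patient.

`build_match_log()` chooses the rating-period and opponent granularity.
Cohort runs default to one period per *session* (the natural clinical
batch: ratings change between visits, not within one sitting) and to
`task_by_difficulty` opponents, because the same task at a harder
parameter configuration is a genuinely stronger opponent. The
feasibility fixture uses one period per execution round, which is the
only structure consistent with its published leaderboard (two players
with the same 18–2 record but different ratings cannot arise in a single
period under batch semantics).

`truncate_first_n()` (default n = 50) restricts rating to each
patient's earliest executions — at roughly nine executions per session,
about five sessions or two weeks of data — so the stratification is
available early enough to steer therapy. `filter_frequent_tasks()`
implements both defensible readings of "drop rarely executed tasks": a
coverage mode (smallest prefix of tasks, by descending execution count,
reaching a coverage fraction) and a minimum-count mode; the filter
report carries the retained fractions to two decimals.

## Stratification and outcome models

`stratify_terciles()` splits patients into low/mid/high thirds by rating
rank; with $N$ not divisible by 3 the extras go to the lowest group(s)
first — a documented convention, since only the divisible case occurs in
the motivating cohort (288 = 3 × 96). Because only ranks matter, any
strictly increasing transform of the ratings leaves the groups
unchanged.

`group_summary()` reproduces the stratified-report layout: assessment
means (SD) per group, improvement proportions (RAVLT learning total
gain ≥ 5; delayed recall, recognition and digit span gain ≥ 1), mean
executed tasks and results, and the difficulty-level cross-tab.
Continuous rows are compared with one-way ANOVA and categorical rows
with Pearson's chi-square without continuity correction — the sources
this layout follows report per-row *P* values without naming the tests,
so both choices are recorded here as assumptions, and no multiplicity
correction is applied across rows.

`forward_stepwise()` adds candidates greedily, maximising adjusted
$R^2$ (linear) or AUC (logistic), stopping when no candidate improves
the criterion by more than $10^{-6}$; a p-value entry rule is *not*
used because the selection criterion, not an entry threshold, is what
the motivating analysis states. Standardized coefficients come from
refitting on z-scored variables. Diagnostics follow the conventions of
clinical prediction reports: VIF and tolerance (= 1/VIF, flagged at
$\le 0.40$), the Durbin–Watson statistic
$d = \sum_{t\ge2}(e_t - e_{t-1})^2 / \sum e_t^2$, and for logistic
models the Mann–Whitney (rank) AUC with a DeLong-type normal CI plus
accuracy, sensitivity and specificity at threshold 0.5 (configurable).
Whether the motivating analysis used DeLong or bootstrap intervals is
unstated; DeLong is the deterministic choice. Internal validation is
available as an optional k-fold cross-validated criterion (off by
default). `ablation_compare()` reports the criterion drop when the
rating covariate is withheld — the quantity that makes the case that
early ratings carry prognostic information.

## What the synthetic generator emulates — and what it does not

No clinical data ship with the package; two seeded generators make every
stage runnable and testable.

`generate_feasibility_case()` rebuilds the 20-patient × 20-round maze
exercise from its printed win/loss records. Loss rounds are placed
uniformly at random; results are drawn from truncated normals centred at
30/55/80 (SD 12) for the low/mid/high compliance groups, restricted to
the winning (>50) or losing (<50) side so the induced record is exact
for every seed. Only the side of 50 is contract-bearing; the centres
merely mimic the published compliance boxplots qualitatively. One
consequence worth knowing: because loss *timing* is random, the final
ordering of players with adjacent records (17–3 vs 16–4) across
compliance groups can occasionally invert — in about 2% of placements a
mid-group player edges past the weakest high-group player. The grouped
ordering printed in the original single run is therefore a
high-probability property of the simulation, not a certainty.

`generate_cohort()` draws a full cohort (default 288 patients, 68
tasks, mean 155 executions per patient, SD 113.2, floored at 50). Each
patient has a latent skill on the rating scale, drawn per compliance
stratum ($2200 + s\,(-1.5, 0, +1.5)$ with within-stratum SD $0.5s$,
where $s$ = `skill_sd`, default 130); tasks carry latent difficulties
$2200 + (\text{level}-2)\times 150$ plus jitter. Every result is
$\mathrm{clip}(100\,E(\text{skill}, \text{difficulty}) + \varepsilon)$
with the *same* logistic the engines use — deliberately, so the rating
systems are correctly-specified estimators of skill and parameter
recovery is a fair test of the implementation rather than of model
mismatch. Admission memory scores are linear in standardized skill;
discharge adds a gain increasing in skill and length of stay, with
coefficients calibrated once so the improvement base rates sit near 51%
(RAVLT learning, gain ≥ 5) and 34% (digit span, gain ≥ 1). The
`signal` presets give a strong-separation cohort (`skill_sd` 250, low
result noise) and an exchangeable null (`skill_sd` 0), used by the
recovery tests: Spearman correlation between true skill and first-50
Stephenson ratings above 0.7 on defaults, tercile agreement above 0.8
under the strong preset and at chance (≈ 1/3) under the null.

Features of real data the generator does *not* emulate: adaptive task
assignment (tasks are drawn uniformly, so the difficulty-level mix is
flat across rating groups rather than assortative as in a clinic),
within-stay learning curves (results are stationary given skill),
missing assessments, and any covariate structure beyond the fields the
models use. Passing tests therefore demonstrate that the pipeline
recovers structure it is designed to see, not that real rehabilitation
data satisfy these models.

## Numerical and design notes

* Problem sizes in the tests: 50 seeded placements for the feasibility
  averages; 20 seeds × 288 patients for the recovery checks, rating
  each cohort on its first 50 executions (~14,400 matches per run).
* Leaderboards sort by rating descending with player-id tie-break;
  tercile ties likewise break by id — all outputs are reproducible
  byte-for-byte from a seed.
* Degenerate inputs fail loudly with typed conditions
  (`rehabElo_input_error`, `rehabElo_numeric_error`), which the
  command-line wrapper maps to distinct exit codes (2 and 3).
* The Glicko worked-example oracle is exercised with `c_inflation = 0`
  so the single-period closed form is exact; with the default c = 15
  the onset inflation shifts the example by under half a rating point.
* All randomness flows from one explicit seed per generator call and is
  consumed in a fixed order; identical seeds give identical files.

## Limitations

The cohort-scale numerical results of the motivating study (its
regression coefficients, $R^2$ = 0.54/0.43, AUC = 0.73/0.81) depend on
clinical data that were never deposited and are not reproduced here;
the package validates against the self-contained feasibility exercise
and property-based checks instead. Win/draw/loss thresholds are global
rather than per-task, K is fixed, and no streaming (per-match) rating
variant is provided beyond period batching.
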