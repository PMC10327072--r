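---
title: "Modelling choice inclusivity with a collapsing-bound LCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice inclusivity with a collapsing-bound LCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicelca)
```

## The scientific question

When people pick one item from a set, choosing it excludes the rest. Framing
the same decision *inclusively* — you may keep selecting further items
afterwards, as at a buffet — empirically makes the first choice faster at
little cost in accuracy, and makes it feel less conflicting. Two mechanisms
could produce faster choices: a relaxation of the *competition* between
candidate responses, or a lowering of the *decision threshold* (urgency).
These mechanisms leave different fingerprints on how reaction time (RT) and
accuracy depend on the values of the options, so they can be told apart by
simulation. `choicelca` packages the full machinery for doing so: the
accumulator model, a generator of complete synthetic studies, the
mixed-effects regression battery, and the simulate–regress–compare
identification step.

## The model

Each of the four options drives its own leaky accumulator. With inputs
$V_i$ (liking ratings on a 0–10 scale), the activations evolve as

$$
dy_i = \left(-k\,y_i - k\,m \sum_{j \ne i} y_j + g\,V_i\right) dt
       + c\,\sqrt{dt}\,\varepsilon_i ,
$$

with $y_i(0) = 0$, per-step rectification $y_i \leftarrow \max(y_i, 0)$,
and a decision boundary that starts at $a$ and collapses as
$a\,e^{-\beta t}$. The first accumulator to reach the boundary determines
the choice and the RT; if none crosses before `t_max` the trial is an
omission. The parameters:

| parameter | meaning | default |
|---|---|---|
| `k` | leak, per unit time | 1 |
| `m` | mutual inhibition as a ratio to the leak | 0.8 (exclusive) |
| `g` | input gain on the ratings | 0.25 |
| `c` | noise scale (SD per $\sqrt{\text{unit time}}$) | 0.8 |
| `a` | initial boundary | 3 |
| `beta` | collapse rate, per unit time | 0.25 |
| `dt` | Euler–Maruyama step | 0.001 |
| `t_max` | horizon | 10 |

Inclusivity is operationalised as lower mutual inhibition (`m` 0.8 → 0.3,
all else shared); urgency as a lower initial bound and faster collapse
(`a` 3 → 1.8, `beta` 0.25 → 0.55).

### Why these defaults

The literature this model family comes from does not pin down `g`, `c`,
the collapse form, or the integration step, so these were fixed once, on
two grounds. First, realism of the baseline (exclusive) condition:
simulated first choices average about 2.9 time units with accuracy near
0.5 against a 0.25 chance level and essentially no omissions, matching
the order of magnitude reported for four-alternative product choices, so
simulation time can be read as seconds. Second, the regime must actually
express the dissociation the design turns on: with partial competition
($m < 1$: rivals are suppressed but not silenced) and crossings governed
by the collapsing bound, higher overall value both speeds the winner
(through $g V$) and slows it (through value-dependent inhibition from its
rivals). Lowering `m` removes the slowing channel, which is why the
overall-value speeding effect *strengthens* when inhibition drops, while
lowering `a` simply compresses all RTs and attenuates every value effect.
In strongly winner-take-all regimes ($m \gg 1$ with losers rectified to
zero) that inhibition channel is absent and the two manipulations become
much harder to tell apart; this is a property of the model worth knowing
when mapping the package onto other datasets.

Exponential collapse was chosen over linear because it keeps the bound
strictly positive and recovers a fixed bound at `beta = 0`; a linear
variant is available via `collapse = "linear"`. Rectification at zero
follows the standard formulation of competing accumulators. There is no
non-decision time parameter.

## What the synthetic-data generator emulates

`generate_study()` produces a complete study: per participant, a catalog
of product ratings (uniform on the 0–10 analog scale), a constrained
session of four-product choice sets, LCA-driven first choices, conflict
ratings, and voluntary subsequent (de)selections.

Choice sets are built the way the task builds them: overall value (OV)
drawn uniformly on $[0,10]$; the best option uniformly on
$[\mathrm{OV}, \min(10, 4\,\mathrm{OV})]$; the remaining three values
sampled to satisfy the mean constraint exactly (two uniform draws on
$[0, \text{best}]$, the third fixed by the constraint, resampling on
infeasibility — the source procedure does not fully specify this step).
Sessions respect three hard constraints — no product more than 3 times,
never on consecutive trials, no duplicate four-product sets — and match
OV/relative-value (RV) distributions across conditions by realising each
sampled target set once per condition with different products.

Conflict ratings come from a generative model that is U-shaped in OV
(quadratic term positive), decreasing in RV, lower under inclusivity,
with an inclusivity-by-OV interaction whose default sign flips between
selection framing (negative: inclusivity relieves conflict most for
high-value sets) and removal framing (positive), echoing the empirical
pattern. Ratings are continuous, then rounded and clamped to the 1–5
scale; the discretisation is treated as extra noise, which is accurate
away from the scale ends. Voluntary keeps follow a sigmoid rule with
indifference point at the participant's global mean rating and
temperature 0.8 rating units (temperature → 0 recovers the hard
threshold rule).

What the generator does *not* emulate: within-session learning or
satiation, product-category structure, response devices, and any
participant heterogeneity in the LCA parameters themselves (all regular
participants share the condition parameters; heterogeneity enters through
the ratings and the stochastic accumulation). Passing tests therefore
show that the pipeline recovers what it plants under its own assumptions,
not that those assumptions hold of any particular dataset.

## The regression battery

`fit_rt_model()`, `fit_accuracy_model()`, `fit_conflict_model()` and
`fit_voluntary_models()` mirror the analysis specifications: linear or
logistic mixed models (via `lme4`) of RT, first-choice accuracy, conflict
and the four voluntary-choice analyses, each with the two-level condition
coded as a −0.5/+0.5 successive-differences contrast (so the intercept is
the grand mean), OV either linear or as orthogonal polynomials (conflict
models), RV as the framing-relevant value gap, condition-by-value
interactions, and trial order standardised within participant.

Numerical policy, fixed once:

* Random effects default to participant intercepts plus slopes for every
  fixed predictor, with a convergence ladder — correlated slopes,
  uncorrelated slopes (`||`), intercept only — stepping down on error,
  non-convergence or singularity; the rung used is recorded in the
  table's metadata.
* Intervals are Wald-type 95% intervals and p-values two-sided Wald z
  tests, applied uniformly to linear and logistic fits.
* Omitted trials are dropped from RT and accuracy models and counted only
  for the urgency-omission exclusion rule.
* Near-constant predictors are dropped and reported as inestimable;
  degenerate responses (all-accurate, constant counts) yield flagged
  tables rather than errors, with a weakly regularised logistic fallback
  for separation.
* The per-product keep model excludes the option acted on first, whose
  fate is forced by the framing rather than chosen.
* Counts of selections/removals are modelled linearly, not as Poisson,
  matching the source analyses.

Participant-level exclusions (`apply_exclusions()`): rating SD outside
(1, 5); easy-trial accuracy below 25% (easy = RV above the participant's
median); conflict-rating SD below 0.5; and, where a high-urgency
condition exists, a high-urgency omission rate of 40% or more.

## Model identification

`signature_scan()` manipulates one parameter, re-simulates, refits the
RT/accuracy regressions (without random effects — simulated trials are
exchangeable), and classifies each quantity's change. A change is
reported only when it is both beyond Monte-Carlo error (3 standard errors
of the first-vs-last difference) *and* material (at least 10% of the
larger absolute estimate); otherwise `~unchanged`. The 3-SE gate keeps
the per-scan false-change rate low enough for classifications to be
stable across seeds; the 10% gate stops arbitrarily large simulations
from elevating trivia into signatures.

`fit_grid()` scores each grid point by the sum of squared differences
between simulated and target coefficients after z-standardising each
coefficient across grid points, so RT slopes, log-odds and means
contribute comparably. `compare_mechanisms()` evaluates an
inhibition-varying family against a boundary-varying family, pooling the
standardisation across both grids so the two best losses are directly
comparable, and reports the winning family with per-coefficient
residuals. Identification stages default to a coarser integration step
(`dt = 0.005` in the pipeline) than behavioral simulation; the
qualitative signatures are insensitive to this, and it keeps grid
searches tractable on a desktop.

Problem sizes used by the shipped checks (chosen for desk-scale
replication): signature scans use a fixed 12-set OV×RV evaluation grid at
1000 iterations per set and level; mechanism discrimination and
two-condition recovery use 20 replicates over 8 evaluation sets with
compact per-condition grids; coefficient-recovery checks use 30–40
replicate studies of 20 participants × 60 trials generated directly from
the fitted model forms, with coverage judged against a three-sigma
binomial band around 95% with the replicate count as the effective n
(checks within a replicate are correlated, so this is the conservative
choice).

## A worked run

```{r example, eval = FALSE}
design <- design_spec(n_participants = 8, trials_per_condition = 40)
study <- generate_study(design, seed = 21)
kept <- apply_exclusions(study$trials, study$ratings)

summarize_condition_means(kept$trials, seed = 1)
fit_rt_model(kept$trials)
autoplot(fit_conflict_model(kept$trials))

scan <- signature_scan(lca_params(dt = 0.01), "m", c(0.8, 0.3),
                       n_iter = 1000, seed = 1)
scan$profile
```

## Known limitations

* Parameter identification is by grid search against regression
  signatures, as in the source procedure; there is no likelihood-based
  fitting, and the loss surface inherits Monte-Carlo noise from the
  simulated coefficients.
* Wald intervals from `lme4` are mildly anti-conservative with few
  participants; profile or bootstrap intervals are out of scope.
* The count sub-models of the voluntary battery are linear approximations
  to a bounded count (0–4); their planted-coefficient recovery is checked
  qualitatively, while quantitative coverage is asserted for the
  per-product keep model whose generative form matches the fit.
* The dissociation between inhibition and boundary manipulations is a
  property of the partial-competition, collapse-dominated regime the
  defaults encode; it should not be assumed to transfer to arbitrary
  parameter regimes.
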