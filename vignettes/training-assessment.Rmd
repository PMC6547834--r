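---
title: "Assessing bypass-prosthesis training: scoring, learning curves, and prepositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing bypass-prosthesis training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bypasstrain)
```

## The problem

Bypass prostheses let able-bodied volunteers operate a prosthetic terminal
device, which makes controlled prosthesis research feasible — but only
after the volunteers have been trained. Two training decisions lack
objective guidance: how many sessions are enough, and whether coaching
users to *preposition* (manually rotate the terminal device into a
favourable orientation before a task) measurably improves performance.
`bypasstrain` turns per-session assessment logs into answers to both.

## Scoring model

Each mSHAP task attempt is timed and scaled linearly between two
boundaries taken from a normative data set: the average normative time
$n$ (scoring 100, "normal function") and $m = 8n$ (scoring 0, "minimal
function"):

$$T_s(t) = 100\,\frac{m - t}{m - n}.$$

Times outside $[n, m]$ are clamped to keep scores in $[0, 100]$; whether
super-normative times should exceed 100 is an open question in the
original assessment, and clamping is the choice consistent with a 0–100
scale. Failed attempts (DNF) score 0.

Task scores are averaged within each prehensile pattern into a linear
index of functionality (LIF), and the six LIFs are combined into the
weighted summary index

$$wLIF = \tfrac{1}{25}\left(3\,LIF_{sph} + 3\,LIF_{tri} + 6\,LIF_{pow}
 + 5\,LIF_{lat} + 5\,LIF_{tip} + 3\,LIF_{ext}\right),$$

the weights being pattern membership counts. Because the battery has 22
tasks but the counts sum to 25, some everyday tasks must load more than
one pattern. The 12 abstract tasks map by name; the 10 everyday tasks use
a packaged default mapping (`default_task_patterns()`) chosen so the
counts come out 3, 3, 6, 5, 5, 3 — a documented convention, overridable
per study. Likewise the normative boundaries are not published alongside
the battery; `default_bounds()` ships illustrative values (in seconds)
and real analyses should supply their own table.

BBT sessions are scored as the mean blocks/minute over the recorded
trials (normally three); a session with a missed trial is averaged over
what exists rather than dropped.

## Learning curves and the training endpoint

Session score series are fit to the inverse curve

$$Y = a - \frac{b}{X},$$

with plateau $a$ (score units), rate $b$ (score units; the session-1 to
session-∞ gain is exactly $b$), and $X$ the administration index. Because
the model is linear in $\{1, 1/X\}$, the least-squares fit is computed
exactly by linear regression — deterministic, with no initialisation or
convergence concerns, and identical to what iterative nonlinear
optimisation of the same model would return (the test suite checks this
against a brute-force grid-refinement oracle).

Numerical conventions:

* A constant series has $SS_{tot} = 0$; the fit returns $b = 0$ and
  reports $R^2$ as `NA` (undefined) rather than 1.
* The endpoint is the smallest integer $X$ with $a - b/X \ge 0.9a$, i.e.
  $\lceil b / (0.1\,a) \rceil$; the ceiling is taken with a $10^{-9}$
  tolerance so ratios that are exactly integral do not round up through
  floating-point error. Non-positive $b$ gives endpoint 1. The 0.9
  fraction is a tunable argument (`endpoint_fraction`).
* Measures not administered from session 1 carry an explicit
  `session_offset`: the BBT runs on sessions 2–10, so its administration
  indexes 1–9 map to sessions 2–10 and its endpoint is reported on the
  session scale (offset 1). This reconciles, e.g., a BBT fit with
  $\lceil b/(0.1a)\rceil = 5$ administrations with a six-session
  endpoint.

Per-category fits (`fit_score_table()`) default to fitting the
cross-subject session means, which matches how grouped fit tables are
usually reported; `pooled = TRUE` fits all individual subject-session
points instead. Both pathways are exposed because published analyses are
often ambiguous between them.

## Session effect sizes

The effect of session $i$ is the mean of the per-subject paired
differences $Y_i - Y_{i-1}$ divided by the standard deviation of those
differences. The SD uses the $n-1$ sample denominator by default
("group SD" conventions differ; `sd_denominator = "n"` switches).
Magnitudes follow the conventional thresholds — negative, then
negligible $[0, 0.2)$, small $[0.2, 0.5)$, medium $[0.5, 0.8)$, large
$\ge 0.8$. Zero-variance differences leave the effect size undefined
(flagged, not an error), and unpaired subjects are dropped with a
warning.

## Prepositioning analysis

Orientation is recorded per task as a quadrant code 1–4 (boundary calls
are resolved at recording time; the pipeline accepts only integer
codes). The per-assessment quadrant-change count $Q$ — adjacent task
pairs with differing codes — is the proxy for prepositioning use. wLIF
scores are centred on their session mean (so each session's centred
scores sum to zero and training stage is removed), pooled across
subjects and sessions by $Q$, averaged within each $Q$, and the group
means regressed on $Q$ by ordinary least squares.

The regression is unweighted by default — each group mean counts once,
matching how such grouped plots are usually fit — with a count-weighted
option. Slope, Pearson $r$, and $R^2$ are all reported: a single
"correlation" number is ambiguous between them, and the three answer
different questions (direction and size of the trend per change;
strength of linear association; variance explained).

## The synthetic cohort generator

`generate_cohort()` draws, per subject, a plateau and rate around
population values, builds each session's target wLIF as
$a_i - b_i/X$ plus Gaussian noise (clamped to $[0, 100]$), back-solves
each task's time through the inverse of the scoring map, and multiplies
by mean-one lognormal jitter so times stay positive and re-scoring
reproduces the target in expectation. DNF events occur with a
probability that decays geometrically across sessions (failures vanish
as skill grows); BBT counts come from a second inverse curve on
administrations 1–9 with per-trial noise, rounded to nonnegative
integers; quadrant sequences follow a Markov switch process with a
subject-level switch propensity, independent of performance.

Defaults are the study conditions the package emulates: 6 subjects, 10
sessions, population plateau/rate 79.75/22.09 (wLIF) and 37.21/15.91
(BBT) — reported fitted values for such a cohort — with dispersion set
once to realistic levels: session noise SD 3, subject-level plateau/rate
SDs 8/6 so the session-1 between-subject SD is near the reported ~11.5,
BBT subject SDs 3/2 and trial noise 2 (early-session spread ≈ 4.5
blocks), DNF probability 0.15 halving per session, switch propensity
0.3 ± 0.15.

What the generator does *not* emulate: scheduling gaps between sessions
(and any forgetting across them), coaching effects, within-session
fatigue, task-specific learning rates, or any dependence of
prepositioning on performance. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers the structure it
assumes — not that real training data satisfies those assumptions.

Clamping and DNFs make the generator's early sessions slightly harder
than the bare curve, so fitted rates on default cohorts exceed the
population rate; the plateau, dominated by late sessions where DNFs have
decayed away, is recovered with small bias (the recovery test bounds the
mean recovered plateau within ±2 score units over 1000 cohorts).

## Problem sizes and runtimes

The test suite fits: 1000 noiseless random curves, 50 grid-oracle
comparisons, 1000 default synthetic cohorts for plateau recovery, and
200 cohorts for the null-prepositioning slope check — sizes chosen to
make the stochastic checks stable at fixed seeds while the whole suite
runs in minutes on a single core.

## Worked fixture

`generate_worked_fixture()` builds a 2-subject × 3-session × 4-task
dataset whose scores are hand-checkable: task times are chosen so each
subject's tasks score a common round value per session, one DNF zeroes
the tripod pattern in subject S01's first session
($wLIF = 880/25 = 35.2$), and the session-2 effect size is
$22.4 / (2.4\sqrt{2}) = 14\sqrt{2}/3 \approx 6.600$. The same tables
ship as CSV under `inst/extdata/` together with the expected scoring
output, and the tests require byte-identical regeneration.

## Known limitations

* The default normative bounds and task–pattern mapping are
  conventions, not published normative data; study-specific tables
  should replace them.
* With six subjects, grouped prepositioning regressions are noisy; the
  package reports standard errors per group but draws no inferential
  conclusion, and a curvilinear (e.g. parabolic) relationship is out of
  scope.
* Mixed-effects longitudinal models and alternative learning-curve
  families (exponential, power law) are deliberate non-goals; the
  inverse curve is the model of record here.
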