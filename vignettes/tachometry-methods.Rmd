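---
title: "Methods: tachometric curves, selection history, and the conditional-independence interaction test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tachometric curves, selection history, and the conditional-independence interaction test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tachometry)
```

## The task and its data model

In an urgent oddball search the go signal precedes the color cue by a Gap of
0–225 ms and the saccade must land within 450 ms of the go signal. The only
time that can inform the choice is the processing time, PT = RT − Gap, which
is negative whenever the saccade is launched before the cue appears — such
trials are legitimate, fully uninformed choices and are always retained. A
trial table carries one row per trial (subject, session, within-session
index, Gap, RT, PT, target color, target and chosen quadrant, outcome);
`validate_trials()` enforces the exact identity PT = RT − Gap and the
consistency of the outcome flag with the two quadrants, and `load_trials()`
re-derives PT after parsing so the identity holds exactly for every loaded
record even when the file's printed precision is finite. Positions given in
degrees of visual angle map to the four quadrant labels by half-open
90° sectors anchored counter-clockwise on the axes (positive x axis →
`right`, positive y axis → `up`, and so on), which reproduces the axis
conventions of the field with no gaps or overlaps; the origin has no
quadrant and is rejected.

## Tachometric estimation

`compute_tachometric()` counts trials in bins of width 50 ms whose centers
advance every 1 ms. Bins are half-open, [c − w/2, c + w/2), so every trial
falls in exactly w/step consecutive bins and merged trial sets aggregate
additively. Empty bins are carried as missing — never as zero accuracy — and
are not interpolated. Per-bin uncertainty uses the Agresti–Coull interval,
which is well-behaved at the small counts that occur in the tails of the PT
distribution; a resampling band is available through `resample_compare()`
when a distribution-free comparison is wanted.

The scalar summaries are binning-free: floor accuracy is the proportion
correct over trials with PT strictly below 100 ms, ceiling accuracy over
trials strictly above 150 ms. The 100–150 ms transition band belongs to
neither — the cutoffs are compared as real numbers with no rounding rule.
Difference curves between S- and D-conditioned curves subtract per-bin
fractions and pool the binomial standard errors in quadrature; bins
undefined in either input stay undefined.

`resample_compare()` is a percentile bootstrap over trials, resampled with
replacement within each group (10,000 resamples by default); the two-sided
p-value uses the add-one rule so it is never exactly zero, and a seed is
mandatory — there is no silent global-RNG path.

## Selection-history classification

Two labeling schemes coexist because they answer different questions and
differ for depths above one:

* **Run mode** ("at least N"): a trial is NS when its N immediately
  preceding same-session trials all share its target color (or quadrant),
  ND when every one of them differs from it — for locations the
  predecessors need not match one another — and NC/NE for all-correct /
  all-error runs. Nesting holds by construction: (N+1)S ⊆ NS. Joint labels
  (1SC, 2DE, 1SSC, …) conjoin the per-dimension conditions over the same
  window.
* **Sequence mode**: each of the H preceding trials carries its own
  relation letter per dimension, so color×location at H = 2 yields 16
  distinct labels. This is the labeling the interaction analysis consumes.

Histories never cross session boundaries. Overnight carry-over is not
measurable from a within-session design and would contaminate the lag
analyses, so trials with fewer than the required within-session predecessors
belong to no condition. Histories are computed on the same validity-filtered
trial stream that enters the analyses; if a study design demands that
discarded trials still count as history events, classify before filtering —
the functions only assume ordered rows within each session. Single-event
conditions (`classify_single_event()`, the 1S(N−1)x / 1D(N−1)x families)
constrain exactly one past trial and leave the intervening ones free, which
is what makes the decay timescale of a single repeat or switch measurable.

Every classifier is checked against a brute-force oracle that materializes
each predecessor window explicitly, over a thousand random sessions.

## Cross-subject alignment

Two subjects rarely share the same PT scale. `align_curves()` transforms one
curve as z(j) = g·y₂(j + δ) + b and minimizes the mean absolute deviation
from the reference over the overlapping defined bins. The objective is
deliberately L1 — robust to the ragged tails of real tachometric curves —
and is therefore piecewise-linear and non-smooth, so the search is an
exhaustive grid over δ at the grid step and over g (0.5–1.5 in steps of
0.01); for fixed (δ, g) the L1-optimal baseline is available in closed form
as the median residual, clamped to ±0.25, so no grid in b is needed. The
objective is normalized per overlapping bin to avoid rewarding small
overlaps, and candidates within 1e−12 of the minimum are tie-broken toward
the smallest |δ|, then |b|, then g nearest 1 — making the result fully
deterministic. Only δ is propagated to the data, as an RT shift
(`shift_rts()`, `pool_subjects()`); g and b are diagnostics of how similar
the two subjects' curves are after the time shift. Search ranges and
resolution are package choices: nothing in the procedure depends on them
once they bracket the optimum, and the recovery test (50 random transforms,
binomial noise at 200 trials/bin, δ within ±2 ms in ≥90% of cases) runs at
exactly these defaults.

## The conditional-independence interaction test

For history events A and B and outcome C, conditional independence
P(A,B|C) = P(A|C)P(B|C) combined with Bayes' rule yields the prediction

$$P(C=1\mid A,B) = \frac{p_A\,p_B}{p_A\,p_B + (1-p_A)(1-p_B)\,\pi/(1-\pi)}$$

with $p_A = P(C=1\mid A)$, $p_B = P(C=1\mid B)$ and prior $\pi = P(C=1)$.
The formula is symmetric, nondecreasing in each component, and collapses to
$p_A$ when $p_B = \pi$. `interaction_analysis()` applies it to every
sequence-mode label of depth H: the measured accuracy comes from informed
trials (PT > 150 ms, the same boundary that defines the ceiling — the only
stated informed-region cutoff) matching the joint label; the components come
from the two marginal labels; and the prior is recomputed per analysis as
the informed-region proportion correct of all trials entering it (a flag
switches to the all-PT proportion; the informed-region prior is the default
because the analysis itself lives in the informed region). For the triple
analysis the outcome letters enter both marginals (color-with-outcome vs
location-with-outcome), so the two conditioning events deliberately share
the outcome dimension.

Reliability gating: a point is reliable when its measured 95% CI spans fewer
than 15 percentage points. `interaction_slope()` regresses predicted on
measured over the reliable points (that orientation matches how such panels
are drawn); the 95% CI is a percentile bootstrap over points (10,000
resamples, seeded) because the points are heteroscedastic — their binomial
errors vary by an order of magnitude between common and rare sequences — and
the closed-form OLS interval is reported alongside for comparison. The
exactness of the prediction is tested against direct summation over 100
random discrete joints built to satisfy conditional independence
(agreement to 1e−12), and end-to-end: a generator with independent color and
location effects yields a β₂ CI covering 1, while a built-in outcome-gated
color×location coupling flattens the slope — the extremes become
under-predicted, which is exactly the signature the test is designed to
expose.

## The generative model

No generative model is given for this task in the literature the package
builds on, so the synthetic module defines its own, with every magnitude
exposed in `generative_params()`:

* target color ~ uniform{red, green}; quadrant ~ uniform{4}; Gap ~ uniform
  over {0, 25, …, 225} ms (the Gap *range* is a task constant; its sampling
  grid is a package choice, configurable); RT ~ Normal(275, 60) truncated to
  (0, 450] ms.
* with probability q(PT) = logistic((PT − center)/width) the choice is
  informed: the target with probability p_ceil, otherwise a uniform
  distracter. Otherwise it is a guess from a softmax over four location
  weights.
* after every trial the location weights decay by exp(−1/9) and the target
  quadrant's weight gains ±κ_loc (positive after a correct trial, negative
  after an error); the two color gains decay by exp(−1/5) and the target
  color's gain changes by ±κ_col. The decay constants (5 trials for color,
  9 for location) mirror the inter-trial timescales reported for the two
  biases. The ceiling passes through a logistic link,
  p_ceil = plogis(qlogis(ceiling_base) + gain + interaction·gain·weight),
  so probabilities are squashed smoothly rather than clipped and the
  history-free likelihood stays differentiable.

Defaults: ceiling_base 0.70, center 125 ms, width 5 ms, both kappas 0
(history-free), interaction 0 (conditionally independent). The width
deserves a note: the model's defining condition is chance accuracy strictly
below PT = 100 ms and asymptotic accuracy above 150 ms, so the logistic's
1%–99% span (≈9.2 widths) must fit inside the 100–150 ms band, which bounds
the width at ≈5.4 ms; 5 ms is the largest round value that satisfies it. A
wider transition would leak informed choices into the floor region and push
the measured floor visibly above 25% at the trial counts used here.

With κ = 0 the agent reproduces the design priors exactly: color repetition
probability 0.5, location repetition 0.25, floor 25%. Outcome gating is a
sign flip of the latent update, which has a consequence worth knowing: at an
overall reward rate near 0.5 the ceiling-region S−D color difference is
driven through the *concave* part of the logistic, so symmetric ±κ updates
produce a net negative repetition effect at the ceiling. The dissociation
tests therefore assert on |S−D| — the location bias expresses itself at the
guessing floor and the color gain at the informed ceiling, each silent in
the other's region, whatever the sign. Real datasets with higher reward
rates sit in the regime where the same mechanism yields positive repetition
effects.

The generator logs every latent (weights, gains, p_ceil, arbitration
probability) together with the uniform draws behind each choice, and
`replay_choices()` re-derives all choices from the log deterministically —
the suite verifies bit-exact agreement. What the generator does *not*
emulate: RT-history coupling (RT is drawn independently of the latents),
sensory adaptation within a trial, block structure, or fatigue; passing
tests therefore certify the estimators, not any claim about biological
mechanism.

## Parameter recovery

`recover_parameters()` fits p(correct | PT) = floor + (ceiling −
floor)·logistic((PT − center)/width) by maximum likelihood: a coarse grid
(3×3×3×3 over plausible starts) followed by L-BFGS-B with an analytic
gradient and box constraints. Confidence intervals are Wald intervals from
the *expected* Fisher information — the standard choice for binomial
likelihoods, and better calibrated here than the observed numerical
Hessian. Estimates within tolerance of a box bound are flagged as boundary
solutions (all-correct data drive the ceiling into its bound, shuffled PTs
inflate or pin the width) and their CIs are withheld. At 20,000 trials per
fit, per-parameter CI coverage is close to nominal; the suite requires at
least 93/100 replicates to cover each true parameter.

## Problem sizes and numerical choices

The test suite's simulation sizes are chosen so each check has clear
resolution at modest cost: 100,000 trials for the design priors (Monte-Carlo
SE ≈ 0.0016 on a repetition rate), 200,000 for the floor/ceiling
dissociations (per-bin SE small against the several-point effects at κ = 1),
50,000 for the end-to-end slope, 100 × 20,000 for recovery coverage. The
dissociation check accounts for the 50-fold overlap of adjacent sliding bins
by requiring band exceedances to be *sustained* — ≥25 consecutive 1-ms grid
steps beyond 2 SE inside the active region — and declares the inactive
dimension quiet when no 25-ms run beyond 3 SE occurs anywhere; isolated
single-bin excursions are expected under the null and ignored. Exceedance is
only evaluated on bins with at least 50 trials in both curves, since the
plug-in binomial SE degenerates to zero on tiny bins with p ∈ {0, 1}.

Known limitations: alignment is pairwise to a reference, not simultaneous
across many subjects; the interaction test is the predictability criterion
only, not a parametric model of interaction; and a deliberately narrow
default transition (5 ms) means synthetic tachometric curves rise more
steeply than many empirical curves — widen it (and accept a contaminated
floor) when visual similarity to a specific dataset matters more than the
floor/ceiling separation.
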