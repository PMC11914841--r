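---
title: "Closed-loop difficulty regulation and movement kinematics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop difficulty regulation and movement kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinadapt)
```

## What the package models

`kinadapt` is a simulation and analysis toolkit for self-adaptive
serious-game motor-learning studies in immersive VR. The setting it
models is a whack-a-mole-style search-and-strike game for older adults:
the player must find and hit a target mole among distractors, and a
block-level regulator retunes the game's difficulty after every block so
that the player stays near a 75% success rate — the zone generally
considered motivating (neither trivially easy nor discouraging).
Transfer of the trained skill is assessed before, directly after and one
week after the intervention with a 3D drawing task scored by two
kinematic indexes: the speed–accuracy trade-off (SAT) and
spectral-arc-length smoothness (SPARC).

The package implements all four layers as testable code: the regulator,
the kinematic metric engine, synthetic data generators (learner agents,
drawing trajectories, outcome cohorts), and the repeated-measures
statistical pipeline.

## The difficulty regulator

A difficulty state has five dimensions: target exposure time
(`exposure_level` 0–6, shorter is harder), working-area extent
(`area_level` 0–6, wider is harder), distractor count (0–23), the
fraction of low-salience (target-like) distractors (0–1), and the cue
mode (`visual_and_auditory` → `auditory_spatial` → `none`). A scalar
*total difficulty index* puts these on a common scale where one
regulator step on any dimension moves the index by one unit: exposure,
area and cue stages count 1 per level, distractors 1 per 4 moles, and
the salience mix 2 at full mix (a 0.25 step = 0.5 units). The index
ranges from 0 to 21.75. Block size grows with difficulty as
`4 + 2 * index`, clamped to the game's 1–24 target trials per block.

After each block the success rate (hits / target trials; struck
distractors count separately as false positives) is classified into
three bands: above 75% = too easy, 50–75% inclusive = difficult (the
intended operating band), below 50% = excessively difficult. The
adjustment is a deterministic decision table:

* **too easy** — step the first available dimension harder in the
  priority order cue withdrawal → shorter exposure → wider area → more
  distractors → more target-like distractors. Cues are explicit help,
  so help is withdrawn before the task itself is intensified;
  target-like distractors are the most confusing manipulation and come
  last. A perfect block steps two dimensions.
* **too difficult** — step the dimension the error diagnostics
  implicate: mostly-peripheral omissions shrink the working area and
  restore one cue stage; mostly low-salience false positives reduce the
  salience mix (then the distractor count); otherwise the exposure
  window is lengthened, with a fixed fall-back chain.
* **difficult** — no level changes; the spawn bias is re-aimed at the
  centroid of the block's omissions so the failing region gets
  practice.

All moves are one level per dimension per block, clamped at the bounds
with silent fall-through. This table is one deliberate reading of a
regulator described only by its bands, adjustable parameters and goal;
we chose the smallest deterministic rule set that is auditable and
satisfies the closed-loop property below.

### Closed-loop behaviour

With band boundaries at 50% and 75% and symmetric one-step moves, the
stochastic equilibrium of the loop sits in the interior of the operating
band: for a *stationary* skill level the long-run mean success rate
settles near the low 60s (%), because upward steps trigger at observed
rates above 75% while downward steps only trigger below 50%. The test
suite asserts the band form of this property: for any fixed-skill
learner whose success probability spans the difficulty range, the
long-run mean lies in [0.60, 0.80]. Mean success near the 75% goal
itself emerges when the player keeps *learning*: skill growth adds
upward drift that the regulator continually absorbs by hardening the
game, holding observed rates just under the too-easy boundary.

## Synthetic learners

A learner agent hits a target with probability
`plogis((skill(b) - index) / slope)`, where
`skill(b) = asymptote - (asymptote - baseline) (1 - rate)^b` after `b`
blocks — exponential approach to an asymptote, the standard practice-
curve shape. Peripheral targets incur an extra logit penalty; false
positives are Poisson with a rate scaled by the distractor count and
salience mix, and low-salience distractors are disproportionately the
ones struck.

The default population (`default_learner_population()`) draws baseline
skill N(6, 1.5), skill gain N(20, 2.5) (floored at 2), learning rate
N(0.025, 0.008) (clipped to [0.005, 0.3]), logistic slope N(2, 0.4)
(floored at 0.8), false-positive propensity N(1, 0.4) and periphery
penalty N(0.5, 0.2), both floored at 0. These constants were calibrated
by simulation so that a 20-learner cohort starting from the easiest
state reproduces the intended session course: an initial too-easy ramp,
cohort-median success entering the 60–80% band within about a dozen
blocks, near-total band occupancy through block 55, and a pooled
post-burn-in mean success rate near the 75% goal. The slow learning
rate paired with a large gain is the load-bearing choice: it sustains
skill growth across a hundred blocks, which is what keeps the loop
operating near the top of its band rather than at its stochastic
stationary point.

What the agents do **not** model: fatigue, day boundaries, attention
lapses, strategy shifts, or any coupling between the game and the
drawing assessments other than a configurable practice-gain mapping.
Passing feasibility checks on these agents shows the regulator logic is
sound under its stated assumptions, not that real players behave this
way.

## Kinematic metrics

Trajectories are 60 Hz, 3D controller positions (seconds, metres). The
analysis pipeline (`analyze_task()`) is: zero-phase Butterworth low-pass
→ speed from the first derivative of position → SAT and SPARC.

**Filtering.** 4th-order Butterworth, 10 Hz cutoff, applied
forward–backward. The order is the movement-science default (the study
setting specifies only the 10 Hz cutoff and 60 Hz sampling); zero-phase
filtering squares the magnitude response, and `butter_gain()` exposes
the analytic digital (prewarped bilinear) response the implementation is
tested against. The implementation mean-centres and odd-reflects ~1 s of
signal at each end before the double pass: a plain forward–backward IIR
run starts from zero state and would corrupt the ends (a constant input
would not even be preserved).

**SAT** = mean speed (path length / duration, cm/s) divided by the RMS
orthogonal deviation from the ideal shape (cm). Mean rather than peak
speed is used because one scalar per task is needed and the mean is
robust to single spikes. The error term is floored at 0.1 cm so perfect
traces do not divide by zero. For the line task the deviation is
assessed in 2D — samples are projected onto the plane spanned by the
line direction and the dominant orthogonal variance direction —
because the drawing assessment treats straight lines as planar; circles
use the full 3D distance to the ideal circle. A path-length-ratio error
is deliberately *not* the default; deviation-from-ideal is the
definition implemented. SAT's absolute scale is arbitrary units, so
printed study means are not reproduction targets.

**SPARC** = the negative arc length of the amplitude-normalized
magnitude spectrum of the speed signal over `[0, ω_c]`, with the
standard published parameterization of the metric: amplitude threshold
0.05, maximum band 20 Hz, zero-padding to 4× the next power of two, and
the adaptive cutoff `ω_c` = the last frequency within the band at which
the normalized spectrum still reaches the threshold. Frequencies are
normalized by `ω_c`, making the metric dimensionless, amplitude-
invariant and duration-scale-free; values are ≤ 0 and closer to 0 means
smoother. The implementation is verified against a brute-force DFT +
arc-length quadrature oracle to 1e-6.

**Numerical choices.** Derivatives are central differences (one-sided at
the ends); sampling gaps beyond 3 nominal intervals are an error rather
than silently interpolated; the trajectory validator requires strictly
increasing timestamps and a median interval within 20% of nominal.

## Synthetic trajectories

`generate_trajectory()` composes: (1) an ideal line or circle, (2) a
traversal speed that is a sum of `n` minimum-jerk bursts with 25%
overlap (a standard submovement decomposition; one burst gives the
classic bell with peak speed `1.875 D/T`), (3) an orthogonal sinusoidal
deviation with an integer number of cycles over the task, and (4)
isotropic white positional noise. The deviation is sinusoidal in *time*
rather than arc length so the closed-form RMS error, amplitude/√2,
holds exactly under the minimum-jerk time-warp; with cycles matched to
the task duration the sampled RMS agrees with the closed form to well
under 2%. Submovement count, deviation amplitude and duration are the
three monotone dials the tests exercise against SPARC, path error and
SAT respectively.

## Synthetic cohorts and the statistical pipeline

`generate_cohort()` draws, per participant and outcome, a random
intercept plus configured standardized shifts at T1/T2 plus measurement
noise. Shifts are standardized against the SD of a paired difference
(`√2 × noise SD`), so a configured effect of `d` is recovered as a
paired Cohen d of `d` — the contract the parameter-recovery test
checks. Baseline means/SDs default to the modelled study's observed
baselines, and the reaction-time outcome defaults to mean 398 ms,
SD 117 ms with zero true effect, serving as the pipeline's negative
control. The virtual box-and-block score is rounded to a non-negative
integer. With all effects zero the generator is an exact null for the
statistical stage.

`run_study_analysis()` mirrors the standard pre/post/follow-up plan:
per outcome, listwise deletion to complete cases (the deletion count is
reported), a Shapiro–Wilk gate at α = 0.05 per time point (parametric
only if all pass; constant columns route nonparametric with a warning),
then either a one-way repeated-measures ANOVA (partial η² =
SS_effect/(SS_effect+SS_error)) with Bonferroni-adjusted paired t post
hocs and Hedges-corrected paired Cohen d, or a Friedman test with
Tukey-style rank post hocs (`q = |R_i - R_j| / sqrt(n k (k+1)/12) · √2`
against the studentized range, Cohen `r = |z|/√n`, `z = q/√2`).

Two convention notes, both recorded in the output rather than silently
assumed. ε² for the Friedman test is reported as `χ²/(n(k−1))`
(Kendall's-W-equivalent); published ε² values under other conventions
are not comparison targets. "Adjusted" Cohen d is interpreted as the
Hedges small-sample correction. One operating characteristic worth
knowing: requiring *all three* time points to pass Shapiro–Wilk means
normally distributed data route parametric with probability ≈ (1−α)³ ≈
0.86, not 1; the suite tests the gate against that derived rate.

## Problem sizes and verification

The feasibility simulations use the study's own scale: 20 learners, 55
blocks for band entry and occupancy, 100 blocks for the long-run mean.
Monte-Carlo checks use 100–500 replicates (type-I error 500, power 100,
effect-size recovery 200), sizes at which the binomial error bands in
the assertions are meaningful. The full suite runs in well under a
minute of compute per file.

`scripts/acceptance.R` recomputes the three feasibility quantities from
scratch with the installed package — long-run mean success, 60–80% band
occupancy over blocks 12–55, and first block of band entry — from a
single command-line seed, writing JSON.

## Known limitations

* The regulator's step sizes, priority order and diagnostic thresholds
  are one deterministic reading of a system described only at the level
  of bands and adjustable parameters; other readings (several steps per
  block, probabilistic dimension choice) are plausible.
* The learner agents respond to difficulty only through the scalar
  index; real players are differentially sensitive to exposure time
  versus distractor load.
* The drawing-assessment plane and the exact speed/error definitions
  behind published SAT values are not pinned; SAT here is internally
  consistent but not numerically comparable across implementations.
* Reported ε² and nonparametric Cohen r depend on conventions that vary
  across statistical software; compare like with like.
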