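---
title: "Methods: time-resolved selectivity analysis of visuospatial preselection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved selectivity analysis of visuospatial preselection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sefspace)
```

## The scientific problem

In the saccadic choice task a monkey fixates a central point; a foveal
colored shape (one of four symbolic cues, L1/L2/R1/R2) instructs whether the
upcoming saccade target will appear in the left or the right visual
hemifield. After the cue disappears and a short delay, two choice targets
appear — one per hemifield, on a 10-degree circle, with the line joining
them at an angle between −45° and +45° in 5° steps — and after a go signal
the animal saccades to the target on the instructed side. From cue onset to
target onset (the *preselection period*) the animal knows the relevant
hemifield but not the target location; from target onset to the go signal
(the *target determination period*) the specific target is identifiable. A
companion visually guided delayed saccade task with six fixed target
directions (RU, R, RD, LD, L, LU) characterizes each neuron's visual and
movement properties.

The package asks, window by window, *what task factor does each neuron's
activity represent?* — the symbolic cue's visual identity, the instructed
hemifield (the "potential target space"), the target-pair angle, their
conjunction, or nothing — and then relates hemifield coding to each
neuron's preferred direction (PD), to fixational eye position, and to the
behavioral effects of electrical stimulation.

## Activity measure: windowed iISI

Spiking is converted to the inverse interspike interval (iISI): between two
consecutive spikes the instantaneous rate is the reciprocal of the
enclosing interval; before the first and after the last spike it is zero
(trains with fewer than two spikes are identically zero; the alternative
convention that divides by the interval to the trial edge is isolated
behind `iisi_function()` and could be swapped without touching anything
else). `windowed_iisi()` averages this step function *exactly* over each
10-ms window of an event-aligned grid — each interspike interval
contributes exactly 1 to the cumulative integral, so the window mean is a
two-point evaluation of a piecewise-linear function, not a numerical
quadrature. Spike counts use half-open windows `[a, b)` so that counts are
additive over window partitions.

## The two-stage classifier

For every 10-ms window (stepped by 10 ms) of the regular success choice
trials, `classify_windows()` runs:

1. **Stage 1 — cue identity.** Separately for each same-hemifield cue pair
   (L1/L2 and R1/R2), a two-way ANOVA of the window-mean iISI with cue
   object and target angle (−45/0/45°) as factors, at α = 0.005 per pair.
   A significant object main effect in either pair labels the window
   *object*; object-and-angle main effects or an interaction label it
   *object_and_choice* (which takes precedence — a neuron meeting both
   conveys both factors).
2. **Stage 2 — spatial factors**, only where stage 1 assigned nothing: a
   two-way ANOVA with instructed hemifield (2) and angle (3) as factors at
   α = 0.01. Hemifield-only → *potential_space*; angle-only →
   *choice_targets*; both mains or the interaction → *target_position*;
   otherwise *none*.

Raw labels persist only when the same category holds in ≥ 3 consecutive
windows (`apply_persistence()`, idempotent); no further multiplicity
correction is applied across windows — the persistence rule is the
procedure's false-positive control, and its actual behavior is quantified
below.

Numerical choices: the ANOVAs use type-II sums of squares (identical to
type I/III on the balanced designs the generator produces, and
well-defined on the mildly unbalanced designs real behavioral errors
create); they are computed by a vectorized QR projection shared across all
windows of a neuron, which is what makes a 500-neuron × 140-window
calibration run affordable, and the routine is verified against
`car::Anova(type = 2)` to 10⁻¹⁰ in the tests. Windows with an empty design
cell or zero residual variance (e.g. all-zero iISI) are labeled *none*
with `NA` p-values. Additional-angle trials are excluded from the ANOVA
and used nowhere in this module.

Default grids: cue-aligned over [−0.2, +1.2] s and target-aligned over
[−0.2, +0.75] s for the classifier; cue-aligned 100-ms/100-ms windows for
ROC and regression. The preselection epoch is [0, 1.2] s after cue onset
(700-ms cue + 500-ms delay) and epoch membership uses an any-overlap rule.
These spans are this package's defaults, declared rather than inferred.

## PD, neuron types, and population contrasts

`determine_pd()` takes delayed-task spike counts 0–300 ms after target
onset: a one-way ANOVA across the six directions at α = 0.05, plus a
*unique* arg-max rule (ties → no PD). `classify_neuron_type()` applies
one-sided Wilcoxon signed-rank tests to paired counts (visual: 0–300 ms
after vs. 300–0 ms before target onset; movement: −100–50 ms around vs.
350–200 ms before saccade onset), giving the visual / visuomovement /
movement / none truth table; all-zero differences are non-significant by
convention.

Choice trials are split into *PD-included* and *PD-opposite* by whether the
instructed hemifield contains the PD. Contrasts across the population:

- `auc_track_with_null()` — per 100-ms window, the Mann–Whitney AUC
  between PD-included and PD-opposite spike counts (ties count ½), with a
  label-permutation null (1000 permutations by default; fewer than 100 is
  refused). `population_auc_test()` compares observed vs. null-mean AUC
  across neurons per window — Wilcoxon signed-rank by default, paired t
  optionally, since the field's descriptions of this step disagree between
  the two — then Benjamini–Hochberg across windows at α = 0.05.
- `signed_count_binomial()` — per window, counts of neurons individually
  significant (two-sample pooled-variance t, α = 0.05) in each direction,
  compared by an exact two-sided binomial test against ½, BH-corrected.
- `tuning_matrix()` / `align_tuning_population()` — 200-ms/10-ms
  direction-by-time rate matrices; pre-target columns are reordered so the
  PD-containing hemifield's three directions come first, post-target
  columns are rotated onto an 8-point 45°-grid with the PD at 0° and the
  two empty slots (Up/Down for a horizontal PD) linearly interpolated from
  their circular neighbors.
- `rayleigh_uniformity()` — the standard Rayleigh test (closed-form
  p-approximation) for uniformity of the PD distribution, implemented here
  because no circular-statistics package is among the dependencies.

FDR control is Benjamini–Hochberg throughout (`fdr_bh()`), the field
default where a procedure is not named.

## Eye position and the confound analysis

`preprocess_eye()` cue-aligns each trial's horizontal trace on a 240-Hz
grid, subtracts the per-trial baseline (0.5 s before cue onset), averages
by instructed hemifield and removes the pointwise grand mean of the two
condition means. `detect_divergence()` runs a paired t-test (left vs.
right condition means across sessions) at every time point (α = 0.01) and
takes the first run of significant points lasting ≥ 20 ms at or after cue
onset; the 20-ms persistence default follows the stricter of the two
thresholds in circulation (10 ms is exposed as an option), and the search
starts at cue onset because the pre-cue trace is baseline noise by
construction. `classify_shift_direction()` labels each trial by the sign
of its eye position at the session's maximal left/right separation time
(exact zeros take the next sample's sign).

Two analyses separate hemifield coding from eye position:

- `hemifield_vs_eyeshift_anova()` — per 10-ms window, a 2×2 ANOVA
  (instructed hemifield × shift direction) with the ≥ 3-consecutive-window
  rule at p < 0.01 for calling a window instruction- or eye-modulated.
- `regress_activity_on_eye()` — per 100-ms window, standardized OLS of
  spike count on the PD-condition code (+1/−1; raw left/right coding is
  available for neurons without a PD), with and without the window-mean
  horizontal eye position as a second regressor, plus a label-shuffle null
  for both hemifield coefficients; `regression_population_test()` compares
  the two coefficients (paired t by default) and each against its null,
  BH-corrected. Designs with |correlation| > 0.999 between the regressors
  are flagged unstable.

## Stimulation statistics

`stim_behavior_stats()` computes (i) a pooled-variance two-sample t (with
pooled-SD Cohen's *d*) on session-level correct rates between stimulation
and non-stimulation sessions; (ii) within stimulation sessions, paired t
(Cohen's *d* = mean diff / SD of diffs) on the stimulated vs.
non-stimulated trial rates, separately for trials instructed toward the
hemifield ipsilateral and contralateral to the stimulated (left)
hemisphere; and (iii) a two-way ANOVA (stimulation × trial type) on the
per-session mean horizontal eye position 0.35–0.45 s after cue onset, with
η² = SS/SS_total. The correct rate is computed among completed choices
(fixation breaks excluded from the denominator).

## What the synthetic generator emulates

`generate_session()` reproduces the task's block structure (per choice
block: 4 cues × 3 regular angles + 4 additional angles drawn from
±5–40°; stimulation sessions interleave stimulated/non-stimulated versions
of all 16 types; delayed blocks cycle the six directions), event timing
(1-s fixation, 700-ms cue — 120 ms in stimulation sessions — 500-ms delay,
go signal 750–1200 ms after target onset), and outcomes (fixation breaks
drawn independently at 2 %, then a correct choice with probability
`p_correct` = 0.97, so `p_correct` *is* the correct choice rate among
completed trials and the stimulation parameter `stim_ipsi_error_increase`
maps one-to-one onto the recovered rate difference). Sessions default to
one choice-task pass (10 blocks, 120 regular trials) and three delayed-task
passes (30 blocks, 30 trials/direction), matching sessions that alternated
the task sets two to three times with a few hundred trials per neuron.

Spiking is an inhomogeneous Poisson process sampled by thinning (candidate
times at the rate bound, accepted proportionally to λ(t); duplicate
candidates from the RNG's finite granularity are removed to keep spike
times strictly increasing). Poisson was chosen deliberately: every
downstream statistic is a rank, count or ANOVA statistic for which renewal
refractoriness is immaterial, and the thinning output is verified against
an independent per-segment exponential-waiting-time sampler by a KS test.
Rate profiles compose a baseline with (a) a multiplicative hemifield gain
during the preselection epoch (or the determination epoch for the
target-position archetype) when the instructed hemifield matches the
neuron's preferred side, (b) per-cue and per-angle multiplicative gains,
(c) a transient visual kernel (80-ms latency, 150-ms flat peak, 200-ms
exponential decay) scaled by a von Mises direction tuning normalized to
max 1 (κ = 0 is direction-blind; the unchosen target contributes at
half weight by default), and (d) a Gaussian peri-saccadic bump (σ = 40 ms,
centered 20 ms before saccade onset). The kernel shapes are free
parameters of this package, chosen to mimic typical visual and
peri-saccadic responses, not fitted to any dataset — no quantitative
firing-rate distributions were available to fit.

Eye traces are an Ornstein–Uhlenbeck drift (τ = 0.35 s, σ = 0.25°,
exact discretization at 240 Hz) plus, on choice trials, a ramped bias
(0.14° plateau, 0.17-s latency, 0.15-s rise) toward the instructed side
whose sign flips on a random fraction of trials
(`opposite_shift_prob` = 0.25), plus a ramped contralateral shift (0.08°)
on stimulated trials; traces are clamped to the 2.5° fixation window. The
`eye_coupled` control archetype adds a rate term proportional to the
horizontal eye position (25 Hz/deg), giving a neuron whose apparent
hemifield coding is entirely eye-driven — the positive control for the
regression disentanglement.

Everything is deterministic given `master_seed`: trial sequence, every
neuron-trial spike train and every eye trace draw from arithmetically
derived sub-seeds, so regenerating a session is byte-identical.

**What the generator does not emulate** — refractoriness and bursting,
rate drift and nonstationarity, microsaccades (drift is the only
fixational component), correlated noise across neurons, saccade
kinematics, and between-session heterogeneity of effect sizes. Passing
recovery tests therefore show that the pipeline is correct and calibrated
under its own assumptions, not that those assumptions hold in recordings;
in particular the synthetic stimulation eye effect is far more consistent
across sessions than a real one, which inflates its F statistics.

## Validation studies and the problem sizes used

The `calibration_*`/`recovery_*` drivers run the validation suite that the
package's acceptance tests and `scripts/acceptance.R` execute:

- **Oracle equivalence** — `auc()` against exhaustive pair enumeration
  (1000 random instances, n ≤ 20), `fdr_bh()` against a hand-walked
  step-up (50 random vectors), the binomial test against direct summation.
- **Null calibration** — 500 null-archetype neurons (20 Hz), 10 choice
  blocks: the per-window rate of spurious stage-2 labels is checked
  against the analytic union bound 3 × 0.01 plus twice its Monte-Carlo
  (cluster) SE. The fraction of null neurons acquiring any *persistent*
  label is checked against an independent oracle cohort — homogeneous
  Poisson trains drawn by exponential waiting times, not by the thinning
  sampler — classified identically (200 neurons). An independence-based
  analytic bound would be wrong here and is deliberately not used:
  adjacent 10-ms windows share interspike intervals, so their labels are
  strongly serially dependent and ≥ 3-window runs are orders of magnitude
  more frequent (≈ 3–5 % of null neurons) than independent-window
  combinatorics predicts (≈ 0.04 %). This serial dependence is intrinsic
  to the persistence rule as defined, and is the package's measured
  false-positive rate for it. The population AUC test is also run on 60
  null neurons with uninformative labels (1000 permutations) and flags
  essentially nothing after FDR.
- **Parameter recovery** — 200 hemifield neurons (gain 1.5, 10-Hz
  baseline, the full 120 regular trials, hence error-free behavior for
  this cohort) scored for a persistent *potential_space* label in the
  preselection epoch: measured ≈ 0.90 ± 0.02, right at its design
  threshold, because the per-window F-test on heavy-tailed 10-ms iISI
  means is slightly conservative and has ≈ 18 % power per window at this
  effect size. PD recovery uses 100 direction-tuned neurons at the
  generator defaults (20-Hz baseline, κ = 2, 30 trials/direction): ≈ 98 %
  exact recovery. Eye-model recovery uses 49 behavior-only sessions for
  the bias onset (detected within ~20 ms of the planted 0.17 s; the
  paired-t threshold crossing necessarily lags the true ramp start) and 6
  low-drift sessions (σ = 0.02°) for the flip probability — the per-trial
  flip is only identifiable when drift noise is small against the 0.14°
  bias; under the default drift the classifier measures the
  side-of-fixation proportion (≈ 0.37–0.40, inside the 11–42 % range
  observed in recordings), which is reported separately.
- **Regression disentanglement** — 100 hemifield-driven neurons (with the
  instruction-driven eye bias present but not driving spikes): adding eye
  position leaves the standardized hemifield coefficient unchanged (no
  FDR-significant paired difference; means agree to < 0.02). 40
  eye-coupled control neurons: the coefficient collapses to ≈ 0.3 of its
  single-regression value. 300 shuffles per neuron here (the function
  default is 1000); the paired comparison does not use the shuffle null,
  so this only smooths the reported null means.
- **Stimulation recovery** — 16 stimulation + 16 control sessions with a
  planted 0.05 ipsilateral rate drop: the paired estimate covers 0.05 and
  is significant in every replicate seed set tried; a five-replicate
  zero-effect arm shows false positives at the nominal rate.

These sizes keep the full validation suite at a few minutes on one CPU
while leaving every binomial comparison adequately powered.

## Known limitations

- The persistence rule's false-positive rate (≈ 3–5 % of null neurons
  over a 140-window track) is a property of the published procedure under
  serially dependent windows; users who need strict neuron-level control
  should add a track-level permutation test.
- The classifier's power at small sustained gains (≤ 1.5× on ≤ 10-Hz
  baselines) is modest; reported proportions of selective neurons are
  therefore conservative.
- `normalize_activity()` flags flat neurons as non-normalizable and
  excludes them from population averages rather than guessing a scale.
- The delayed-task PD is a visual-epoch quantity; movement-type neurons
  often have no PD and are excluded from PD-referenced analyses by
  construction.
- The NWB import path is not implemented; sessions interchange via the
  documented TSV dialect.

## A worked mini-example

```{r example, eval = FALSE}
specs <- c(neuron_cohort(6, "hemifield_spatial", hemi_gain = 2),
           neuron_cohort(2, "null"))
cfg <- synthetic_config(neurons = specs, n_choice_blocks = 6,
                        n_delayed_blocks = 12, master_seed = 2024)
report <- run_full_analysis(config = cfg, seed = 7, n_perm = 200)
print(report)
```
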