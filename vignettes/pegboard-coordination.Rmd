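---
title: "Methods: eye-hand coordination analysis for pegboard tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-hand coordination analysis for pegboard tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazehand)
```

## The task and the measurement problem

A participant stands at a desk and moves eight small metal pegs, one at a
time, from a concave collection tray into small pegboard holes (placement
phase), then back (retrieval phase). Three sensor systems watch: load
cells under the tray and pegboard record normal and torque forces at
~1,600 Hz, a hand tracker records the index-finger position at ~120 Hz,
and a gaze tracker records eye position at ~30 Hz, all mapped into a
common coordinate frame in the plane of a screen behind the workspace.
Experiments of this design compare behavior across condition blocks —
baseline, sham (saline) injection, and digital anesthesia of the thumb,
index, and middle fingers — to ask how gaze compensates when tactile
feedback is removed.

The analysis problem is threefold: (1) find the task actions in the force
traces, (2) quantify the spatial and temporal relationship between gaze
and hand per action, and (3) test condition effects with models that
respect the nested repeated-measures structure. This vignette documents
the modelling choices behind each stage, the simulator that makes the
stages testable, and what a green test does and does not establish.

## Segmentation

**Change points.** Collection and delivery actions are contact events:
force pulses on the source and destination transducers. Onsets and
offsets are defined by change points in the normal force, detected with
the Pruned Exact Linear Time algorithm. The cost is the within-segment
sum of squares about the mean (piecewise-constant mean), so the pruning
condition holds with `K = 0` and the pruned search provably returns the
exhaustive-search optimum; the test suite checks this equivalence against
an unpruned O(n²) dynamic program and full enumeration at tiny n. One
subtlety: with a minimum segment length m > 1, the textbook pruning rule
is unsound — a candidate dominated at time t can still be optimal for the
next m − 1 points, where the dominating split is not yet admissible — so
candidates are removed only m steps after they are first dominated.

**Penalty.** The per-change-point penalty defaults to `2·σ̂²·log n`
(BIC-like), with σ̂ the median absolute deviation of the differenced
series divided by √2 — robust to the pulses themselves. Noise-free series
get a small positive penalty floor so that exact plateaus do not shatter
on floating-point cancellation noise. The minimum segment length defaults
to 40 samples (25 ms at 1,600 Hz), suppressing contact chatter.

**Detrending.** Delivered pegs leave a persistent ≈0.0745 N (7.6 g ×
9.80665 m/s²) step on the receiving transducer, so each series carries a
monotone staircase under the pulses. The staircase is estimated as the
median force over each quiescent run — long, flat plateau segments merged
at a common level — held piecewise-constant, with level changes placed at
the midpoint of the intervening contact interval. Plateau classification
(length ≥ 150 ms and within-segment SD ≤ 3σ̂) deliberately rejects the
short sloped fringe segments of a pulse, which are absorbed into the
contact interval; this is what makes the recovered staircase exact at the
pulse onset and offset points, where the per-trial baseline (the average
of the onset and offset values after detrending) must be zero. A series
with no quiescent interval is a hard error, not a guess.

**Boundary refinement.** Any smooth contact pulse starts with zero slope,
so near onset the force grows quadratically and its square root grows
linearly. Raw change points and threshold crossings therefore lag the
true contact time by an amount that grows with pulse width (tens of
milliseconds for a 300 ms pulse). Boundaries are instead refined by
fitting a line to √force over the rising (falling) edge between ~2σ̂ and
25% of the pulse peak and extrapolating to zero, with a noise-floor walk
as fallback. In simulation this localizes boundaries to ~2–4 ms at the
default noise level. This refinement is the package's operationalization
of "return of normal force to baseline levels".

**Failure surface.** Where a manual-inspection step would traditionally
correct mis-segmented trials, this pipeline instead fails loudly: if the
detected contact count on a transducer does not equal the expected pegs
per phase, or events do not interleave as collection ≺ delivery per peg,
`extract_actions()` raises an error naming the phase and counts. No
silent repair.

## Coordination metrics

**GISI** is the absolute gaze–index separation along the horizontal
screen axis, in mm. Distance implies magnitude, so the absolute value is
the default (a signed variant exists for diagnostics). Most positional
variance in this workspace layout is horizontal, which is why the x axis
carries the metric; a 2-D variant is deliberately out of scope.

**Progress profiles** snapshot GISI at the gaze samples nearest to 0, 25,
50, 75, and 100% of the action's onset→offset span — nearest-sample, not
interpolated, because the quantity is a snapshot of a measured sample.
Actions shorter than five gaze samples are flagged and excluded. **GISI
at peak force** reads the profile at the earliest maximum of |detrended
normal force| within the action (earliest, so ties are deterministic).

**Temporal offset.** Per series × phase, the hand signal is linearly
interpolated onto the 30 Hz gaze timebase (a 4:1 rate ratio makes linear
interpolation adequate; nearest-sample is available as a config switch)
and the Pearson correlation between the mean-centered series is maximized
over integer-sample lags within ±1,000 ms. Positive offsets mean gaze
leads. Resolution is one gaze sample (33.3 ms); the estimator is exact
for integer-sample shifts, which is how the recovery tests constrain it.
Near-constant series make the offset undefined and raise an error.

**Total torque** is ambiguous in the field's phrasing ("total torque
force"); it is implemented as the time-integral of |torque| over the
action (N·m·s, trapezoidal), with a per-sample sum behind a flag. The
integral is the default because it is invariant to sampling rate.

## Statistical models

The models follow the standard mixed-model stack for this design:

- `DV ~ block * hand + (1 | subject/round)` for durations, forces, and
  GISI at peak force;
- `... * progress` (progress as a 5-level factor, since per-quartile post
  hocs are the target) with by-subject random slopes where estimable;
- `offset ~ block * hand * phase + (1 + block*hand*phase | subject)`;
- `DV ~ block * hand * series_block + (1 | subject/round)` for learning
  trends, with the within-block series index numeric.

Estimation delegates to lme4 (REML). Everything around it is first-class
package code, because no Type-II/EMM/Tukey machinery is assumed present:

- **Type-2 Wald χ² tests** build each term's hypothesis matrix in
  coefficient space by taking, within the span of the term and its
  higher-order relatives, the subspace conjugate (orthogonal under the
  coefficient covariance) to the relatives. On fixed-effect models this
  reproduces classic Type-II sums of squares exactly, which the tests
  verify against residual-sum-of-squares model comparisons.
- **Marginal (reference-grid) cell means** average model-matrix rows over
  the levels of the other factors with equal weights; numeric covariates
  sit at their mean.
- **Tukey adjustment** uses the studentized range distribution with
  asymptotic (infinite) degrees of freedom, matching the large-trial
  regime of these experiments.
- **Δ and ΔΔ contrasts** are linear functions of the fixed effects:
  Δ = (treatment − baseline) within hand, ΔΔ = Δ_treated − Δ_untreated,
  overall and per progress quartile. On balanced data with intercept-only
  random structure the model-based ΔΔ equals the descriptive cell-mean
  arithmetic exactly (tested).

**Convergence ladder.** The maximal random structure for the progress
model has q = 20 slope columns, i.e. 210 covariance parameters — far more
than a 5–20 subject study can support. The fitting ladder therefore
simplifies on non-convergence or singular fit: maximal slopes → nested
intercepts `(1|subject/round)` → subject intercept, recording each step
in the result; a stage whose covariance parameter count exceeds twice the
subject count is skipped outright with a note rather than ground through.
Fixed effects are never dropped automatically, so the contrasts stay
defined. lme4's double-bar syntax does not expand factor terms, so a
separate "drop correlations only" rung is folded into the slope-dropping
rung.

## The simulator: a stated world

The generator exists so that every stage has ground truth. Its defaults
state one plausible world and are not revisited per test:

| parameter | default | why |
|---|---|---|
| sampling rates | 1,600 / 120 / 30 Hz | the instruments' rates |
| peg mass | 7.6 g | the physical pegs |
| trial lattice | 4 rounds × 5 series × 2 phases × 8 pegs | the designs (1,280 / 1,920 trials) |
| gaze lead | 150 ms baseline, 75 ms anesthesia | order of the reported phase-level leads |
| coupling κ | 0.70 baseline, 0.92 anesthesia | yields emergent offsets and GISI changes on the reported scale |
| action durations | 300 ms contacts, 450 ms movements; ×1.5 under anesthesia | slower actions with anesthesia |
| peak forces | 1.2 / 1.5 N; ×1.4 under anesthesia | stronger contacts with anesthesia |
| noise SD | 0.01 N force, 1 mm hand, 3 mm gaze | load-cell and tracker-grade noise |

Mechanics: the hand follows minimum-jerk point-to-point trajectories
between handrest, tray, and holes (smooth, standard, closed-form); gaze
at time t is `(1−κ)·target(t+lead) + κ·hand(t+lead)` plus noise, where
the target is the upcoming interaction station — during a contact the
gaze already looks ahead to the next station, which is what makes GISI
rise through an action at low κ; force pulses are raised-cosine bells
spanning each contact (differentiable, unique interior maximum) riding on
the peg-weight staircase. With κ = 1 the gaze is exactly the lead-shifted
hand, so cross-correlation recovery is exact at integer-sample leads —
the recovery tests constrain injected leads to multiples of the gaze
period for that reason.

What the simulator does **not** emulate: saccade kinematics, blinks,
peg drops, 3-D hand posture, and any action-specific coupling — κ is per
condition × hand, so the coarse-vs-precise GISI asymmetry seen in real
data (precise actions demand more gaze even at baseline) is absent from
synthetic sessions. A green recovery test therefore establishes that the
pipeline measures what was injected, not that the simulator reproduces
every regularity of real recordings.

Two generators exist at different granularities. The sensor-level
simulator drives segmentation and metric recovery. The metrics-level
generator (`simulate_gisi_data()`) draws trial-level DV tables with
subject and round random effects and an injected treated-hand ×
treatment-block shift; it drives the contrast-recovery studies, where
simulating tens of full sensor-level subjects would spend minutes to test
machinery that never touches the raw streams.

## Numerical choices and degenerate inputs

- Ties in change-point minimization and in peak-force location break
  toward the earlier index; segmentation output is deterministic.
- Missing gaze samples are linearly bridged up to 100 ms; longer gaps
  stay missing and propagate out of the metrics rather than fabricating
  fixations.
- Resampling refuses to extrapolate; frame mappings must be rigid to
  1e-12 and preserve pairwise distances to 1e-9 mm.
- The initial reach of each phase has no force-defined onset; its segment
  is anchored at the phase start and documented as such, and recovery
  statistics are computed over force-defined boundaries.
- Identical (schedule, parameters, seed) triples give bit-identical
  sessions; every random draw goes through one seeded path.

## Published reference values

The printed real-data results (placement-phase gaze leads of 158.7 ms
baseline vs 73.3 ms under anesthesia, coarse-collection ΔGISI −57.6 mm
and ΔΔGISI −70.6 mm, baseline GISI 56.2 mm precise vs 78.8 mm coarse,
and the 100.0 ms ΔΔoffset of the three-block design) are carried in
`reference_values()` with their reported uncertainties. Reproducing them
requires the study's released data archive and its manually corrected
change points, so `check_reference_agreement()` gates the comparison on
that data being present and otherwise reports `data-absent`. They are
reference targets, not desk-scale checks, and nothing in this package's
test suite claims to reproduce them from synthetic data.

## Known limitations

- The offset estimator's resolution is one gaze sample; sub-sample leads
  are rounded, and the reported 33.3 ms lattice is visible in simulated
  summaries.
- The Type-2 hypothesis matrices assume a full-rank fixed-effects design;
  rank-deficient designs error out listing the problem rather than
  aliasing silently.
- The detrending step-time inside a contact is unidentifiable (the peg
  leaves mid-pulse); the staircase is exact outside contacts and at their
  endpoints, which is all the downstream metrics use.
- With a single participant, only descriptive contrasts are available;
  the mixed models require ≥ 2 subjects and realistically many more.
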