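---
title: "Measuring dyadic nonverbal coordination with dyadwarp"
author: "dyadwarp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic nonverbal coordination with dyadwarp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadwarp)
```

## The measurement problem

Two people in conversation coordinate their body movements: each tends to
reproduce features of the other's motion within a short, variable time
delay. dyadwarp quantifies that coordination for an interviewer and an
interviewee who each wear four body-worn motion sensors (back of the head,
rib cage, both wrists) streaming 3-axis gyroscope readings at a nominal
120 Hz. The gyroscope magnitude traces index how much a body part is
moving moment to moment, without direction — a deliberately coarse signal
that is robust to sensor placement.

The pipeline has four stages: screening the raw streams, aligning the two
interactants' screened streams by dynamic time warping (DTW), inverting
the per-body-part alignment cost into a coordination score, and analysing
the scores statistically. A synthetic generator with known coupling ground
truth exercises every stage.

## Screening raw streams

Each task segment (the questioning about one interview topic, cut at the
experimenter's start/end markers; boundaries are closed intervals) is
screened in four fixed steps:

1. **Impossible values.** Samples with any axis outside the sensor's
   representable range (`valid_range`, default ±1200 device units for the
   synthetic device, configurable per deployment) are electronic recording
   errors, roughly 0.5% of samples, and are removed.
2. **Alignment.** The two devices are stamped by the same capture host but
   begin recording at different moments; both streams are cut to start at
   the first timestamp present on both recordings.
3. **Down-sampling to 5 Hz.** Frame *k* is the per-axis mean of the 200 ms
   bin `[t0 + 200k, t0 + 200(k+1))`. Bin means rather than decimation:
   after error removal the samples are irregular, and a mean is unbiased
   under missingness while a decimator would propagate single-sample
   noise. An interior bin left empty by error removal is filled by linear
   interpolation of its neighbours (with a warning); more than 10% empty
   bins invalidates the segment.
4. **Standardization.** Per axis, z-scores with the sample SD (n−1),
   multiplied by 1000 and rounded to integers, ties away from zero. This
   removes the placement-dependent gain of each device; after this step
   streams are comparable across body parts and dyads.

Choices the method description leaves open, fixed here once: the
standardization window is one task segment (scores are compared per task,
so per-task unit scaling is the comparable choice; per-interview
standardization would mix task-level variance into every segment), and the
longer stream is truncated to the shorter after down-sampling (the
residual length difference of an aligned capture is an artifact, not
signal).

## Dynamic time warping

Coordination happens at a short, *drifting* delay, so plain
cross-correlation at a fixed lag under-measures it. DTW finds, by dynamic
programming, the monotone alignment path between the two standardized
frame sequences that minimizes the accumulated pointwise distance, letting
the time axis locally stretch or compress. The pointwise metric is the
Euclidean distance over the three standardized axes (the per-axis sum is
available via configuration).

Which local moves the path may take is the *step pattern*. dyadwarp
implements the full Rabiner–Juang taxonomy (`rj_step_pattern(type,
weighting, smoothed)`): seven production sets crossed with four slope
weightings (per elementary move of displacement (di, dj): a = min, b =
max, c = di, d = di + dj), plus smoothed variants that spread each
production's total weight evenly over its moves. The pipeline default is
type VI with weighting c: productions (3,2), (1,1), (2,3), which confine
the local slope to [2/3, 3/2] — the alignment may only moderately stretch
or compress either sequence, and with anchored endpoints the time offset
of an equal-length alignment is bounded by `floor((N-1)/5)` frames (the
test suite verifies this envelope; it is tighter than the one-sixth-of-
length figure sometimes quoted for this pattern). Both endpoints are
anchored; no additional global window is imposed by default because the
slope bounds already confine the path, but a Sakoe–Chiba band is
available (`window =`). Equal-cost ties are broken toward the diagonal
production, so output is deterministic.

The normalized distance divides the accumulated cost by the number of
aligned index pairs on the optimal path — the average pairwise distance
per aligned data point — so segments of different lengths are comparable.
The canonical per-pattern normalizations (reference length, query length,
sum of lengths) are available for cross-checking against other DTW
implementations.

**Correctness.** `brute_force_dtw()` enumerates every legal path for tiny
inputs. The test suite checks the dynamic program against it exhaustively
over all 1-D sequence pairs of length ≤ 3 on the alphabet {0, 1, 2} and on
a seeded sample of length 4–6 pairs, under three patterns of different
structure (VI-c, III-c, I-d); sizes chosen so the enumeration stays exact.

**Symmetry.** The VI production set is mirror-symmetric, so neither
interactant is structurally privileged as "leading" — the reason this
pattern suits a bidirectional measure. The slope weighting c, however,
weights each elementary move by its reference-axis displacement, which
makes the accumulated cost itself direction-dependent (about 10% relative,
in simulation). Weightings b and d are exactly swap-symmetric, and the
suite verifies that. For scoring, dyadwarp removes the residual
orientation dependence by construction (next section) rather than altering
the canonical weights.

## Coordination scores

A body part's score is −1 × the normalized DTW distance between the two
interactants' screened streams for that part, so higher = more
coordinated, with 0 the maximum (identical movement). By default the
distance is the mean over both alignment orientations
(`orientation = "symmetric"`), making the score exactly invariant to which
interactant is the reference; `orientation = "xy"` gives the single
canonical orientation.

The main analysis uses four parts: head, torso, and the same-label hand
pairings (interviewer left ↔ interviewee left, right ↔ right). Cross-hand
pairings (left ↔ right, `hand_mode = "cross"` or `"both"`) are exploratory
outputs and never enter the aggregate. The dyad × task aggregate is the
arithmetic mean of whatever main parts are available; a part lost to
sensor failure or a frozen-sensor segment (zero variance) is recorded as
missing, never imputed.

## Statistics

* **Judgement coding.** Interviewers rate "the interviewee told the
  truth" on a 1–7 Likert scale; 5–7 about truths and 1–3 about lies are
  correct, the neutral 4 is always incorrect. Contingency tables of coded
  accuracy are analysed with Pearson's χ² (no continuity correction — the
  convention that reproduces the published values for these table sizes)
  and the effect size `sqrt(χ²/(n·min(r−1, c−1)))` (φ for 2×2, Cramér's V
  otherwise; non-negative by definition, any sign is a directional
  annotation).
* **Difficulty model.** Task difficulty is coded 1–4 equally spaced in
  the empirically established order easy lie < truth < difficult lie <
  very difficult lie. `fit_difficulty_model()` fits, by REML, a random-
  intercept-per-dyad model with task as a factor (omnibus Wald F) and
  with the numeric coding (linear trend). Denominator df use the
  containment rule `n_obs − n_dyads − rank(X)` by default; Satterthwaite
  is available via `ddf = "satterthwaite"`. The published analyses do not
  state their df method, so the choice is documented rather than matched
  blind. The effect size r is computed from the linear-trend t as
  `sqrt(t²/(t²+df))` and labelled as trend-based: a single r reported
  next to a multi-df F cannot be reconstructed unambiguously, and the
  trend-based reading is the defensible one. Pairwise task contrasts are
  paired t tests on dyad differences with Cohen's
  `d = mean(diff)/sd(diff)` and a Bonferroni-corrected α (reported to 3
  decimals, e.g. 0.017 for three contrasts).
* **Suspicion model.** The same random-intercept structure with the
  interviewer's continuous suspicion rating as predictor.
* **3 × 3 mixed ANOVA.** Attention instruction (between dyads) × task
  (within), classical decomposition with each effect tested against its
  own stratum's error; partial η² = SS_effect/(SS_effect + SS_error).
  Dyads missing a task level are dropped listwise with a warning.

## The synthetic generator

`simulate_study()` generates what the analysis assumes, with ground truth
exposed:

* **Movement kernel.** Per axis, a mean-reverting Ornstein–Uhlenbeck
  process (θ = 1 s⁻¹, unit stationary SD) sampled at 120 Hz — smooth,
  stationary, unit-scaled. Any stationary unit-variance kernel is
  acceptable; the `kernel` hook swaps it out, and a test asserts the
  pipeline's conclusions survive the swap.
* **Coupling.** The interviewee is a lagged, attenuated copy of the
  interviewer: `follower(t) = κ·leader(t − τ(t)) + sqrt(1−κ²)·OU′(t) +
  noise`, with `τ(t) = τ0 + lag_drift·sin(2πt/60)` (defaults τ0 = 0.5 s,
  drift 0.2 s) — a short, slowly drifting delay, exactly the structure
  DTW is designed to absorb and a fixed-lag correlation is not. The
  construction preserves unit variance for every κ.
* **Study designs.** `exp1`: every dyad gives a truth and an easy lie;
  the first half adds a difficult lie, the rest a very difficult lie
  (43 dyads → 22/21). `exp2`: truth, easy and very difficult lie for all,
  with round-robin allocation to nonverbal/verbal/no-instruction groups.
  Default per-task coupling strengths are κ = 0.20 (easy lie), 0.30
  (truth), 0.45 (difficult), 0.60 (very difficult) — *invented* values,
  chosen once so the qualitative ordering is detectable at the study's
  sample size, and clearly not empirical estimates. A dyad-level shift
  (SD 0.05) plays the role of the random intercept.
* **Capture artifacts.** Out-of-range spikes at 0.5% per sample, and a
  per-device recording-start delay (uniform up to 1 s). Delays are
  modelled as late starts with host-clock timestamps — not as clock
  skew — because the alignment step's "first common timestamp" semantics
  presuppose comparable stamps across devices.
* **Judgements.** Veracity ratings are drawn directly at the target
  coded-accuracy level per task; a rating consistent with the drawn
  correctness is sampled uniformly from the matching Likert band. Only
  the coding and contingency machinery needs exercising, so no
  psychological response model is layered underneath.
* **Problem sizes.** Task segments default to 20 s of questioning
  (100 frames at 5 Hz), the package's chosen simulation scale: per-frame
  normalized scores make every statistic length-invariant, and at this
  length the κ grid {0, 0.2, 0.4, 0.6, 0.8} maps to cleanly separated
  mean aggregates. Each generated unit draws its random stream from a
  counter-derived sub-seed, so enlarging a study never perturbs the
  dyads already generated.

What the generator does *not* emulate: biomechanically realistic gesture
forms, cross-site correlation within a person, non-stationary arousal
drift, or any verbal/facial channel. Passing tests therefore demonstrate
that the pipeline measures the kind of lagged statistical coupling it
claims to measure — not that real interview data contain such coupling.

## What the end-to-end checks establish

* With the default κ ordering, the fitted linear trend of aggregate
  coordination on difficulty is positive in ≥ 99 of 100 seeded studies of
  43 dyads.
* With κ constant across tasks, the trend test rejects at the nominal 5%
  rate (±2 percentage points over 500 reduced-size studies of 12 dyads,
  8 s segments) — the pipeline does not manufacture difficulty effects.
* The mixed model recovers a known generating slope within ±0.15 at 40
  dyads × 4 tasks.
* Mean aggregate coordination is strictly monotone in κ (Spearman ρ ≥
  0.9 over the κ grid, 50 dyads per level).
* The χ² layer reproduces, to two decimals, the published detection-
  accuracy statistics when the tables are rebuilt from the printed rates
  and group sizes.

## Known limitations

* Lead–follow directionality is out of scope: the measure is symmetric by
  design and cannot say who initiates coordination changes.
* The published mixed-model F and r values themselves are not
  reproducible without the original recordings; the package substitutes
  the property-based checks above.
* Weighting-c DTW costs are orientation-dependent; dyadwarp's symmetric
  score averages the orientations, so its absolute score values are not
  bit-comparable to a single-orientation implementation (the `"xy"`
  orientation is provided for such comparisons).
* The 7-point judgement generator produces ratings uniform within
  correctness bands, which is adequate for coding/χ² checks but not a
  model of judge behaviour.

```{r example, eval = FALSE}
## a complete miniature run
report <- run_pipeline(list(seed = 7, n_dyads = 8, duration_s = 10,
                            out_dir = tempfile("dyadwarp")))
report$results$difficulty$trend
```
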