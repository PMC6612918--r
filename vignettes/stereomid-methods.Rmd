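---
title: "Methods: stimulus synthesis and analysis for motion-in-depth experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus synthesis and analysis for motion-in-depth experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomid)
```

# Background

Binocular vision supports two complementary cues to motion in depth (MID).
A *changing disparity* (CD) cue arises when the horizontal positional offset
between the two eyes' images varies over time; an *interocular velocity
difference* (IOVD) cue arises when matching retinal features translate with
equal speed but opposite direction in the two eyes. The two cues can be
isolated with dynamic random-dot stereograms: CD stimuli carry disparity but
no coherent monocular motion, IOVD stimuli carry opposed monocular motion but
no usable disparity. A further experimental axis is chromaticity: dots can be
modulated along the achromatic (L+M+S) direction or along an S-cone-isolating
direction that silences L and M cones, probing whether the koniocellular
(S-cone) pathway feeds the MID mechanisms.

`stereomid` implements the full desk-scale computational apparatus of such an
experiment: the stimulus generators and their matched null controls, the
cone-contrast colorimetry, a Bayesian psi adaptive staircase with simulated
Weibull observers, the threshold statistics, and a miniature event-related
design/GLM pipeline, with synthetic-data generators so every stage is
testable without external data.

# Stimulus model

All stimuli are sequences of per-eye dot frames inside an annular aperture
(inner radius 0.5°, outer radius 5°), sampled at 120 Hz for 3 s, with a
monocular density of one dot per square degree (78 dots in the default
annulus) and dot centers at least 0.5° apart. Dots take positive or negative
contrast polarity with probability 0.5. A raised-cosine contrast envelope
(`contrast_envelope()`) ramps over 0.75 s at either end, leaving a 1.5 s
plateau at peak contrast.

## CD stimulus and control

Signal dots are binocular pairs displaced horizontally by the disparity
signal $d(t) = A \sin(2\pi f_{CD} t)$ with $A = 24$ arcmin and $f_{CD} =
1.4$ Hz, applied symmetrically as $\mp d(t)/2$ per eye (disparity is
right-eye $x$ minus left-eye $x$; positive = uncrossed). The peak disparity
stays well within the ±32 arcmin fusional range. In fMRI mode every frame
regenerates all dot positions, which removes coherent monocular motion; in
behavioral mode positions are held for 4 consecutive frames (and dot
diameter doubles) while $d(t)$ continues to evolve at its usual rate. At
coherence $c$, `round(c * N)` of the $N$ per-eye dots are signal pairs; the
rest are placed independently per eye and carry no systematic disparity.
The CD control shuffles the frames of a fully coherent CD sequence in time:
each frame's disparity content is preserved (the disparity multiset is
identical), but the smooth temporal change conveying MID is destroyed.

## IOVD stimulus and control

IOVD dots translate horizontally with velocity $v(t)$ in one eye and
$-v(t)$ in the other. Three measures jointly remove residual disparity
("CD leakage"): the per-eye dot patterns are decorrelated; the display is
divided into horizontal stripes assigned alternately to the two eyes; and
any interocular dot pair falling within `anticorr_radius` near a stripe
border is forced to opposite polarity. Anticorrelation constraints can chain
(one dot near two others), so polarity is resolved per frame by two-coloring
each connected component of the proximity graph — always possible because
edges only join the two eyes, making the graph bipartite.

Dots live at most 50 ms (6 frames), and the same number of dots is
regenerated in new positions on every video frame so that visual transients
are balanced. Noise dots (fraction $1-c$ per eye) move at the same speed as
signal dots but split evenly between leftward and rightward within each eye,
nulling their net contribution to the interocular velocity difference. The
IOVD control applies that balanced split to *all* dots in both eyes: the
monocular speed distribution is unchanged while the opponent binocular
signal vanishes.

Two numerical subtleties are worth recording:

* **Lifetime scheduling.** With $N$ dots per eye and a 6-frame lifetime, the
  per-frame regeneration quota is $q = \lceil N/6 \rceil$. Dots are retired
  by a per-group largest-deficit rule (FIFO within group) rather than plain
  oldest-first: because the schedule depends only on group pool sizes, both
  eyes always retire the same mixture of signal/leftward/rightward dots, so
  the surviving population has identical composition in the two eyes and
  the control's velocity-difference trace cancels to numerical noise. The
  rule still guarantees the hard lifetime cap and a constant regeneration
  count.
* **Constraint margins.** Moving dots are spawned only where their entire
  lifetime trajectory stays inside the annulus (so no dot ever exits
  mid-life and the regeneration count never has to absorb escapes), and
  with an extra pairwise margin of twice the peak lifetime displacement
  against dots moving in a different direction, so the 0.5° minimum
  separation holds on *every* frame, not only at spawn.

## The displacement/velocity ambiguity

The stimulus description pins both a ±100 arcmin monocular displacement and
a 0–1.7°/s monocular velocity range to the same 1.1 Hz oscillation; for a
sinusoid these are mutually inconsistent (a 100-arcmin, 1.1 Hz positional
sinusoid peaks at ≈11.5°/s). Both readings are implemented:
`iovd_profile_mode = "velocity_matched"` (the default) uses
$v(t) = 1.7 \sin(2\pi\,1.1\,t)$ °/s, because the 1.7°/s figure is tied to
the peak of the IOVD velocity sensitivity curve; `"displacement_matched"`
uses a 100-arcmin positional sinusoid. Neither is asserted to be the
original intent.

# Colorimetry

Stimuli are specified in LMS cone-excitation space and converted to device
RGB through a `display_model()` (gamma linearization followed by a 3×3
RGB-to-LMS matrix). Measured display spectra are not available, so
`default_display()` is a *synthetic* model representative of an LCD: a
Hunt–Pointer–Estévez-flavored cone matrix with gamma 2.2 and a background
placed so that the S-cone-isolating Michelson contrast is gamut-limited at
≈45% — the regime the contrast-scaling rule assumes. Tests treat the 45%
figure as approximate (±2 points), never to the third decimal.

Achromatic dots modulate L, M and S with equal Michelson contrast; S-cone
dots modulate S only. The achromatic contrast is set to 10% of the S-cone
contrast (`scale_achromatic_contrast()`), i.e. 4.5% Michelson at the 45%
gamut limit, balancing the salience and early-cortical drive of the two
axes.

Isoluminance is handled as in heterochromatic flicker photometry: the
lime/violet S-axis alternation is nulled by adding $k$ units of (L+M)
contamination until the luminance modulation $w_L \Delta L(k) + w_M \Delta
M(k) + w_S \Delta S$ vanishes. Contamination enters linearly, so $k^*$ has
a closed form (`solve_isoluminance()`), which the simulated task
(`simulate_flicker_task()`, three settings per eye plus Gaussian adjustment
noise) is built around. The 7.5 Hz alternation rate affects only the
narrative of the task; no temporal filtering model is included.

# Psychophysics

The simulated observer is a Weibull 2AFC model parameterized directly in
its 80%-correct point: $P(x) = \gamma + (1-\gamma-\lambda)\,(1 -
e^{-k (x/\alpha_{80})^\beta})$ with $\gamma = 0.5$, lapse $\lambda = 0.02$,
and $k$ solved so that $P(\alpha_{80}) = 0.80$ exactly.

The adaptive procedure is the psi method: a posterior over a grid of
(threshold, slope) hypotheses — 41 log-spaced thresholds over 1–100%
coherence × 25 log-spaced slopes over 0.5–10, uniform prior, fixed guess
and lapse — is updated by Bayes' rule after each trial, and the next trial
is placed at the integer coherence (1–100%) minimizing the expected
posterior entropy. These grid choices are standard psi-method practice; the
source protocol does not specify them. Because the grid is parameterized in
the 80% point itself, the posterior mean and SD are already in threshold
units.

A session per condition consists of one practice run (discarded) and two
test runs, each with two interleaved 30-trial staircases in strict
alternation, yielding four (threshold, SE) estimates. Subject-level
thresholds aggregate the four estimates with weights $1/SE$ — the literal
"inverse of its SE" rule; inverse-variance weighting ($1/SE^2$) is
available through an argument, with no claim about which was originally
intended. The S-cone performance decrement is the achromatic minus the
S-cone variance-weighted threshold within a cue; negative values mean the
S-cone stimulus needed more signal.

# Event-related designs and the GLM

A run schedules five repeats of each of nine conditions (eight stimulus
conditions plus blank) in seeded random order; seven runs give 35 events
per condition. ISIs are multiples of 1.5 s within 3–12 s. The retained run
lasts 330 s (110 volumes of TR 3 s after discarding 4 dummy volumes), which
a uniform ISI draw (mean 7.5 s) essentially never fits; since only the ISI
*range* is given (the original schedules were optimizer-generated), the
generator instead distributes the available slack — 42 steps of 1.5 s over
44 gaps — uniformly at random subject to the per-gap cap. Every schedule
respects the printed range and fits the run exactly.

The HRF is a gamma density with mean lag 6 s and SD 3 s (shape 4, scale
1.5; mode 4.5 s), normalized to unit peak so that betas are comparable
across conditions; a difference-of-gammas variant subtracts a delayed
undershoot. The 3 s presentation is modeled as a full 3 s boxcar (the
cosine contrast ramp is a rendering property, not a regressor property).
Design matrices contain one convolved regressor per non-blank condition
plus an intercept; blanks live in the baseline. Fitting is ordinary least
squares; prewhitening is not reimplemented, but OLS unbiasedness under
AR(1) noise is verified by simulation. Subjects whose mean variance
explained across ROIs falls below 5% are dropped (`qc_filter()`).

Differential responses Δβ (MID minus matched control, per cue ×
chromaticity) feed a within-subject factorial ANOVA. The reported effect
size is partial η² = SS_effect/(SS_effect+SS_error) — the quantity the
source literature labels "ε² partial" — and Greenhouse–Geisser ε corrects
the degrees of freedom of any factor with more than two levels (at two
levels ε = 1 identically). Sums of squares and ε come from `car::Anova()`
on a multivariate linear model; the test suite checks them against the
paired-t algebraic identity (2×2 interaction F = t²) and an independent
covariance-based ε estimator.

# Synthetic cohorts

`simulate_psychophysics_cohort()` draws each subject's condition thresholds
as condition mean + shared subject offset + independent condition jitter.
The shared offset encodes the within-subject design's assumption that a
generally good observer is good in every condition. The default condition
means (CD 25/60%, IOVD 35/45% for achromatic/S-cone) lie in the ranges the
human group data display and embed a CD decrement of about −35 points
against an IOVD decrement of about −10 — configuration values, not claims
about any particular dataset. Defaults of 8% between-subject SD and 4%
condition jitter are plausible spreads for coherence thresholds; they are
configurable.

`simulate_bold()` builds voxel time series as design matrix × true β plus
AR(1) noise (innovations scaled so the marginal SD equals `noise_sd`), with
`default_beta_pattern()` embedding the cue × chromaticity interaction in
the Δβ structure (CD larger achromatic, IOVD larger S-cone).

What the generators deliberately do not emulate: lapses drifting over a
session, learning effects, hemodynamic nonlinearity, physiological noise
spectra, retinotopic spatial structure, or scanner drift. Passing tests
therefore certify the *pipeline* — that injected effects of realistic size
are recovered through staircases, aggregation and GLM fitting — not the
behavior of human observers or real scanners.

# Problem sizes and numerical choices

* Sequence-level tests use 0.2–1.5 s sequences (the generators are
  parameter-identical to the 3 s defaults); full 3 s sequences are used
  where lifetimes and plateau durations are measured.
* Staircase calibration uses 100 sessions (the acceptance script) and
  recovery/coverage properties use 60 sessions in the test suite; cohort
  recovery uses 3 cohorts of 4 subjects.
* Sinusoid fitting scans 0.2–3 Hz in 0.01 Hz steps (bracketing both
  stimulus frequencies) with local refinement of the best grid point;
  constant traces are flagged rather than fitted.
* Rejection sampling caps at 10,000 attempts per dot and then reports the
  density as infeasible; all randomness flows through integer seed mixing
  (`(seed, counter...)` → 32-bit seed), so every artifact is exactly
  reproducible and independent across substreams.
* Degenerate inputs are defined rather than left to chance: identical
  vectors give t = 0, p = 1 (a constant nonzero difference gives a flagged
  infinite t); all-equal ANOVA tables give F = 0; all-zero regressors are
  excluded and flagged; a constant trace returns amplitude 0 with the
  frequency marked undefined.

# Known limitations

* The anticorrelation radius and stripe geometry are not constrained by the
  source description; the defaults (1° stripes, radius = dot diameter) are
  exposed as parameters. With 1° stripes every dot is within one stripe
  height of a border, so the border condition is effectively global.
* `rm_anova()` supports up to three within-subject factors and complete
  balanced tables only; mixed between/within designs are out of scope.
* The renderer (`render_frame()`) is for inspection; it makes no attempt at
  photometric calibration of output files.
* Staircase simulation operates on the psychometric model directly; it does
  not render dot sequences per trial. The link from coherence to dot-level
  structure is exercised separately by the stimulus-core tests, which share
  the same coherence semantics.
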