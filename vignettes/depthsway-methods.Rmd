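---
title: "Measuring postural sway from a depth camera: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring postural sway from a depth camera: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthsway)
```

## The measurement problem

Standing balance is commonly quantified as *postural sway*: the small,
continuous excursion of the body's centre of mass (CoM) around its mean
position during stance. The reference instrument is a force plate, which
measures the centre of force (CoF) under the feet and projects it to a CoM
estimate; computerised posturography platforms run the six-condition Sensory
Organisation Test (SOT, conditions *a*–*f*) on such plates, manipulating
vision and support-surface stability to grade the balance challenge.

`depthsway` implements an alternative measurement chain that needs only a
consumer depth camera: the camera's fitted 25-joint skeleton stream is
turned into a 2D CoM path, sway is summarised as an RMS statistic, and the
camera method is compared against the plate method with the standard
method-agreement toolkit (Bland–Altman bias and limits of agreement,
repeatability coefficients). A seeded simulator stands in for the hardware
so that every stage — and the agreement analysis itself — is exercised end
to end in software.

## The camera pipeline

A recording is a `skeleton_sequence`: nominally 30 Hz frames of 25 named
joints in camera space (axis 1 mediolateral ML, axis 2 superior–inferior SI,
axis 3 anterior–posterior AP/depth; metres). The pipeline
(`com_path()`) applies four steps:

1. **Mirror** (`flip_ml()`). The camera views the subject from behind (the
   visual surround occludes the front), so its ML axis is reversed relative
   to the plate frame; the ML coordinate of every joint is negated.
2. **Align** (`align_to_first()`). Every frame is rigidly translated by
   minus the first frame's three-joint centroid, so all movement is relative
   to the initial stance. A whole-frame translation preserves intra-frame
   geometry exactly; because sway later de-means the path, the choice of
   alignment anchor cannot affect the sway statistic, which is why we fixed
   the simplest rigid convention rather than any per-joint scheme.
3. **CoM per frame**. The primary estimator (`com_three_joint()`) is the
   coordinate-wise mean of left hip, right hip and mid-spine — three joints
   the camera tracks reliably at standing height, and ones whose position
   already integrates the rest of the kinematic chain. A segmental
   total-body estimator (`com_tbcm()`, Dempster-style mass fractions in
   `default_segment_table()`) is provided as a comparator; it is more
   sensitive to poorly tracked distal joints and is not the primary method.
4. **Emit**. The SI axis is dropped and the 2D (ML, AP) path is converted
   from metres to millimetres — the only unit conversion in the chain — at
   the native timestamps, with no resampling or filtering.

Recordings are screened first (`validate_recording()`): a core joint
untracked in more than 5% of frames marks a *malformed skeleton*, and a
duration differing from the simultaneous comparator recording by more than
0.5 s marks an *out-of-sync* recording. Both thresholds are our
operationalisation of what is, in a live study, a manual screening step, and
both are exposed as arguments. Isolated dropouts of a core joint within the
5% tolerance are linearly interpolated in time rather than discarded, since
screening is meant to remove consistently bad recordings, not single lost
frames. The default reference duration is 20 s, a standard SOT trial
length. When several exclusion rules fire, the first in the documented
precedence order (out_of_sync, malformed_skeleton, fall, over_recording,
harness_confusion) is recorded, so every excluded trial carries exactly one
reason.

## The force-plate comparator

The plate estimates CoM from CoF under a rigid inverted-pendulum model
pivoting at the ankle: the CoM sits at a fixed fraction **0.5527** of the
subject's stature (so a 172 cm subject carries it at 95.06 cm), and quiet
stance includes an average anterior lean of **−2.3°**. `cof_to_com()`
removes the modelled lean as a static AP offset, `a' = a − c·tan(−2.3°)`,
forms the sway angles `θ = atan(a'/c)`, and returns the horizontal CoM
displacement `c·tan(θ)` at the plate's 100 Hz. Algebraically this composition
is the identity on the lean-corrected CoF — the model's content is the
*geometry*, and any constant-offset convention (per-sample correction vs
calibration offset) yields identical sway because the sway statistic is
translation-invariant; this equivalence is asserted in the test suite rather
than assumed. No filtering is applied to the 100 Hz trace.
`com_to_cof()` is the exact inverse and drives the simulator's plate
channel.

## Sway

Foot placement is not reproducible across trials or methods, so sway is
computed on the de-meaned path: the resultant distance
`RD_i = sqrt((ML_i − mean(ML))² + (AP_i − mean(AP))²)` and

`swayRMS = sqrt(sum(RD²) / N)`.

Note the population (1/N) normalisation — the definition fixes it, and it
gives the exact identity `swayRMS = sqrt(popvar(ML) + popvar(AP))`, which the
tests verify on random paths to 10⁻⁹ mm along with translation and rotation
invariance and scale equivariance. Each method's sway is computed at its
native rate (30 Hz camera, 100 Hz plate); no detrending, filtering or
resampling is applied. Supplementary stabilometric summaries (path length,
mean velocity, 95% prediction-ellipse area) are available behind
`sway(..., extras = TRUE)` but are not part of the agreement surface.

## Agreement analysis

`bland_altman()` works on all paired records without averaging repeats
(an `average_repeats` switch is provided in `agreement_report()` for the
alternative convention): bias = mean difference, SD of differences with
1/(n−1), limits of agreement at bias ± 1.96·SD, bias CI via the t
distribution, and LOA CIs via the large-sample standard error
`SD·sqrt(3/n)`. The 1.96 multiplier is fixed: it is what "two standard
deviations" operationally means in the reference arithmetic the tests pin
down (bias 0.12, SD 0.38 → LOA −0.62 to 0.86 at 2 dp).

Repeatability of one method uses paired repeats: within-subject SD
`sqrt(Σ d_j² / 2m)` over m pairs and the 95% repeatability coefficient
`CR = 1.96·√2·SD ≈ 2.7718·SD`. This CR definition reproduces the reference
repeatability rows at 2 dp (e.g. SD 7.37 → CR 20.43; SD 1.14 → CR 3.16),
which is how it was selected among the minor variants in circulation.

Significance of absolute agreement comes from the two-tailed one-sample
t-test of zero mean difference, with the Wilcoxon signed-rank test as the
nonparametric cross-check. Differences are screened for normality with
Shapiro–Wilk (base R) and the D'Agostino–Pearson omnibus K² test, which we
implement from the standard skewness (D'Agostino 1970) and kurtosis
(Anscombe–Glynn 1983) normalisations; it matches an independent reference
implementation to 10 decimal places in the tests and requires n ≥ 8.
Report display rounds to 2 decimal places, half away from zero.

## The simulator

No public dataset pairs skeleton streams with plate traces, so
`generate_study()` simulates the study conditions.

**Sway process.** True CoM sway is a 2D stationary Ornstein–Uhlenbeck
(mean-reverting Gaussian) process, independent in ML and AP, with
mean-reversion rate `θ = 2π·bandwidth`. We chose OU because it is
stationary, its bandwidth is one interpretable knob, and its stationary RMS
is in closed form — the diffusion is set exactly so the stationary resultant
RMS equals the preset target (per-axis SD = target/√2). One path is drawn on
a 300 Hz grid (the least common multiple of the two device rates) and
subsampled to 30 and 100 Hz, so both channels observe the same motion.

**Condition presets** (`sot_presets()`): target RMS 2.9, 4.2, 4.0, 5.8, 17,
15 mm for conditions a–f — the characteristic magnitudes of the six SOT
challenges — with bandwidth 0.3 Hz for the quiet conditions and 0.6 Hz for
the support-perturbed ones (sway is a sub-hertz phenomenon; perturbation
adds faster content), 20 s trials throughout.

**Skeleton synthesis.** A template standing body (standard anthropometric
landmark heights as fractions of stature, documented in
`template_skeleton()`) is scaled to the subject and driven so the
three-joint centroid follows the true path exactly before noise. The
strategy-mix parameter λ shapes the motion: fraction 1−λ translates the
whole body (ankle strategy); the remainder is a trunk lean in which joints
displace proportionally to their height above the pelvis, normalised so the
centroid excursion is preserved (hip strategy). λ rises with the perturbed
conditions (0 → 0.7). This is an operational device for producing
hip-dominated kinematics, not a biomechanical claim. Per-joint Gaussian
tracker jitter (default SD 2 mm) and the rear-camera ML mirror complete the
channel. The plate channel applies `com_to_cof()` (including the static lean
offset) plus 0.5 mm sensor noise.

**Calibration without tuning.** Preset targets and injected between-method
biases refer to *measured* sway — the quantity the devices report, noise
included. Two analytic corrections make that exact in expectation: the
finite-window shrinkage of the population-variance estimator for an OU
process (`E[popvar] = s²(1 − S/n²)` with `S = ΣΣ e^{−θΔ|i−j|}`, computed in
closed form per grid) and the additive variance contributed by sensor noise
(joint noise averaged over three joints for the camera; plate noise
directly). The true stationary RMS and the plate-channel scale are solved
from these, so nothing is fitted to test outcomes. Between-method bias is
injected physically, by scaling the plate channel's shared true path —
mimicking a pendulum model that mis-scales sway as the hip strategy takes
over — and defaults to the characteristic pattern of growing disagreement
with difficulty (0.12, 0.45, 0.09, 0.64, 1.64, 1.69 mm for a–f); pass
`bias_add_mm = 0` for a null study.

**Determinism.** All randomness flows from one master seed through
per-trial seed streams; the same seed reproduces a study byte for byte.

**What the simulator does not model.** Human inter-trial variability (a
person's true sway differs between repeats far more than finite-window
sampling does), soft-tissue and clothing artefacts, tracking failures that
are systematic rather than Gaussian, support-surface rotation mechanics, and
any genuine kinematic disagreement between a pendulum CoM and a skeletal CoM
beyond the injected scaling. Consequently simulated repeatability SDs are
much smaller than a human cohort's, and passing recovery tests demonstrates
correctness of the measurement chain and the statistics — not that the
camera method agrees with plates in people.

## Numerical choices and edge cases

* Pipeline identity in the noise-free limit holds to < 10⁻⁶ mm (camera) and
  < 10⁻⁹ mm (pendulum round-trip); these are asserted, not nominal.
* At the quietest preset (≈ 3 mm sway) the default 2 mm joint noise adds a
  noise floor of ≈ √(8/3) mm² to the camera channel's squared sway — about a
  5% inflation — which is why `generate_study()` calibrates against measured
  sway and why recovery-versus-truth checks are run at the perturbed presets.
* Zero-variance differences (identical paired measurements) are flagged
  degenerate: LOA collapse to the bias and test p-values are NA rather than
  fabricated.
* A constant path has sway exactly 0; a circle of radius r about its
  centroid has sway exactly r — both are used as closed-form anchors.
* Problem sizes in the routine suite: 20-seed recovery studies, 500-replicate
  calibration checks; the deeper acceptance checks use 1000 random paths,
  2000 null replicates, 50-seed medians and a 25-subject simulated study.
  These sizes give Monte-Carlo error comfortably inside the asserted bands.

## Using the package

```{r example, eval = FALSE}
study <- generate_study(n_subjects = 15, repeats = 2, seed = 1)
agreement_report(study$data)     # per-condition bias, LOA, CIs, tests
repeatability_report(study$data) # per-condition x method SD and CR

# single-trial view
tr <- generate_com_process(sot_presets()[1, ], seed = 1)
sk <- synthesize_skeleton(tr, seed = 2)
p  <- com_path(sk, "three_joint")
sway(p)
```

A command-line front end with `simulate`, `process`, `sway`, `agree` and
`config show` subcommands ships at
`system.file("cli", "depthsway.R", package = "depthsway")`.
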