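---
title: "Methods: simulating and analysing 2D video gait reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing 2D video gait reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitagree)
```

## What this package models

Clinical gait analysis with a 2D video tool is cheap and accessible, but its
measurements carry several distinct error sources: markers are re-palpated
and re-placed at every session, observers choose the initial-contact frame
and click marker centroids by eye, and the camera's perspective distorts a
sagittal plane viewed from 2.5 m away and 1 m above the floor. `gaitagree`
implements (i) the sagittal hip/knee/ankle angle constructions used with
such video tools, (ii) initial-contact detection from the vertical ground
reaction force (20 N threshold) and from heel kinematics, (iii) the
agreement statistics of a reliability study (ICC with F-based CIs,
Bland–Altman limits of agreement, paired t tests, Walter's sample-size
formula), and (iv) a synthetic cohort generator whose variance components
mirror that error structure, so the entire pipeline can be exercised and
validated end to end without any raw motion-capture data.

## Angle conventions

All signed angles assume x = direction of progression, y = up; frames whose
pelvis markers indicate walking toward −x are mirrored first, which makes
flexion and dorsiflexion signs direction-independent.

* **Hip**: the line through ASIS and PSIS defines the pelvis; its caudal
  perpendicular through the greater trochanter is the reference, and the
  hip angle is the signed angle from that reference to the GT→LFC thigh
  line. A vertical thigh under a level pelvis reads 0°; anterior = flexion
  = positive. Note the reference is the *pelvis* perpendicular, not the
  world vertical, so pelvic tilt does not masquerade as hip motion.
* **Knee**: 180° minus the inner angle at the femoral condyle between the
  greater trochanter and the external malleolus. A manual unsigned angle
  tool cannot distinguish flexion from hyperextension, so the side of the
  malleolus relative to the extended thigh line assigns the sign
  (posterior shank = flexion = positive).
* **Ankle**: 90° minus the angle between the foot line (CAL→MT2) and the
  shank line, with dorsiflexion positive. Of the two inner angles between
  those lines we fix the one between the *anterior* foot ray and the
  *proximal* shank ray (the convention under which a typical heel-strike
  posture reads ≈ −8°, i.e. plantar flexed); the alternative choice flips
  the sign pattern and is inconsistent with normal gait values.

All three constructions are invariant to translation, scaling (metres vs
pixels) and in-plane rotation, and are computed with two-argument
arctangents rather than `acos`, which is unstable near collinearity. They
are validated against an independent rotation-matrix oracle on 1000 random
poses at 1e−6 degrees.

## Event detection

The force rule takes the first sample at/above 20 N that *stays* above it
for `min_above` consecutive samples; the dwell (default 10 samples = 10 ms
at 1000 Hz, the threshold itself being the only published constant) rejects
pre-contact spikes. The kinematic surrogate for visual frame selection
takes the first local minimum of the heel-marker height within a search
window — with the generator's foot-flat plateau this is exactly the first
frame of ground contact. Frames and samples are 0-based everywhere,
including exported CSV headers.

## The synthetic cohort generator

Each subject draws a stature (1.67 ± 0.26 m, truncated to 1.40–2.00 m with
resampling), height-scaled segment lengths, and subject-level true
initial-contact angles (hip 33.06 ± 5.7°, knee 4.55 ± 3.8°, ankle −7.77 ±
3.7°, the healthy-adult values the generator is calibrated to). Joint-angle
curves over the gait cycle are two-harmonic least-squares fits to a coarse
normative sagittal profile, shifted additively so each curve passes
*exactly* through the subject's targets at the contact phase — smooth,
periodic, and analytically evaluable, which the frame-shift sensitivity
test exploits. A planar forward-kinematics chain places the nine markers
(ASIS, PSIS, GT, THI, LFC, TIB, LM, CAL, MT2); a vertical whole-body
translation keeps the heel on the floor through foot-flat and lands it with
zero vertical velocity at contact (translation only, so no joint angle is
altered by the ground-contact emulation).

The error structure, per `error_model()`:

| component | acts on | default | rationale |
|---|---|---|---|
| `sd_subject` | true IC angles | 5.7/3.8/3.7° | published between-subject SDs |
| `sd_session` | marker placement, per marker | 2–8 mm | re-palpation error is landmark-dependent (GT worst, foot markers best); calibrated so intra-rater ICC ≈ 0.85–0.9 |
| `sd_observer_frame` | IC frame choice | 0.5 frames | observers agreed on the event to within a frame |
| `sd_digitize` | marker clicks | 1 px | ≈ 2.5 mm at the working distance |
| `sd_residual` | per-trial true angles | 1.2° | stride-to-stride variability |
| `system_bias` | reference offset | 0.4/1.6/−2.0° | with the perspective contribution (≈ +0.4 to +0.7°) this centres the video-minus-reference bias near the published 0.8/2.0/−1.3° |
| `sd_system`, `sd_system_subject` | reference noise / subject-level disagreement | 1.0°, 1.2° | widens system limits of agreement to the published ±2.5–5° |
| `sd_force` | force plate | 1 N | keeps 20 N detection within ±2 samples |

The video system is measured by actually projecting the (placement-
perturbed) markers through the camera and re-running the angle
constructions on the digitized 2D points. Marker depths differ (lateral
markers sit closer to the camera), so perspective genuinely distorts the
geometry — that, not an injected offset, is the mechanism for part of the
video-vs-reference disagreement. The 3D reference system is *emulated* as
ground truth plus per-joint bias and noise; re-implementing a full
multi-segment 3D model would add nothing to the statistics under test. One
consequence: the zero-noise-equals-truth invariant holds under orthographic
projection; under perspective the depth geometry itself produces a small,
wanted distortion. Degenerate/zero-noise tests therefore use the
orthographic camera.

Randomness is funnelled through one base seed with deterministic substreams
per subject/session, so cohorts are bit-reproducible and adding subjects
does not perturb existing ones.

What the generator does *not* emulate: soft-tissue artefact, marker
occlusion and tracking dropouts, non-sagittal motion leaking into the view,
observer learning effects, and any difference between the emulated
reference and a real 3D model's segment definitions. Passing tests
therefore demonstrate the correctness of the computational pipeline and the
internal consistency of the statistics under a realistic variance
structure — not field performance on real video.

## Agreement statistics

`two_way_anova()` decomposes an n×k complete ratings matrix; `icc_single()`
implements both single-measures forms — absolute agreement,
r = (MSR − MSE)/(MSR + (k−1)MSE + (k/n)(MSC − MSE)), and consistency,
r = (MSR − MSE)/(MSR + (k−1)MSE) — with the standard F-based 95% CIs
(Satterthwaite degrees of freedom for absolute agreement). The study this
package emulates labelled its index "ICC 3,1" while describing *absolute
agreement*; those two descriptions conflict (ICC(3,1) is the consistency
form), so the pipeline defaults to absolute agreement — what SPSS computes
under that description — and always reports both. Estimates are checked
against an independent reference implementation at 1e−9 on random
matrices, and CI coverage is verified by simulation (95% ± 2% over 500
cohorts at n = 50, k = 2).

Bland–Altman limits of agreement use the fixed 1.96 multiplier on the
sample SD of differences (the bias CI, in contrast, is t-based).
`loa_from_summary()` inverts a published mean difference + t-based 95% CI
back to the SD of differences, which lets published limits be audited for
internal consistency: of the video-vs-reference rows the package carries in
`reference_study_summaries()`, only the knee limits are reproducible from
their own MD + CI (to < 0.1°); the hip and ankle rows are not, and the hip
MD itself (0.80) disagrees with the difference of the published means
(0.86). These inconsistencies are flagged rather than "corrected".

`walter_sample_size()` evaluates the closed-form reliability-study size
n0 = 1 + 2k(z_α + z_β)² / ((k−1)(ln C0)²), C0 = (1 + kθ0)/(1 + kθ1),
θ = ρ/(1−ρ). With ρ0 = 0.6, ρ1 = 0.8, k = 2, *one-sided* α = 0.05 and
power 0.8 this gives n0 = 39 and, inflated multiplicatively by 10%
attrition and ceiled, an enrolment target of 43 — the published
requirement. One-sided α and ×1.1 inflation are the only choices under
which 43 is reproduced; both are documented here as deliberate.

## Design decisions and numerical choices

* **Repetition aggregation**: the five repetitions per design cell are
  averaged before reliability analysis (`aggregation = "mean"`,
  configurable to `"first"`). The emulated study does not state its rule;
  the mean is the least-variance default.
* **Contrast difference orders** are fixed and documented: session1 −
  session2, observer1 − observer2, video − reference. Inter-rater and
  system contrasts use session 1 (configurable), matching how the
  published observer-1 session-1 means reappear in the between-system
  table.
* **Band boundaries**: ICC labels follow the printed bands — excellent
  (> 0.9), good (0.76–0.9), moderate (0.5–0.75), poor (< 0.5) — with the
  unprinted gap (0.75, 0.76) mapped to "good", 0.9 to "good" and 0.75 to
  "moderate".
* **Numerical zero**: paired differences whose largest magnitude is below
  1e−9° are treated as exactly zero, so floating-point residue from the
  extraction chain cannot yield spurious p-values in degenerate cohorts.
* **No multiple-testing correction** is applied (none was in the design
  this emulates); reports state p-values per joint and contrast.
* **No marker smoothing** is applied by default.
* **Problem sizes**: the validation suite uses cohorts of 3–10 subjects
  for structural checks and the full 50-subject design for calibration
  checks over a handful of seeds; CI-coverage simulations use 500
  replicate 50×2 matrices, which estimates coverage to about ±1%
  (binomial SE). These sizes were chosen to make the checks statistically
  meaningful while keeping the suite quick to run.

## Known limitations

The generator's marker-placement error is applied in each marker's segment
frame and held fixed within a session — a small-angle idealization of skin
movement. Force and video are perfectly synchronized (no trigger offset is
modelled). Only the left limb and the initial-contact phase are modelled,
and only sagittal angles; none of the statistics here generalize to other
gait phases or planes. Emulated-reference caveat: system-agreement results
quantify the pipeline's behaviour under the *configured* disagreement
mechanism, not the true disagreement between a video tool and any
particular 3D system.
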