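---
title: "Joint-freezing surrogate analysis of bowing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-freezing surrogate analysis of bowing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowfreeze)
```

## The model

Bowing performance lives at the end effector — the bow — but is produced by
rotations and translations distributed over the right arm. `bowfreeze`
represents a motion-capture trial as a kinematic chain of per-frame
rigid-body motions:

* a **root pose**: the scapula's local coordinate system (LCS) in the lab
  frame;
* three **joint motions**: the upper-arm LCS expressed in the scapula LCS
  (shoulder), the lower-arm LCS in the upper-arm LCS (elbow), the hand LCS
  in the lower-arm LCS (wrist);
* a **grip motion**: the bow LCS in the hand LCS.

Each LCS is built per frame with a Gram–Schmidt construction
(`gram_schmidt_frame()`) on two marker-derived vectors: scapula from
sternum → shoulder center with the global vertical fixing the secondary
axis; upper arm from shoulder → elbow center with the lower-arm axis
fixing the secondary (valid as long as the elbow does not hyperextend —
degenerate frames are flagged and excluded, never patched); lower arm from
elbow → wrist center crossed with the radial–ulnar wrist marker line; hand
from wrist → first knuckle crossed with the same wrist line; bow from its
two markers with the distal finger marker (the first interphalangeal,
`pip1`, the most distal hand marker) closing the frame. Joint centers are
virtual markers, either estimated from surface markers and anthropometric
thicknesses (`estimate_joint_centers()`) or emitted exactly by the
generator.

Two representational choices make the analysis exact rather than
approximate:

* **Per-frame local marker offsets.** Marker positions are stored as
  per-frame offsets in their owning segment's LCS, not as one rigid
  template. Reconstruction of an unmodified chain therefore reproduces the
  input markers to numerical precision (round-trip error ~1e-13 mm) even
  in the presence of soft-tissue wobble or marker noise, and a frozen-joint
  surrogate differs from the original *only* through the frozen joint:
  markers proximal to it are bit-identical.
* **6-DoF freezing.** `freeze_joint()` replaces a joint's full rigid
  motion — rotation *and* translation — by its value at a reference frame:
  the midpoint (`floor((start+end)/2)`) of the first analyzed stroke for
  the movement measures, the first analyzed reversal for the acceleration
  measure.

## Bow kinematics and measures

The scalar bowing coordinate is the signed arc-length position, along the
bow's long axis from the proximal bow marker, of the point on the bow axis
closest to the string axis (the line through the scroll and tailpiece
markers) — the common-perpendicular foot, i.e. the physically bowed
contact coordinate. Velocity and acceleration are central differences
scaled by the sampling rate. The bow angle is the angle between the
oriented bow and string axes in degrees (orthogonal bowing = 90°); its
per-frame value is well defined whenever the axes are non-degenerate, and
frames with a bow axis (near-)parallel to the string are flagged missing.

Strokes are movements between velocity zero crossings with durations in
[0.5, 1] s (instructed duration 0.75 s); the first ten clean up-bows and
ten clean down-bows are analyzed, with 45-sample (0.75 s at 60 Hz)
windows around the adjacent reversals. Five measures are scored:
amplitude (max − min position per stroke), bow-angle SD, within-bow
velocity variance, and between-bow velocity variance on the central 80%
of each stroke, plus the maximum absolute acceleration per reversal
window.

## Tunable parameters

All tunables live in `freeze_params()`; defaults are the analysis
conditions:

| parameter | default | unit | role |
|---|---|---|---|
| `cutoff_hz`, `filter_order` | 20, 5 | Hz, – | zero-phase Butterworth low-pass, applied forward and backward |
| `target_hz` | 60 | Hz | analysis rate; 120 Hz trials are decimated after filtering |
| `min_stroke_s`, `max_stroke_s` | 0.5, 1.0 | s | admissible stroke durations |
| `reversal_window_s` | 0.75 | s | reversal window; `round(0.75 × rate)` = 45 samples at 60 Hz |
| `central_fraction` | 0.8 | – | stroke portion used for variability measures |
| `n_strokes` | 10 | – | analyzed strokes per direction |
| `hysteresis_frac`, `min_run` | 0.05, 3 | –, samples | reversal-detection hysteresis (see below) |
| `n_points` | 100 | – | normalized-time grid for between-bow variance |
| `accel_peak` | `"max_abs"` | – | acceleration amplitude definition (`"peak_to_peak"` available) |
| `ratio_eps` | 1e-12 | measure units | guard: effects with original measure below this are NA, never ±Inf |

## Numerical and design choices

Where the procedure admits more than one reasonable reading, the package
fixes one and exposes it:

* **Filter, then decimate.** The low-pass (20 Hz) runs at the native rate
  and already prevents aliasing at the 60 Hz target (Nyquist 30 Hz);
  decimation is then plain sample-picking. Filtering is per contiguous
  non-missing block with odd-reflection end padding; blocks shorter than
  the warm-up length pass through and are logged. Missing samples are
  masked, never interpolated — analyzed strokes must be gap-free anyway.
* **Surrogate segmentation reuse.** Stroke and reversal windows are taken
  from the *original* trial and re-applied to the surrogate. This is the
  analysis' most consequential convention: surrogate bow velocity need not
  cross zero at all (a full freeze leaves the bow static), so original and
  surrogate must be compared on identical time windows for the ratios to
  be meaningful.
* **Reversal detection with hysteresis.** A zero crossing counts only
  between velocity states whose magnitude exceeds 5% of the trial's median
  absolute velocity for at least `min_run = 3` consecutive samples; the
  reversal frame is the minimum-|velocity| sample in between (first such
  sample on ties). This suppresses jitter-split strokes near sharp
  reversals without biasing reversal times.
* **Central-fraction trimming** removes `floor(n × 0.1)` frames from each
  end of an *n*-frame stroke — a 45-frame stroke keeps 37 frames (~82%).
* **Population (divide-by-n) variance/SD** throughout the measures; the
  convention cancels in ratios but is fixed for reproducibility.
* **Vertical-referenced scapula.** Following the LCS definition, the
  scapula secondary axis uses the global vertical. Joint motions are
  therefore invariant under vertical-preserving rigid transforms of the
  lab (rotations about gravity plus translations); an arbitrary rotation
  of the world would re-orient the vertical reference and alter the
  shoulder motion, while all joints distal to the scapula remain fully
  invariant.
* **Degenerate inputs.** Near-collinear frame constructions raise errors
  in the scalar API and flag frames as missing in the per-frame pipeline;
  parallel bow/string axes make the contact coordinate undefined for that
  frame; a zero-variance one-sample t against its own mean returns t = 0,
  p = 1, and against any other null is refused.

## The synthetic generator

`simulate_trial()` works in joint space and synthesizes markers through
the same forward model the analysis inverts, so decomposition,
reconstruction, and freezing have exact ground truth. A 4-segment arm
(upper arm 300 mm, lower arm 280 mm, hand 80 mm) hangs from a static
trunk; shoulder, elbow, and wrist rotate about the vertical, sweeping a
650 mm bow (marker separation 217 mm, held rigidly in the hand) along its
own axis across a static horizontal string. Trials default to 20
metronome-paced cycles (0.75 s per bow) at 60 or 120 Hz, with i.i.d.
Gaussian marker noise (σ = 0.5 mm, motion-capture-realistic) and smooth
low-passed per-joint angle noise.

Transport velocity follows `tanh(sin(ωt)/k)` scaled so that the `plateau`
parameter is the fraction of each stroke spent above 90% of peak speed:
`plateau = 0` gives the sinusoidal, bell-shaped profile of point-to-point
movements; `plateau = 0.8` the near-rectangular profile with sharp
reversals characteristic of experts. In compensatory coupling the wrist
counter-rotates against the summed shoulder+elbow rotation; because the
wrist's transport lever (~75 mm from wrist to the bow's contact point) is
much shorter than the shoulder's (~450 mm), the same rotation that cancels
most of the bow-angle deviation also brakes transport a little — the
counter-movement. The presets encode the study conditions:

* `expert_like`: shoulder+elbow transport in phase (0.28 rad each),
  plateau 0.8, wrist cancelling 90% of the proximal rotation plus 5%
  extra braking, small joint noise (0.01 rad).
* `novice_like`: shoulder-only transport (0.25 rad), plateau 0, nearly
  rigid distal joints (0.005 rad noise).
* `independent_noise`: shoulder transport (0.15 rad) plus mutually
  independent smooth angle noise, distal-dominant (0.01/0.02/0.12 rad at
  2.5 Hz). Distal dominance is deliberate twice over: novice wobble is
  anatomically distal, and the short distal levers keep the noise out of
  the bow-velocity channel so stroke segmentation stays clean while bow
  angle is still perturbed — letting the preset instantiate the
  no-coordination null (freezing a joint can only remove variance).
* `compensatory`: the same transport with the wrist cancelling 90% of the
  angle deviation (noise 0.01/0.01/0.02 rad), so freezing the wrist
  removes coordination and *raises* angle variability.

Two geometric idealizations matter for interpretation. First, all joint
rotations are about the vertical, so the task is effectively planar; the
generator is a caricature of coordination structure, not of anatomy.
Second, the simulated wrist marker line is parallel to the rotation axis,
which makes it rigid in both the forearm and hand frames and hence makes
the marker-derived hand LCS exactly rigid with the hand and bow. With an
anatomically oblique wrist line (which moves with the forearm), the hand
LCS wobbles slightly relative to the bow as the wrist flexes, and a full
freeze of all three joints would leave mm-level residual bow motion — an
artifact of the LCS construction, not of the freezing logic. For the same
reason the exact full-freeze and frozen-joint identity checks in the test
suite run on the unfiltered chain: the low-pass acts on each coordinate
independently and breaks rigid-body consistency at the harmonic level
(~1e-3 mm for sharp reversals), which is irrelevant to the mechanism under
test.

What passing tests on synthetic data do **not** show: robustness to
soft-tissue artifact (marker noise is i.i.d., not correlated with
movement), to out-of-plane coordination, to gap-filling practices, or to
real novices' irregular tempo. The acceleration measure deserves extra
caution: second differences amplify marker noise (~0.5 mm noise at 60 Hz
maps to thousands of mm/s²), so reversal-acceleration effects sit on a
noise floor in the simulation — consistent with treating surrogate-based
acceleration results more cautiously than the movement measures, where
mechanical interactions also make real surrogates least realistic.

## Inferential layer

Per group and measure, the six joint × direction cells form one family:
one-sample t-tests of the log10 ratios against 0, Holm-adjusted within the
family (Benjamini–Hochberg available by configuration). Group differences
are tested per cell with a Type-II ANOVA with factors Group, Lab, and
their interaction, reporting the Group main effect — Type II because the
two-lab design confounds group with lab, and only the group effect is of
interest. On balanced designs the Type-II group SS provably reduces to the
classical sequential SS (tested against a brute-force least-squares
oracle).

## Problem sizes

The test suite and acceptance script use 20-cycle trials (30 s, 1800
frames at 60 Hz) for cohort-level checks — 10 simulated participants per
group, matching the study design of 2 experts + 6 novices at the 120 Hz
lab and 8 experts + 4 novices at the 60 Hz lab — and shorter 2–6-cycle
trials for unit-level geometry checks, sizes at which every documented
property is already exact or statistically unambiguous.

## Known limitations

* Purely kinematic: no joint torques, interaction torques, or
  muscle-level constraints; frozen surrogates can be physiologically
  unrealistic, especially around quick reversals.
* No C3D reader: trials enter through the vendor-neutral wide-TSV + YAML
  dialect (`write_trial()` / `read_trial()`).
* No gap filling: trials with missing samples inside all candidate
  strokes yield an empty analyzed set rather than interpolated data.
* The anthropometric joint-center constructions are approximations whose
  offset directions are not exactly rigid in their segments; analyses
  demanding exact center geometry should supply measured or simulated
  center markers directly.
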