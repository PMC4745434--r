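---
title: "Methods: six-degrees-of-freedom and conventional gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-degrees-of-freedom and conventional gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gait6dof)
```

## The measurement problem

Clinical gait analysis reports lower-limb joint rotations — pelvis, hip,
knee, ankle, three rotations each — as curves over the gait cycle.  Two
families of optical marker protocols dominate:

* **Conventional gait models** (Helen Hayes / Newington / Davis lineage):
  single reflective markers on skin over bony landmarks, plus wand markers
  that the assessor aligns by eye to define the thigh and shank frontal
  planes.  Medial landmarks are avoided (they drop out of camera view
  during walking), at the cost of anatomical fidelity: segment axes depend
  partly on manual wand alignment, and the foot is usually reduced to one
  or two degrees of freedom.
* **Six-degrees-of-freedom cluster models** with the *calibrated
  anatomical systems technique* (CAST): each segment carries a rigid
  cluster of at least three noncollinear technical markers; anatomical
  landmarks — including medial ones — are registered once with a tracked
  pointer during a static trial, as constant vectors in the cluster
  technical frame, and reconstructed dynamically as *virtual markers*.
  Every segment is tracked independently, so all three rotations (and
  translations) of every joint are observable, and anatomical frames can
  follow the ISB recommendation exactly.

This package implements both protocols end to end, the repeatability and
protocol-comparison statistics used to evaluate them, and a synthetic
gait generator that supplies ground-truth marker data — the test bed on
which every claim made by the package is verified, since studies of this
design rarely deposit raw recordings.

## Rigid-body machinery

**Cluster pose.** For each frame the cluster pose is the orthogonal
Procrustes solution: given reference geometry $A$ (static-trial mean
marker positions) and observations $B$, the rotation
$R = V \,\mathrm{diag}(1,1,\det(VU^\top))\, U^\top$ from the SVD
$U\Sigma V^\top$ of the weighted cross-covariance minimises the weighted
sum of squared distances; the diagonal factor guards against reflections.
The per-frame residual RMS is kept and surfaced — it is the working
estimate of marker noise plus cluster non-rigidity.  Collinear reference
geometry (second singular value below $10^{-8}$ of the first) is refused.

**Pointer tip.** The protocol never states how a pointer's tip offset is
known, so the package calibrates it: pivoting the pointer about a fixed
point gives, per frame, $R_i t_p + d_i = p$, a linear system in the tip
offset $t_p$ (pointer frame) and pivot point $p$ (lab) solved by SVD
least squares.  Rank deficiency (pure translation, no rotational
diversity) is detected on the smallest singular value.  The residual RMS
is stored with every pointer model.

**Landmark registration** expresses the tip in the cluster technical
frame, $v = R_c^\top(\mathrm{tip} - t_c)$, averaged by default over *all*
static frames (a single instant is also supported).  Averaging over $n$
frames reduces registration scatter roughly as $1/\sqrt{n}$; the tests
verify a better-than-2$\times$ reduction at $n = 50$.

## Anatomical frames

All segment frames are right-handed, X anterior, Y proximal (up), Z to
the subject's right (right limb throughout; left-limb processing would be
by mirroring).

* **Pelvis**: origin mid-ASIS; Z along the inter-ASIS line; X anterior in
  the plane of the ASISs and the PSIS midpoint.
* **Femur**: origin at the hip joint centre (HJC); Y from the epicondyle
  midpoint to the HJC; X normal to the HJC–epicondyles plane.
* **Shank**: origin mid-malleoli; Y towards the tibial condyle midpoint;
  X normal to the plane of Y and the malleolar axis.  The recommendation
  leaves room in the choice of proximal shank landmarks; tibial condyles
  are used here so the frame is rigid in the shank (femoral epicondyles
  would make the "shank" frame move with the femur).
* **Foot**: defined *in the neutral static position* as a copy of the
  shank anatomical frame, then rigidly attached to the foot technical
  cluster.  Ankle angles are therefore zero in neutral stance by
  construction, and the foot has full 3-D freedom afterwards.

The **hip joint centre** uses the Davis (Newington) regression for both
protocols — deliberately, so protocol differences cannot be attributed to
HJC localisation: with $C = 0.115\,L - 15.3$ mm (leg length $L$),
$\theta = 28.4^\circ$, $\beta = 18^\circ$, ASIS–trochanter distance
$d_{AT}$ (measured, or $0.1288\,L - 48.56$ mm), marker radius $r$:

$$x = C\cos\theta\sin\beta - (d_{AT}+r)\cos\beta,\quad
  y = -C\cos\theta\cos\beta - (d_{AT}+r)\sin\beta,\quad
  z = \pm\left(\tfrac{d_{ASIS}}{2} - C\sin\theta\right)$$

in the pelvis frame (origin mid-ASIS).  The tests pin every term of this
implementation to a hand evaluation of the published equations.

The **conventional model** builds the pelvis from ASIS markers and the
sacrum; knee and ankle centres come from the *chord* construction: the
centre lies in the plane of (proximal centre, lateral marker, wand), at
half joint width plus marker radius from the lateral marker, with the
centre–marker segment perpendicular to the centre–proximal segment.  The
wand defines the segment frontal plane — which is exactly where its error
mode lives: the package reproduces the classic cross-talk mechanism by
rotating the synthetic thigh wand about the femur long axis.

## Joint angles

Relative orientation $R_{rel} = R_{prox}^\top R_{dist}$ is decomposed in
the intrinsic **z–x–y Cardan sequence**: flexion about the proximal
mediolateral axis, then ab/adduction about the floating anterior axis,
then axial rotation about the distal longitudinal axis — the ordering
equivalent to the joint coordinate system.  Pelvis angles use the same
sequence against the laboratory frame (tilt, obliquity, rotation).  The
sequence and the right-limb sign table (flexion +, adduction/varus +,
internal rotation +, anterior tilt +, dorsiflexion +, inversion +) are
declared package conventions, exported via `rotation_conventions()`; the
source protocols name the rotations but not their exact sequence, so
these are documented choices rather than inferences.

The middle angle is kept in $(-90^\circ, 90^\circ)$; samples with
$|\beta| > 89.9^\circ$ carry a gimbal flag, and at exact lock the third
angle is fixed to zero by convention.  Curves are unwrapped across
$\pm180^\circ$ jumps.  Decompose-then-recompose is tested to
$10^{-10}$ over random rotations in four sequences.

## Filtering, events, normalisation

Marker trajectories (not angle curves) are smoothed with a **zero-lag
Butterworth** filter: two passes (forward, backward) of a 2nd-order
low-pass, giving an effective 4th order.  Because each pass attenuates,
the per-pass cutoff must be raised; the correction
$(\sqrt{2}-1)^{-1/4} \approx 1.2465$ is applied to the *prewarped* analog
frequency, so the two-pass gain at the nominal cutoff is exactly
$1/\sqrt 2$ rather than the $\approx 0.713$ obtained when correcting the
digital frequency directly.  The series mean is removed and restored and
the ends are extended by point reflection (one 6/cutoff-seconds length),
making the DC gain exactly 1 and keeping end transients outside the
data.  At 100 Hz / 6 Hz cutoff the stop-band attenuation at 25 Hz is
about 50 dB.  A `per_pass` mode designs the named order in each pass
instead (effective 8th order for order 4).

**Foot strikes** are detected as local maxima of the heel position along
the progression axis relative to the pelvis — a documented stand-in for
manual cycle selection; user-supplied event frames always take
precedence, and the study generator stores its ground-truth events.  A
**gait cycle** is ipsilateral foot strike to foot strike, linearly
resampled to **101 points** (0–100 %), endpoints preserved exactly.  Gap
handling is conservative throughout: invalid samples inside a cycle are a
hard error, and gap interpolation exists only as an explicit operation
(`fill_gaps`, cubic spline, interior gaps of at most 10 frames by
default).

## Variability statistics

With cycles $y_{j,i}(s)$ (subject $j$, trial $i$, sample $s$), per
rotation:

* **Intertrial SD curve**: sample SD (denominator $n-1$) across one
  subject's trials, per sample.
* **AIT** (average intertrial variability): intertrial SD curves averaged
  over the 101 samples, then over subjects.  (Averaging over samples
  first or subjects first coincides for balanced designs; the order is
  fixed and documented.)
* **AIP** (averaged intraprotocol variability): per-sample SD across the
  subjects' mean curves, averaged over the cycle — subject-to-subject
  variability.
* **MAV** (mean absolute variability): per subject, mean over the cycle
  of the absolute difference between the two protocols' curves; then
  averaged over subjects.
* **ROM**: max minus min over the cycle.

All statistics are nonnegative, SD and ROM are invariant to constant
offsets, MAV of constant-offset pairs equals the offset, and each is
tested against an independent brute-force loop to $10^{-12}$.  The $n-1$
convention matters at $n = 3$ trials and is stated for that reason.

## The synthetic study

`generate_study()` emulates the validation design the statistics were
built for: **4 able-bodied subjects × 3 gait trials**, 100 Hz, 1 s
stride, plus per subject a neutral static trial, a pointer pivot trial
and one pointer registration trial per landmark.  Angle templates are
truncated Fourier series loosely shaped on normative adult gait (knee
flexion peaking near 60° at ~74 % cycle, hip flexion maximal at initial
contact); they are fixtures, not claims about any population.  Forward
kinematics composes the chain with the *same* Cardan sequence and sign
conventions the analysis uses, and emits clusters, skin/wand markers and
true landmarks.  With the default 100 Hz rate and 1 s stride the
101-point normalisation grid coincides with the sampled frames, so the
noise-free end-to-end recovery can be checked to $10^{-6\,\circ}$
without interpolation error entering the comparison.

**Dispersion injection.** Each rotation receives a constant subject
offset (dispersion $\tau$, default 3°) and a constant trial offset
(within-subject dispersion $\sigma$, default 1°).  Offsets are drawn as
*moment-exact randomisations*: a random permutation of a fixed design
scaled to unit sample SD (for 3 trials this is exactly
$\{-\sigma, 0, +\sigma\}$), plus a Gaussian trial-mean component of
variance $\sigma^2/m$.  The marginal variance of a trial effect is
exactly $\sigma^2$, and — the point of the construction — the *realised*
within-subject SD equals $\sigma$ in every study.  With $n$ as small as 3
trials and 4 subjects, i.i.d. Gaussian draws would realise only
$c_4(n)\,\sigma$ in expectation ($c_4(3)=0.886$, $c_4(4)=0.921$), so a
generator meant to let AIT converge to the injected $\sigma$ and AIP to
$\sqrt{\tau^2+\sigma^2/m}$ must control the realised moments, not just
the population ones.  Under this design AIT recovers $\sigma$ exactly and
AIP lands within ~2 % of the mixture value (the centred trial design
removes part of the $\sigma^2/m$ term; the Gaussian trial-mean component
restores it in expectation).

**Artefacts.** Measurement noise is i.i.d. isotropic Gaussian per sample
(default 0.5 mm).  Soft-tissue artefact is modelled as an en-bloc,
cycle-locked sinusoidal displacement of all markers of a segment
(anterior-superior direction) — deliberately simple: the goal is
controllability and the cluster-level error structure (virtual markers of
a segment move together), not physiological realism.  A thigh-wand
frontal-plane misalignment (degrees about the femur long axis) drives the
conventional model's transverse-plane cross-talk: with 15° misalignment
and the ~60° flexion template, conventional knee internal/external ROM
inflates to more than twice the 6DOF value while the 6DOF pipeline stays
within 1° of truth — the direction of the published contrast between the
two protocols, reproduced mechanistically without claiming its values.

What the generator does *not* emulate: genuine soft-tissue dynamics
(frequency content, subject-specificity), marker occlusion patterns,
event-detection ambiguity of pathological gait, or inter-assessor
placement variability.  Tests passing on synthetic data therefore
validate the *computational* pipeline — geometry, conventions,
statistics — not the clinical accuracy of either protocol on real limbs.

## Numerical choices and problem sizes

* Rotations are validated to orthonormality $10^{-9}$; constructed frames
  are re-orthonormalised by polar decomposition before use.
* Procrustes collinearity tolerance $10^{-8}$ (relative); pivot
  diversity tolerance $10^{-6}$ (relative smallest singular value).
* Rotation averaging (static windows) uses the polar factor of the mean
  rotation matrix.
* The test suite uses 1000-draw Procrustes/pivot Monte-Carlo runs,
  500-rotation Cardan round trips, and 500 replicate 4×3 studies for the
  variability recovery; these sizes give sampling error comfortably
  below the asserted tolerances while keeping the default run in the
  low minutes.
* C3D support covers the floating-point Intel subset with the POINT
  section — the portion needed to carry marker kinematics; analog
  channels and integer scaling are rejected with explicit errors rather
  than half-read.

## Limitations

Right limb only (mirroring is the documented route to the left);
conventional-model variant details beyond the canonical Davis
construction are not modelled; no joint translations are reported even
though the 6DOF marker set observes them; no inferential statistics.  On
real data, event detection is a convenience, not a validated gait-event
algorithm.

## A worked example

```{r, eval = FALSE}
cfg <- simulation_config(seed = 1)          # 4 subjects x 3 trials
dir <- tempfile("study")
generate_study(cfg, dir, format = "c3d")

study <- read_study(dir)
cycles <- process_study(study, c("isb6dof", "hh"), cutoff = 6)
report <- variability_report(cycles$isb6dof, cycles$hh)
report$table                                # 12 rotations x AIT/AIP/MAV
```
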