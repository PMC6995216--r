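---
title: "Measuring hemipelvic displacement patterns from standardized radiographs"
author: "pelvirad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hemipelvic displacement patterns from standardized radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvirad)
```

## The measurement model

A unilateral pelvic ring fracture displaces one hemipelvis as an
approximately rigid body. `pelvirad` describes that displacement in a
pelvis-specific Cartesian frame: **X** mediolateral (positive toward
patient-left), **Y** craniocaudal (positive cephalad), **Z**
anteroposterior (positive anterior), with the origin at the posterior
("trailing") edge of the S1 superior endplate and the midsagittal plane
at X = 0. The posterior endplate edge is taken at the S1 level; the
sacral endplate landmark of the catalog is placed at this origin by
convention, so "center of the sacral endplate" and the frame origin
coincide in the template.

The three standardized views are idealized as mutually orthogonal
orthographic projections: the inlet film is the X/Z plane (it drops Y),
the outlet film the X/Y plane (drops Z), and the AP film a second X/Y
projection that differs from the outlet only in its landmark catalog and
in the component it detects. Beam divergence, magnification, and
positioning error are out of scope: the films are assumed standardized
(in practice, reconstructed or calibrated), which is also why a single
isotropic mm-per-pixel calibration suffices.

A deformity is decomposed into **six basic displacement patterns** — three
translations (along X, Y, Z) and three rotations. Rotations are named
anatomically rather than by axis: *sagittal* (flexion/extension, about
the mediolateral axis), *axial* (internal/external, about the
craniocaudal axis), *coronal* (abduction/adduction, about the
anteroposterior axis). The anatomical naming is deliberate: plane-based
and axis-based labels for the same rotation are easily conflated (a
"sagittal-plane" rotation happens about the mediolateral axis), and the
direction vocabulary surgeons use — cephalad, medial, internal rotation —
is side-aware. The mapping from a signed world-axis offset to its
anatomical label, given the injured side, ships as a data table
(`direction_conventions()`) so the conventions are auditable rather than
buried in code.

Each view reads off a fixed subset of components:

* inlet: translations along X and Z, axial rotation;
* outlet: translation along Y, coronal rotation;
* AP: sagittal rotation.

Every component is detectable in exactly one view, and the union covers
all six.

## Landmarks and the symmetry reference

Measurement relies on five bony landmarks: the anterior superior iliac
spine (ASIS), the ischial tuberosity, the superior point of the iliac
wing, the anterior sacroiliac joint on the iliac side, and the center of
the sacral endplate (midline). Each view uses its own catalog
(`required_landmarks()`).

The method's central assumption is **bilateral symmetry**: the intact (or
minimally injured) contralateral hemipelvis, reflected across the
midsagittal reference, predicts where every landmark of the injured side
ought to be. On the inlet and outlet films the mirror line is the
vertical through the projected sacral endplate landmark; the AP catalog
has no midline landmark, so the AP view falls back to the vertical
bisector of the two ischial tuberosities. (For angle measurements the
mirror line's horizontal position is immaterial — reflection across any
vertical line flips a segment's inclination identically — so the AP
fallback affects nothing that the AP view measures.)

## From landmarks to a pattern

Given an annotated view, the engine mirrors the intact side and compares:

* **Rotations** are signed angles between an injured-side landmark
  segment and its mirrored-intact counterpart. The segments are fixed per
  view to maximize lever arm within each view's own catalog: inlet
  ASIS → anterior SI joint; outlet iliac wing → ischial tuberosity; AP
  ASIS → ischial tuberosity. In-plane rotations (axial on the inlet,
  coronal on the outlet) come straight from the 2D angle.

* The **sagittal rotation is out of the AP plane**: it does not rotate
  the projected segment but foreshortens its vertical extent, because the
  ASIS lies ~65 mm anterior to the ischial tuberosity. The engine inverts
  the foreshortening equation `y' = dy cos(s) − dz sin(s)`, taking the
  in-plane expected segment from the mirrored intact side and the
  anteroposterior lever `dz` from the landmark template, scaled to the
  patient via the intact segment length. A single segment makes this
  inversion ill-conditioned where the apparent vertical extent is
  stationary in the angle (about −27° for this template's AP segment),
  so the full-case pipeline estimates the angle by least squares over
  four segments of the X/Y plane — the AP film's segment plus the three
  landmark pairs of the outlet film, whose opposite anteroposterior
  levers (iliac wing → ASIS runs +65 mm where ASIS → tuberosity runs
  −65 mm) keep the joint problem well conditioned across the working
  range. A standalone `measure_view()` call on an AP annotation uses the
  single-segment closed form and assumes the other rotations are zero.

* **Translations** are centroid offsets of the injured side's landmarks
  from their mirrored expectation, measured along the view's world axes,
  with one refinement: a rotation about the hemipelvic centroid also
  moves the centroid of the two or three landmarks a view happens to see,
  so the raw offset conflates rotation with translation (about
  21 × sin(axial) mm of apparent mediolateral shift at this template, for
  example). The engine therefore measures the three rotation angles
  first, predicts the rotation-induced centroid motion from the scaled
  template, and subtracts it. On noise-free synthetic cases this makes
  single-component recovery exact at any magnitude in the working range,
  rather than only below the point where rotational cross-talk crosses
  the detection threshold.

* **Classification** applies a threshold per movement type: a component
  is PRESENT when its measured magnitude reaches the threshold, with the
  tie classified PRESENT for a deterministic boundary, and its direction
  taken from the offset's sign via the convention table.

The measurement pipeline threads estimates between views (inlet and
outlet in-plane angles feed the sagittal solve and the rotation
compensation); `measure_view()` remains available for single-view use
with correspondingly weaker guarantees.

### Thresholds

The defaults are **5 mm** for translations and **5°** for rotations,
configurable via `thresholds()`. The trauma literature repeatedly links
residual post-reduction displacement greater than 10 mm to poor outcomes;
half of that bound is adopted as the detection floor, and the rotational
threshold mirrors the translational one numerically. The decision
constants of the antecedent manual method are not public, so these
defaults are the package's own, stated here once and used everywhere
(classifier, ground-truth labeling, and simulated studies alike).

## The synthetic generator

`make_case()` composes four stages, each of which is what it claims to be
and nothing more:

1. **Template** — a bilaterally symmetric set of 3D landmark coordinates
   (`default_template()`, fixture `pelvis_template_v1.csv`). The
   coordinates are anatomically plausible adult values (ASIS separation
   230 mm, tuberosities 140 mm caudal of the endplate, and so on) chosen
   once and versioned; bony landmarks carry no canonical coordinates, so
   pinning a concrete geometry is what makes every downstream number
   reproducible.
2. **Displacement** — a 6-DOF rigid transform of the injured side's
   landmarks: intrinsic rotations in the fixed order sagittal → axial →
   coronal about a rotation center, then a translation. The center
   defaults to the centroid of the injured hemipelvis's four landmarks
   (configurable); a centroid center keeps pure rotations from dragging
   the landmark cloud far from its expected position, which is also the
   assumption the engine's rotation compensation makes. The composition
   order matters only at second order for the small angles of interest
   and is documented rather than exposed.
3. **Projection** — orthographic projection to each view, retaining the
   view's catalog, with pixels = mm / calibration and the pixel origin at
   the projected sacral endplate, vertical axis cephalad-positive.
4. **Observer jitter** — independent isotropic Gaussian offsets per
   landmark per view (`sigma_mm`), converted to pixels via the
   calibration, seed-controlled. This is the simplest defensible model of
   a human clicking landmarks on a film.

Ground truth is obtained by thresholding the displacement parameters with
the classifier's own rule, so recovery is scored categorically and
exactly.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about clinical data: beam geometry and
magnification, patient malpositioning, anatomical asymmetry between
hemipelves, fracture comminution violating the rigid-body assumption,
landmark ambiguity on genuinely poor films (jitter is isotropic and
unbiased; real observers err anisotropically and systematically), and
bilateral injuries, which are out of scope for the method itself.

Simulation magnitude conventions: there is no published reference range
for clinically observed displacement magnitudes, so study cases draw single-component
magnitudes uniformly from 2–4× the detection threshold (10–20 mm or
10–20°), with 20% undisplaced cases, jitter 1 mm, and calibration
0.5 mm/px — fixed once as the package's study conditions.

## Reliability and validity statistics

`cohens_kappa()` implements chance-corrected agreement
κ = (p₀ − pₑ)/(1 − pₑ) with the large-sample standard error of Fleiss,
Cohen & Everitt (1969) and Wald 95% intervals κ ± 1.96·SE (intervals may
exceed 1, as is conventional for this SE; they are reported unclipped).
The degenerate case of two constant, identical raters (pₑ = 1) is defined
as κ = 1 with SE 0. `landis_koch_band()` maps κ to the six conventional
verbal bands with upper-inclusive boundaries (0.20 is "slight", anything
above 0.20 up to 0.40 "fair", and so on; negative values are "no
agreement").

For more than two observers the aggregate is the **mean of pairwise
Cohen's kappas** over all observer pairs, pooling each case's six
components into one categorical stream; per-pair results are retained,
per-movement-type streams (translational/rotational) are available via
the `components` argument, and Fleiss' multi-rater kappa (1971, with the
Fleiss–Nee–Landis SE) is offered as a clearly non-default alternative.
The choice of mean pairwise Cohen is a design decision: only Cohen's
statistic is named by the antecedent analysis, and averaging pairs is the
aggregation that reduces to it at two observers. Validity is each
observer's kappa against a gold-standard consensus, plus a pooled kappa
of all observers' ratings concatenated against the replicated gold.

`simulate_reliability_study()` re-enacts the four-observer design
in silico: each observer is an independent jittered run of the
measurement engine on the same cases. When a vector of jitter levels is
given, the same standard-normal perturbations are reused across levels
(scaled by sigma), so agreement is compared across noise magnitudes with
all else held fixed and degradation is monotone item by item rather than
only in expectation.

One recorded observation from this simulation: at 1 mm jitter the
**rotational** kappa tends to exceed the **translational** one — the
reverse of the ordering reported for human raters on clinical films.
This is a property of the observer model, not a bug: the rotation
measurements ride on long landmark segments (90–180 mm), so isotropic
millimeter-scale jitter perturbs angles by well under the 5° threshold,
while the mirrored-midline construction doubles midline jitter in the
mediolateral translation estimate (its noise floor is ≈ 2.2 mm at 1 mm
jitter, against a 5 mm threshold). Human raters plausibly find angles
harder than distances for reasons — landmark ambiguity, perspective,
protractor-free judgment — that isotropic jitter does not model. The
simulated study accordingly records both values without asserting the
clinical ordering.

## Numerical choices

* Tolerances: rigidity of the simulator's transform is verified to
  1e-9 mm against an independent homogeneous-matrix oracle; kappa is
  verified to 1e-12 against a brute-force contingency computation.
* The sagittal least-squares solve uses `optimize()` on ±60° with 1e-10
  tolerance; the closed-form single-segment solve clamps its cosine
  argument to [−1, 1] and takes the smaller-magnitude branch (patterns
  are small rigid displacements).
* Degenerate inputs fail loudly with classed errors: coincident segment
  landmarks, missing intact-side landmarks, absent midline reference,
  non-positive calibration, anisotropic DICOM pixel spacing.
* Exact threshold ties classify PRESENT; the boundary is deterministic.
* Midline under jitter: the sacral-landmark estimator is unbiased with
  the jitter's own standard deviation; the suite checks that calibrated
  property (error SD within [0.35, 0.65] mm at 0.5 mm jitter over 200
  draws) rather than a tail-probability assertion that would sit on a
  knife's edge by construction.
* Serialization uses full-precision JSON (`digits = NA`), making repeated
  writes of the same case byte-identical.

## Problem sizes in the shipped tests

The suite exercises: the 12-case direction-resolved recovery matrix and
its sub-threshold complement (noise-free, exact categorical match); 120+
random rigid transforms against the matrix oracle; 200 jittered
single-component cases at 1 mm for classification accuracy (≥ 95%
required); 1000 random tables for the kappa oracle; and a
100-case × 4-observer study across jitter {0, 0.5, 1, 2, 4} mm for the
perfect-agreement-at-zero and monotone-degradation properties. These
sizes are the package's chosen verification scale: large enough that the
stochastic properties are stable under their fixed seeds, small enough to
run routinely.

## Limitations

* The tool classifies patterns; it does not report validated displacement
  magnitudes. Offsets are computed internally and exposed only as an
  attribute for thresholding and diagnostics.
* Unilateral injuries only: the mirrored-intact construction has no
  reference when both hemipelves are displaced.
* Template dependence: out-of-plane levers and rotation compensation use
  the shipped template scaled to the patient; patients whose proportions
  deviate substantially from it will see degraded (though thresholded,
  hence tolerant) rotation estimates.
* The idealized orthographic view model ignores beam obliquity; films
  must be standardized or reconstructed accordingly.
* DICOM support is deliberately minimal: PixelSpacing extraction for
  calibration from little-endian files, nothing more.
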