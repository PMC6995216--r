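# pelvirad

Radiographic measurement and classification of hemipelvic displacement
patterns in unilateral pelvic ring fractures.

## The problem

Closed reduction of an unstable (type B/C) pelvic ring fracture requires
the surgeon to understand a three-dimensional, multidirectional deformity
from two-dimensional intraoperative films. CT answers the question but is
slow, dose-heavy, and unavailable at the table. `pelvirad` implements a
landmark-based measurement method that reads the deformity off the three
standardized pelvic radiographs — anteroposterior (AP), inlet, and
outlet — by exploiting bilateral symmetry: the intact hemipelvis, mirrored
across the midsagittal reference, provides the expected undisplaced
position of every landmark on the injured side.

The deformity of the injured hemipelvis is described in a pelvis-specific
frame (X mediolateral, Y craniocaudal, Z anteroposterior; origin at the
posterior edge of the S1 endplate) as six basic displacement patterns —
three translations and three rotations:

| component | view | direction labels |
|---|---|---|
| translation along X | inlet | medial / lateral |
| translation along Y | outlet | cephalad / caudad |
| translation along Z | inlet | anterior / posterior |
| sagittal rotation | AP | flexion / extension |
| axial rotation | inlet | internal / external |
| coronal rotation | outlet | abduction / adduction |

Each component is classified **present** (with its anatomical direction)
when the measured offset of the injured side relative to the mirrored
intact side reaches a detection threshold (default 5 mm / 5°), otherwise
**absent**. Magnitudes are used internally for thresholding only; the
clinical output is the categorical pattern.

Because no clinical imaging ships with the package, a synthetic projection
simulator (bilaterally symmetric 3D landmark template → 6-DOF rigid
displacement of one hemipelvis → orthographic projection to the three
views → per-landmark Gaussian observer jitter) provides ground truth for
every component, and a simulated multi-observer study re-enacts the
kappa-based reliability/validity analysis (Cohen's kappa, asymptotic 95%
CI, Landis–Koch bands, validity against a gold standard).

## Worked example

Simulate a five-component injury of the left hemipelvis (10 mm medial,
cephalad and anterior translation, 10° extension and internal rotation),
annotate it with 0.5 mm observer jitter, and classify:

```r
library(pelvirad)
case <- make_case(
  rigid_displacement(tx = -10, ty = 10, tz = 10, sagittal = -10,
                     axial = -10, injured_side = "LEFT"),
  sigma_mm = 0.5, seed = 42, mm_per_px = 0.5)
pattern <- measure_case(case)
pattern
#> <displacement_pattern> injured side LEFT
#>      component  status direction
#> 1      TRANS_X PRESENT    medial
#> 2      TRANS_Y PRESENT  cephalad
#> 3      TRANS_Z PRESENT  anterior
#> 4 ROT_SAGITTAL PRESENT extension
#> 5    ROT_AXIAL PRESENT  internal
#> 6  ROT_CORONAL  ABSENT      <NA>
#> extension (AP); cephalad (outlet); medial, anterior, internal rotation (inlet)
```

All five injected components are recovered with their anatomical
directions despite the jitter, the sixth stays absent, and the report
string phrases the findings per view the way the clinical read-out does.

Agreement statistics use the same vocabulary:

```r
cohens_kappa(c("absent","cephalad","absent","flexion","cephalad","absent"),
             c("absent","cephalad","absent","absent","cephalad","absent"))
#> kappa = 0.700 (SE 0.241, 95% CI 0.228-1.172), substantial agreement; n = 6
```

A full in-silico four-observer study:

```r
study <- simulate_reliability_study(n_cases = 25, n_observers = 4,
                                    jitter_sigma_mm = c(0, 1), seed = 1)
study   # overall / translational / rotational / validity kappas per jitter level
```

## Documentation

The methods vignette (`vignettes/pelvic-deformity-measurement.Rmd`)
describes the coordinate system, the measurement model and its
assumptions, the simulator, the statistical machinery, the numerical
choices, and the package's limitations.
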