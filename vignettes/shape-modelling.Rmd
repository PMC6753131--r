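---
title: "Clinical 3D morphable face models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinical 3D morphable face models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphface)
```

## The model

A 3D morphable model (3DMM) is a statistical model of surface shape built
from a cohort of triangulated scans that share one triangulation, so that
vertex *i* is anatomically homologous across the cohort. Writing each scan
as a vector $X = [x_1^\top, \dots, x_n^\top]^\top \in \mathbb{R}^{3n}$ of
stacked vertex coordinates (mm), the model is

$$X^{*} = M + \sum_{i=1}^{d} \alpha_i U_i = M + U\alpha,$$

with $M$ the mean shape, $U \in \mathbb{R}^{3n \times d}$ an orthonormal
basis of principal shape directions and $\alpha$ the *shape vector* of one
face. An arbitrary corresponded face projects into the model as

$$\alpha = U^\top (X - M), \qquad P(X) = M + U U^\top (X - M),$$

which is the least-squares optimum among all shapes the model can
synthesise; the package verifies idempotence and the Pythagorean
decomposition of $\|X - M\|^2$ as standing test properties.

Getting raw scans into this form takes two stages:

1. **Dense correspondence** (`nicp_register()`, `build_correspondence()`):
   a template mesh is deformed onto every scan by non-rigid iterative
   closest point registration with a locally-affine deformation model —
   each template vertex carries a $3 \times 4$ affine transform, and a
   sparse linear system balances closest-point attraction to the target
   surface, sparse landmark agreement, and a stiffness penalty on
   transform differences across template edges, with the stiffness lowered
   over a coarse-to-fine schedule. The deformed templates all share the
   template triangulation.
2. **Alignment** (`generalised_procrustes()`): generalised Procrustes
   analysis removes rotation, translation and scale, leaving shape only.

PCA of the aligned set (`fit_pca()`) is computed by singular value
decomposition of the centred $m \times 3n$ data matrix — never via the
$3n \times 3n$ covariance — so at most $m - 1$ components exist and the
models are cheap and numerically stable. Basis column signs are fixed by
making each column's largest-magnitude entry positive, which makes model
files bit-reproducible.

## Model validation

Three intrinsic metrics characterise a fitted model (`model_metrics()`):

* **Compactness** — cumulative fraction of total variance captured by the
  leading $k$ components; non-decreasing, and exactly 1 at full rank.
* **Generalisation** — leave-one-out reconstruction error (average
  Euclidean distance, AED, in mm) of faces unseen by the model, as a
  function of $k$. Within a fold the error is non-increasing in $k$
  because the projections are nested.
* **Specificity** — randomly synthesised faces are compared with their
  nearest real face (exact exhaustive search; cohort sizes make
  approximate neighbour search unnecessary), low values meaning synthetic
  faces stay realistic.

AED between corresponded meshes is the workhorse error measure:
$\mathrm{AED} = \tfrac1n \sum_i \|a_i - b_i\|_2$. Signed per-vertex maps
(`signed_error_map()`) take the AED magnitude with a sign from the
anterior (z) axis — positive where the reference is more protrusive. The
coordinate convention is right-handed with +z out of the face, units mm;
ties in z take the positive sign (their magnitude is zero anyway).

## Clinical applications

**Diagnosis** (`classify_diagnosis()`): a linear support vector machine
(cost $C = 1$) in shape-coefficient space separates preoperative patient
scans from volunteer scans. Performance is estimated by Monte-Carlo
cross-validation: repeated stratified splits (per class,
`round(fraction * class size)` scans train), confusion counts averaged
over iterations, plus per-scan misclassification tallies that flag
individual faces the model keeps getting wrong. Coefficients enter the
SVM raw (no whitening): the leading components carry the large-scale
shape differences that the diagnosis rests on, and rescaling trailing
noise components up would hurt; a `scale` switch restores standardised
features if wanted.

**Surgery simulation** (`fit_surgery_regressor()`, `simulate_postop()`,
`evaluate_regression()`): a linear *design matrix* maps the leading $k$
preoperative coefficients of a patient to the postoperative ones; the
predicted coefficients are synthesised back into a mesh. Four fits are
available — ordinary least squares (`lr`), ridge with penalty 0.5 (`rr`),
lasso with penalty 0.1 (`lasso`), and least-angle regression stopped at
one nonzero coefficient per output (`lars`). The LARS budget is read *per
output component*: each postoperative component is predicted from its
single best preoperative predictor, which in practice is the same
component — corrective jaw surgery rescales shape modes largely
independently. Ridge is solved in closed form with the intercept
unpenalised; the lasso goes through `glmnet` with an unstandardised
design so the penalty has the conventional $\tfrac1{2n}\|y - Xw\|^2 +
\lambda\|w\|_1$ meaning. Evaluation is leave-one-patient-out, and every
prediction is also compared against the cohort mean face and the mean
postoperative face: a useful simulator must beat both, otherwise it is
reproducing an average surgical result rather than a patient-specific
one.

## The synthetic cohort generator

No face database ships with the package; `sample_cohort()` generates
cohorts with complete ground truth instead, so every pipeline stage is
testable end to end.

* The **template** is a parametric grid surface: an ellipsoidal dome with
  nose, brow, lip and chin protrusions, with named anthropometric
  landmarks at analytically known vertices (the pronasale is the global
  z-maximum by construction).
* **Individual variation** is a rank-`r` basis of smooth random relief
  fields — low-order 2D cosine modes displacing vertices along template
  normals — with a decaying amplitude spectrum (`basis_sd`, default
  3 mm RMS for the leading mode, ratio 0.8). Surface relief is both where
  real faces vary most and the component a closest-point registration can
  actually observe; purely tangential variation is invisible to any
  surface-distance data term.
* **Patients** additionally carry a jaw dipole: broad Gaussian lobes over
  the maxilla (displaced inward, $-z$) and mandible (outward, $+z$),
  peak amplitude `effect_size` (default 8 mm). The lobes are wide —
  the jaws span most of the lower face — which matters when checking
  that group-mean difference maps localise to the jaw.
* The **surgical operator** maps preoperative generative coefficients to
  postoperative ones: a near-diagonal linear map (diagonal 0.95,
  off-diagonal jitter 0.005) plus removal of 90% of the jaw dipole and a
  1 mm persisting nose feature. Crucially, the realised outcome adds a
  per-patient random deviation of 1 mm RMS (`surgical_sd`) within the
  generative shape space: surgery is not deterministic, and without an
  irreducible outcome variability no regression method can overfit —
  the characteristic blow-up of ordinary least squares as $k$ approaches
  the number of pairs, and the advantage of the regularised fits, only
  appear once it is present.
* Every scan is finally corrupted by isotropic **sensor noise**
  (0.5 mm per coordinate) and a random **similarity transform**
  (rotation up to 10°, translation up to 20 mm, scale within 5%), with
  landmarks riding along. All randomness flows from one seed; equal
  configurations generate bit-identical cohorts.

What the generator does *not* emulate: texture, expression, scanner
artefacts other than isotropic noise, missing data beyond what the
hole-punching test fixtures construct, demographic structure (age/sex
covariates exist in the cohort table but do not drive shape), and real
anatomical detail. Passing tests therefore demonstrate the pipeline's
correctness and its statistical behaviour under controlled conditions,
not clinical performance on real faces.

## Numerical choices and design decisions

* **GPA scale and units.** Shapes are normalised to unit centroid size
  during alignment (explicitly recentred and renormalised every
  iteration, so floating-point drift cannot compound), and the cohort's
  mean centroid size is restored afterwards so model units remain mm
  (`scale_mode = "restore_mean"`); `"unit"` keeps pre-shapes. The initial
  reference is the mean of the centred shapes, making an already-aligned
  set a one-iteration fixed point. Convergence: mean-shape change below
  `tol` (default 1e-6) with at most 100 iterations.
* **GPA orientation gauge.** GPA only determines the aligned set up to a
  global rotation. The default gauge orients the consensus mean by its
  own principal axes, with axis signs from the third moment of the
  coordinates and handedness forced to a proper rotation — a gauge that
  depends only on the consensus shape, so the aligned output is invariant
  to how the inputs were posed. `gauge = "first"` rotates the mean onto
  the first input instead, which is simpler but inherits that input's
  pose.
* **NICP schedule.** Stiffness defaults `[50, 20, 5, 2, 0.8, 0.5, 0.35,
  0.2]` with landmark weights decaying 5 → 0, closest-point cutoff 10 mm
  and a normal-agreement cutoff of cos 60°; these are this package's
  choices for face-scale meshes. The inner loop is capped at 3 iterations
  per stiffness level: each closest-point reassignment can only pull
  vertices along the target surface, so long inner loops accumulate
  tangential drift of the correspondence while improving the surface fit
  negligibly (measured on 5 mm synthetic deformations, mean ground-truth
  recovery error roughly halves relative to an 8-iteration cap).
  Matches on border triangles of a cropped target can optionally be
  discarded (`exclude_boundary`); this is off by default because when
  the template spans the whole target, border matches legitimately pin
  the template edge.
* **Degenerate inputs.** Non-triangular faces are rejected at I/O rather
  than silently split; disconnected templates are rejected before
  registration (the stiffness system would be singular); collinear point
  sets are rejected by the Procrustes solver; an over-large component
  request is clipped to $m-1$ with a warning.
* **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state; PCA signs, file writers (full `%.17g` precision)
  and report serialisation are deterministic, so a pipeline run is
  byte-reproducible from its configuration — which the test suite
  asserts by checksumming two complete runs.

## Problem sizes

The test suite and the acceptance script run the study at desk scale:
template resolutions 10–20 (100–400 vertices), cohorts of 12–200
volunteers with up to 113 patient pairs for generator checks, 30 + 15
for the full registered pipeline, 100–200 Monte-Carlo iterations for
classification and 200–10,000 synthesised faces for specificity. These
sizes keep every statistical phenomenon of interest visible (subspace
recovery, overfitting ordering, localisation of the jaw effect) with
comfortable margins.

## Known limitations

* Closest-point NICP cannot observe tangential motion between landmarks;
  correspondence accuracy degrades gracefully but measurably as
  deformations grow (about a third of the deformation AED at face-scale
  amplitudes). Real pipelines lean on dense automatic landmarking, which
  is out of scope here — landmarks are accepted as inputs.
* The brute-force closest-point search is $O(n_\text{template} \cdot
  n_\text{faces})$ per iteration in compiled code; adequate for
  desk-scale meshes, but a spatial index would be needed for
  100k-vertex scans.
* The t-SNE stage is an exact (non-Barnes-Hut) implementation written for
  cohort-scale inputs (hundreds of faces); it is quadratic in the number
  of scans.
* Group labels enter nowhere in model construction; bespoke models are
  plain cohort filters, so a scan assigned to the wrong group biases the
  corresponding model silently. The cohort table is validated for
  structural consistency (unique ids, complete pairing) only.
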