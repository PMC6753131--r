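# morphface

Statistical shape modelling of the human face for clinical use, in R.

Orthognathic (corrective jaw) surgery changes the soft-tissue shape of the
face; planning it, and deciding who needs it, are largely shape problems.
`morphface` builds **3D morphable models** (3DMMs) from collections of
triangulated facial surface scans and runs two clinical applications on
top of them: automated **diagnosis** of patient versus non-patient face
shape with a linear support vector machine, and **surgery simulation** —
predicting a patient's postoperative face shape from the preoperative scan
alone via regularised regression in shape-coefficient space. It is aimed
at researchers in craniofacial surgery, medical image analysis and
geometric morphometrics who work with 3D surface scans.

## The model

Each scan is a vector $X = [x_1^\top, \dots, x_n^\top]^\top \in
\mathbb{R}^{3n}$ of vertex coordinates (mm) on a shared triangulation
(dense correspondence). After generalised Procrustes alignment, principal
component analysis yields the morphable model

$$X^{*} = M + U\alpha,$$

with mean shape $M$, orthonormal basis $U$ of shape eigenvectors and
shape vector $\alpha$. Any corresponded face projects into the model as

$$\alpha = U^\top(X - M), \qquad P(X) = M + UU^\top(X - M).$$

The pipeline stages are:

| Stage | Function(s) |
| --- | --- |
| Mesh and landmark I/O (OBJ, PLY, plain-text landmarks) | `read_mesh()`, `write_mesh()`, `read_landmarks()` |
| Dense correspondence (non-rigid ICP template registration) | `nicp_register()`, `build_correspondence()` |
| Alignment (generalised Procrustes analysis) | `generalised_procrustes()` |
| Model building, synthesis, projection | `fit_pca()`, `synthesise()`, `project()`, `sample_faces()` |
| Validation (compactness, generalisation, specificity), t-SNE | `model_metrics()`, `tsne_embed()` |
| Diagnosis (linear SVM, Monte-Carlo cross-validation) | `classify_diagnosis()` |
| Surgery simulation (LR / ridge / LARS / lasso design matrix) | `fit_surgery_regressor()`, `simulate_postop()`, `evaluate_regression()` |
| Synthetic ground-truth cohorts | `generator_config()`, `sample_cohort()` |
| Staged pipeline with file outputs | `run_config()`, `run_pipeline()`, `cmd_*()` |

Because clinical face databases cannot be redistributed, the package
ships a synthetic cohort generator that emulates one with full ground
truth — a face-like template, smooth low-rank individual variation, a
localised jaw deformation distinguishing patients, a linear surgical
operator with per-patient outcome variability, sensor noise and pose
jitter. All examples, tests and the acceptance script run on it.

## Worked example

Build a model from a synthetic cohort (40 volunteers, 20 patient pairs),
diagnose, and simulate surgery:

```r
library(morphface)

cohort  <- sample_cohort(generator_config(resolution = 14,
                                          n_volunteers = 40,
                                          n_patients = 20, seed = 1))
corr    <- build_correspondence(cohort$template$mesh, cohort$meshes,
                                cohort$landmarks,
                                cohort$template$landmarks)
aligned <- generalised_procrustes(corr$shapes)
X       <- do.call(rbind, lapply(aligned$shapes, function(s) s$x))
rownames(X) <- corr$ids

model <- fit_pca(X, template_faces = corr$template_faces)
model
#> morphable_model: 196 vertices, 79 components (of 79 available), 80 training shapes
compactness(model)[10]   # fraction of variance in 10 components: 0.932

alphas <- t(apply(X, 1, function(x) project(model, x)$alpha$alpha))
rownames(alphas) <- rownames(X)
classify_diagnosis(cohort$cohort, alphas, split_spec(0.8, 200, seed = 1))
#> classifier_report: 200 iterations, 79 components
#>   accuracy 99.8%, sensitivity 99.8%, specificity 99.9%, PPV 99.8%, NPV 99.9%

shapes <- corresponded_set(corr$template_faces,
                           lapply(seq_len(nrow(X)), function(i)
                             flatten(shape_coords(X[i, ]))),
                           ids = rownames(X))
evaluate_regression(model, cohort$cohort, shapes, k_grid = c(5, 10, 18))
#> regression_report (leave-one-out, 20 pairs)
#>   lr    at k18: 13.595 +/- 17.586 mm
#>   rr    at k18: 3.914 +/- 2.624 mm
#>   lasso at k18: 2.777 +/- 1.544 mm
#>   lars  at k18: 1.619 +/- 0.442 mm
```

Reading the numbers: the jaw deformation separates synthetic patients
from volunteers almost perfectly (accuracy 99.8% over 200 stratified
Monte-Carlo splits), and at 18 components — close to the number of
training pairs — ordinary least squares overfits badly (13.6 mm mean
error against the true postoperative shape) while the regularised
regressors stay at a few mm, the least-angle fit closest to the
irreducible outcome-variability floor. `simulation_extremes()` names the
best (1.06 mm) and worst (10.05 mm) simulated patients for figure-style
inspection, and `signed_error_map()` exports per-vertex colourmap data to
PLY.

The same run as a shell pipeline:

```sh
Rscript inst/cli/morphface all --seed 1 --out myrun
```

writes meshes, models, metric tables, t-SNE embeddings, diagnosis and
simulation reports (CSV/JSON/PLY) plus the resolved configuration under
`myrun/`.

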