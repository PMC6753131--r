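#' Configuration for the synthetic face-cohort generator
#'
#' Defines a low-rank generative population of face-like surfaces with a
#' localised jaw deformation distinguishing patients, a linear "surgical"
#' operator producing paired postoperative shapes, and the corruptions a
#' real scanning pipeline adds (sensor noise, arbitrary pose/scale).
#' Because every scan is a deformation of one template, ground truth is
#' known at every vertex, which makes each pipeline stage testable without
#' any face database.
#'
#' @param resolution vertices per side of the parametric grid (template has
#'   `resolution^2` vertices); at least 8.
#' @param n_volunteers,n_patients cohort sizes; each patient contributes a
#'   preoperative and a paired postoperative scan.
#' @param rank number of generative basis components.
#' @param basis_sd per-component amplitude spectrum: root-mean-square
#'   per-vertex displacement (mm) of each component, positive descending.
#' @param effect_size peak jaw displacement (mm) of the patient dipole:
#'   maxillary retrusion (upper jaw, negative/anterior in) and mandibular
#'   protrusion (lower jaw, positive/anterior out). Zero gives a null
#'   cohort in which patients and volunteers are exchangeable.
#' @param jaw_residual fraction of the jaw displacement remaining after
#'   surgery.
#' @param nose_residual amplitude (mm) of the nose feature that persists
#'   postoperatively.
#' @param surgical_shrink diagonal of the linear surgical operator applied
#'   to generative coefficients (close to 1).
#' @param surgical_mixing standard deviation of the operator's
#'   off-diagonal entries. Kept small by default: corrective jaw surgery
#'   rescales each shape mode essentially independently, so the
#'   preop-to-postop map is near-diagonal in component space with only
#'   slight mode coupling.
#' @param surgical_sd per-patient variability of the surgical outcome:
#'   root-mean-square per-vertex displacement (mm) of a random deviation,
#'   within the generative shape space, between the operator-predicted and
#'   the realised postoperative shape. Surgery is not deterministic:
#'   osteotomy placement and soft-tissue response vary at the millimetre
#'   scale, and this term sets the irreducible error floor of any
#'   preop-to-postop regression.
#' @param noise_sd isotropic sensor noise per vertex coordinate (mm).
#' @param rot_max_deg,trans_max,scale_jitter pose corruption ranges: random
#'   rotation up to this angle (degrees), translation per axis (mm), and
#'   scale in `1 +/- scale_jitter`.
#' @param seed master seed; all randomness in the generator flows from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(resolution = 16, n_volunteers = 500,
                             n_patients = 113, rank = 10,
                             basis_sd = 3 * 0.8^(seq_len(rank) - 1),
                             effect_size = 8, jaw_residual = 0.1,
                             nose_residual = 1, surgical_shrink = 0.95,
                             surgical_mixing = 0.005, surgical_sd = 1,
                             noise_sd = 0.5, rot_max_deg = 10,
                             trans_max = 20, scale_jitter = 0.05,
                             seed = 1L) {
  if (resolution < 8) stop("resolution must be at least 8")
  if (length(basis_sd) != rank) stop("basis_sd must have one value per rank")
  if (any(basis_sd <= 0) || any(diff(basis_sd) > 0))
    stop("basis_sd must be positive and non-increasing")
  if (effect_size < 0) stop("effect_size must be non-negative")
  structure(list(resolution = as.integer(resolution),
                 n_volunteers = as.integer(n_volunteers),
                 n_patients = as.integer(n_patients),
                 rank = as.integer(rank), basis_sd = basis_sd,
                 effect_size = effect_size, jaw_residual = jaw_residual,
                 nose_residual = nose_residual,
                 surgical_shrink = surgical_shrink,
                 surgical_mixing = surgical_mixing,
                 surgical_sd = surgical_sd, noise_sd = noise_sd,
                 rot_max_deg = rot_max_deg, trans_max = trans_max,
                 scale_jitter = scale_jitter, seed = as.integer(seed)),
            class = "generator_config")
}

# parametric face height field on the (u, v) in [-1, 1]^2 grid:
# an ellipsoidal dome with nose, brow, lip and chin features (mm)
face_height <- function(u, v) {
  35 * sqrt(pmax(0, 1 - 0.75 * u^2 - 0.55 * v^2)) +
    14 * exp(-((u / 0.18)^2 + ((v + 0.05) / 0.22)^2)) +   # nose
    3 * exp(-((u / 0.55)^2 + ((v - 0.45) / 0.16)^2)) +    # brow ridge
    4 * exp(-((u / 0.30)^2 + ((v + 0.52) / 0.12)^2)) +    # lips
    5 * exp(-((u / 0.25)^2 + ((v + 0.82) / 0.15)^2))      # chin
}

#' Build the synthetic face template
#'
#' A smooth parametric face-like surface on a regular grid: an ellipsoidal
#' patch with nose, brow, lip and chin protrusions, consistent
#' counter-clockwise triangulation (normals facing +z, the anterior axis),
#' and named anthropometric landmarks at analytically known grid vertices.
#' The pronasale landmark is the global z-maximum by construction.
#'
#' @param config `generator_config` (only `resolution` is used here).
#' @return List: `mesh` (`trimesh`), `landmarks` (`landmark_set`, with the
#'   landmark vertex indices in attribute `"vertex_index"`), `uv` (the
#'   grid coordinates of each vertex).
#' @export
make_template <- function(config = generator_config()) {
  ns <- config$resolution
  g <- seq(-1, 1, length.out = ns)
  uv <- cbind(u = rep(g, times = ns), v = rep(g, each = ns))
  vertices <- cbind(x = 55 * uv[, "u"], y = 75 * uv[, "v"],
                    z = face_height(uv[, "u"], uv[, "v"]))
  vid <- function(i, j) (i - 1L) * ns + j  # row i = v index, col j = u index
  faces <- matrix(0L, 2L * (ns - 1L)^2, 3L)
  r <- 1L
  for (i in seq_len(ns - 1L)) for (j in seq_len(ns - 1L)) {
    a <- vid(i, j); b <- vid(i, j + 1L)
    c <- vid(i + 1L, j); d <- vid(i + 1L, j + 1L)
    faces[r, ] <- c(a, b, d); faces[r + 1L, ] <- c(a, d, c)
    r <- r + 2L
  }
  mesh <- trimesh(vertices, faces, id = "template")
  near <- function(u0, v0)
    which.min((uv[, "u"] - u0)^2 + (uv[, "v"] - v0)^2)
  lm_idx <- c(pronasale = which.max(vertices[, "z"]),
              nasion = near(0, 0.25),
              pogonion = near(0, -0.82),
              exocanthion_right = near(-0.45, 0.30),
              exocanthion_left = near(0.45, 0.30),
              cheilion_right = near(-0.30, -0.52),
              cheilion_left = near(0.30, -0.52))
  lms <- landmark_set("template", vertices[lm_idx, , drop = FALSE],
                      names(lm_idx))
  attr(lms, "vertex_index") <- unname(lm_idx)
  list(mesh = mesh, landmarks = lms, uv = uv)
}

# localised displacement fields (3n vectors, x1 y1 z1 x2 ... ordering)
# along vertex normals; peak magnitude 1
field_along_normals <- function(mesh, weight) {
  n <- vertex_normals(mesh)
  as.vector(t(n * weight))
}

# broad maxilla/mandible regions: the jaws span most of the lower face
# width, so the dipole lobes are wide in u and meet near the mouth line
jaw_dipole_weights <- function(uv) {
  upper <- exp(-((uv[, "v"] + 0.40) / 0.22)^2 - (uv[, "u"] / 0.65)^2)
  lower <- exp(-((uv[, "v"] + 0.80) / 0.24)^2 - (uv[, "u"] / 0.70)^2)
  w <- lower - upper   # mandibular protrusion +, maxillary retrusion -
  w / max(abs(w))
}

nose_weights <- function(uv) {
  w <- exp(-((uv[, "u"] / 0.20)^2 + ((uv[, "v"] + 0.05) / 0.22)^2))
  w / max(w)
}

# smooth random relief fields: scalar maps spanned by low-order 2D cosine
# modes, displacing along template vertex normals (face shape varies mostly
# in surface relief), orthonormalised as 3n-vectors
smooth_basis <- function(uv, rank, normals) {
  modes <- expand.grid(p = 0:3, q = 0:3)
  Phi <- vapply(seq_len(nrow(modes)), function(m)
    cos(modes$p[m] * pi * (uv[, "u"] + 1) / 2) *
      cos(modes$q[m] * pi * (uv[, "v"] + 1) / 2),
    numeric(nrow(uv)))
  raw <- vapply(seq_len(rank), function(r) {
    s <- as.vector(Phi %*% stats::rnorm(ncol(Phi)))
    as.vector(t(normals * s))  # interleave to x1 y1 z1 ...
  }, numeric(3L * nrow(uv)))
  qr.Q(qr(raw))[, seq_len(rank), drop = FALSE]
}

random_rotation <- function(max_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Volunteers are template + low-rank smooth deformation + sensor noise;
#' preoperative patients additionally carry the jaw dipole (upper jaw in,
#' lower jaw out) at `effect_size`; each patient's paired postoperative
#' scan applies the linear surgical operator to the generative
#' coefficients, removes most of the jaw displacement and leaves a small
#' nose residual. Every mesh (and its landmarks) is finally corrupted by a
#' random similarity transform within the jitter ranges. All ground truth
#' is retained.
#'
#' @param config `generator_config`.
#' @return Object of class `synthetic_cohort`: `meshes` and `landmarks`
#'   (named lists, one per scan), `cohort` (`cohort_table`), `template`
#'   (as [make_template()]), and `ground_truth` (per-scan generative
#'   coefficients `betas`, clean template-space vertices `true_vertices`,
#'   per-scan jitter `transforms`, the surgical operator, the basis and
#'   displacement fields).
#' @export
sample_cohort <- function(config = generator_config()) {
  tpl <- make_template(config)
  n <- nrow(tpl$mesh$vertices)
  lm_idx <- attr(tpl$landmarks, "vertex_index")
  with_seed(config$seed, {
    B <- smooth_basis(tpl$uv, config$rank, vertex_normals(tpl$mesh))
    coef_sd <- config$basis_sd * sqrt(n)   # basis columns are unit-norm
    jaw <- field_along_normals(tpl$mesh, jaw_dipole_weights(tpl$uv))
    nose <- field_along_normals(tpl$mesh, nose_weights(tpl$uv))
    S <- config$surgical_shrink * diag(config$rank) +
      matrix(stats::rnorm(config$rank^2, sd = config$surgical_mixing),
             config$rank)

    ids <- c(sprintf("vol_%04d", seq_len(config$n_volunteers)),
             sprintf("pat_%04d_pre", seq_len(config$n_patients)),
             sprintf("pat_%04d_post", seq_len(config$n_patients)))
    role <- c(rep("volunteer", config$n_volunteers),
              rep("preop", config$n_patients),
              rep("postop", config$n_patients))
    pair <- c(rep(NA_character_, config$n_volunteers),
              sprintf("pat_%04d", seq_len(config$n_patients)),
              sprintf("pat_%04d", seq_len(config$n_patients)))
    n_scan <- length(ids)
    betas <- matrix(0, n_scan, config$rank, dimnames = list(ids, NULL))
    base <- as.vector(t(tpl$mesh$vertices))
    true_vertices <- vector("list", n_scan); names(true_vertices) <- ids
    meshes <- vector("list", n_scan); names(meshes) <- ids
    landmarks <- vector("list", n_scan); names(landmarks) <- ids
    transforms <- vector("list", n_scan); names(transforms) <- ids

    # one generative coefficient vector per subject
    beta_vol <- matrix(stats::rnorm(config$n_volunteers * config$rank),
                       nrow = config$n_volunteers, ncol = config$rank) %*%
      diag(coef_sd, config$rank)
    beta_pat <- matrix(stats::rnorm(config$n_patients * config$rank),
                       nrow = config$n_patients, ncol = config$rank) %*%
      diag(coef_sd, config$rank)
    for (s in seq_len(n_scan)) {
      if (role[s] == "volunteer") {
        beta <- beta_vol[s, ]
        x <- base + as.vector(B %*% beta)
      } else {
        p <- as.integer(sub("pat_(\\d+)_.*", "\\1", ids[s]))
        if (role[s] == "preop") {
          beta <- beta_pat[p, ]
          x <- base + as.vector(B %*% beta) + config$effect_size * jaw
        } else {
          # realised outcome = operator prediction + surgical variability
          eta <- stats::rnorm(config$rank,
                              sd = config$surgical_sd *
                                sqrt(n / config$rank))
          beta <- as.vector(S %*% beta_pat[p, ]) + eta
          x <- base + as.vector(B %*% beta) +
            config$jaw_residual * config$effect_size * jaw +
            config$nose_residual * nose
        }
      }
      betas[s, ] <- beta
      true_vertices[[s]] <- matrix(x, ncol = 3, byrow = TRUE)
      noisy <- true_vertices[[s]] +
        matrix(stats::rnorm(3L * n, sd = config$noise_sd), n, 3)
      tf <- similarity_transform(
        random_rotation(config$rot_max_deg),
        stats::runif(1, 1 - config$scale_jitter, 1 + config$scale_jitter),
        stats::runif(3, -config$trans_max, config$trans_max))
      transforms[[s]] <- tf
      obs <- apply_transform(tf, noisy)
      meshes[[s]] <- trimesh(obs, tpl$mesh$faces, id = ids[s])
      landmarks[[s]] <- landmark_set(ids[s],
                                     obs[lm_idx, , drop = FALSE],
                                     tpl$landmarks$names)
    }
    cohort <- cohort_table(scan_id = ids,
                           subject_id = ifelse(is.na(pair), ids, pair),
                           group = role, pair_id = pair)
    structure(list(meshes = meshes, landmarks = landmarks, cohort = cohort,
                   template = tpl,
                   ground_truth = list(betas = betas, basis = B,
                                       coef_sd = coef_sd,
                                       surgical_operator = S,
                                       jaw_field = jaw, nose_field = nose,
                                       jaw_weights =
                                         jaw_dipole_weights(tpl$uv),
                                       true_vertices = true_vertices,
                                       transforms = transforms),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d volunteers, %d patient pairs, %d vertices/mesh\n",
    x$config$n_volunteers, x$config$n_patients,
    nrow(x$template$mesh$vertices)))
  invisible(x)
}

#' Vertex mask of the synthetic jaw region
#'
#' Vertices where the jaw dipole carries non-negligible weight, optionally
#' expanded by their one-ring neighbours.
#'
#' @param cohort `synthetic_cohort`.
#' @param threshold minimum absolute dipole weight.
#' @param expand include one-ring neighbours of masked vertices.
#' @return Logical vertex mask.
#' @export
jaw_mask <- function(cohort, threshold = 0.05, expand = TRUE) {
  w <- cohort$ground_truth$jaw_weights
  mask <- abs(w) > threshold
  if (expand) {
    edges <- mesh_edges(cohort$template$mesh$faces)
    hit <- mask[edges[, 1]] | mask[edges[, 2]]
    mask[edges[hit, 1]] <- TRUE
    mask[edges[hit, 2]] <- TRUE
  }
  mask
}
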