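#' Build a 3D morphable model by PCA of a corresponded, aligned set
#'
#' The model of face shape: a mean shape \eqn{M \in R^{3n}}, an orthonormal
#' basis \eqn{U \in R^{3n \times d}} of principal shape directions, and the
#' sample variance along each direction. Any face in the model's span is
#' \eqn{X = M + U\alpha}. The decomposition is computed by singular value
#' decomposition of the centred data matrix (never the 3n x 3n covariance),
#' so at most \eqn{m - 1} components exist for \eqn{m} training shapes.
#' Basis column signs are fixed by forcing each column's largest-magnitude
#' entry positive, making models bit-reproducible.
#'
#' @param data a `corresponded_set` or `aligned_set` (or a plain m x 3n
#'   matrix of flattened shapes, one row per shape).
#' @param n_components number of components to retain; `NULL` keeps all
#'   `m - 1`. Requests beyond `m - 1` are clipped with a warning.
#' @param template_faces triangulation for synthesised meshes (taken from
#'   `data` when it carries one).
#' @return Object of class `morphable_model`: `mean` (`flat_shape`),
#'   `basis` (3n x d), `variances` (length d, descending),
#'   `variances_full` (all m - 1, for compactness), `template_faces`,
#'   `n_training`.
#' @export
fit_pca <- function(data, n_components = NULL, template_faces = NULL) {
  if (inherits(data, c("corresponded_set", "aligned_set"))) {
    if (is.null(template_faces) && !is.null(data$template_faces))
      template_faces <- data$template_faces
    X <- do.call(rbind, lapply(data$shapes, function(s) as_flat(s)$x))
  } else {
    X <- as.matrix(data)
  }
  m <- nrow(X)
  if (m < 2L) stop("need at least 2 shapes to fit a model")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  d_max <- min(m - 1L, ncol(X))
  # numerically null directions beyond m-1 are dropped
  basis <- sv$v[, seq_len(d_max), drop = FALSE]
  variances <- sv$d[seq_len(d_max)]^2 / (m - 1)
  if (!is.null(n_components)) {
    if (n_components > d_max) {
      warning("n_components = ", n_components, " clipped to m - 1 = ", d_max)
      n_components <- d_max
    }
    if (n_components < 1L) stop("n_components must be >= 1")
  } else n_components <- d_max
  # deterministic sign: largest-|entry| of each column positive
  for (j in seq_len(ncol(basis))) {
    k <- which.max(abs(basis[, j]))
    if (basis[k, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(mean = structure(list(x = mu, n_vertices = length(mu) %/% 3L),
                                  class = "flat_shape"),
                 basis = basis[, seq_len(n_components), drop = FALSE],
                 variances = variances[seq_len(n_components)],
                 variances_full = variances,
                 template_faces = template_faces,
                 n_training = m),
            class = "morphable_model")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat(sprintf(
    "morphable_model: %d vertices, %d components (of %d available), %d training shapes\n",
    x$mean$n_vertices, ncol(x$basis), length(x$variances_full), x$n_training))
  invisible(x)
}

model_dim <- function(model) ncol(model$basis)

#' Shape vector: coefficients of one face in a model's subspace
#'
#' @param alpha numeric coefficient vector.
#' @param model_id identifier of the generating model (optional bookkeeping).
#' @return Object of class `shape_vector`.
#' @export
shape_vector <- function(alpha, model_id = NA_character_) {
  alpha <- as.numeric(alpha)
  if (!all(is.finite(alpha))) stop("shape vector must be finite")
  structure(list(alpha = alpha, model_id = model_id), class = "shape_vector")
}

coef_vec <- function(x) if (inherits(x, "shape_vector")) x$alpha else
  as.numeric(x)

#' Synthesise a face from shape coefficients
#'
#' Evaluates \eqn{X^{*} = M + \sum_i \alpha_i U_i = M + U\alpha}. A shorter
#' coefficient vector is zero-padded, so `synthesise(model, numeric(0))`
#' returns the mean face.
#'
#' @param model `morphable_model`.
#' @param alpha `shape_vector` or numeric vector, length at most the
#'   model's component count.
#' @param id id for the synthesised mesh.
#' @return `trimesh` (or `flat_shape` when the model has no triangulation).
#' @export
synthesise <- function(model, alpha, id = "synthesised") {
  a <- coef_vec(alpha)
  d <- model_dim(model)
  if (length(a) > d)
    stop("coefficient vector longer (", length(a),
         ") than model dimensionality (", d, ")")
  a <- c(a, rep(0, d - length(a)))
  x <- model$mean$x + as.vector(model$basis %*% a)
  if (is.null(model$template_faces)) return(flatten(shape_coords(x)))
  unflatten(x, model$template_faces, id = id)
}

#' Project a face onto the model subspace
#'
#' The least-squares fit of the model to an arbitrary corresponded face:
#' \eqn{\alpha = U^T (X - M)} and \eqn{P(X) = M + U U^T (X - M)}. The
#' projection is idempotent and optimal among all shapes the model can
#' synthesise.
#'
#' @param model `morphable_model`.
#' @param x corresponded shape (`flat_shape`, `trimesh`, or coordinate
#'   matrix) with the model's vertex count.
#' @param n_components project with only the leading components
#'   (default: all).
#' @return List: `alpha` (`shape_vector`), `projection` (`flat_shape`).
#' @export
project <- function(model, x, n_components = NULL) {
  xf <- as_flat(x)
  if (xf$n_vertices != model$mean$n_vertices)
    stop("vertex count ", xf$n_vertices, " does not match model (",
         model$mean$n_vertices, ")")
  d <- model_dim(model)
  k <- if (is.null(n_components)) d else min(n_components, d)
  U <- model$basis[, seq_len(k), drop = FALSE]
  dev <- xf$x - model$mean$x
  a <- as.vector(crossprod(U, dev))
  p <- model$mean$x + as.vector(U %*% a)
  list(alpha = shape_vector(a), projection = flatten(shape_coords(p)))
}

#' Randomly synthesise faces from a model
#'
#' Draws coefficients independently per component as zero-mean Gaussians
#' with the model's per-component variances (optionally truncated at
#' `sd_trunc` standard deviations) and synthesises one mesh per draw.
#' Reproducible under a fixed seed.
#'
#' @param model `morphable_model`.
#' @param m number of faces.
#' @param seed integer RNG seed.
#' @param sd_trunc truncate draws at this many standard deviations
#'   (`Inf` = no truncation).
#' @return List of `m` meshes (class as returned by [synthesise()]).
#' @export
sample_faces <- function(model, m, seed = 1L, sd_trunc = Inf) {
  if (m < 1L) stop("m must be >= 1")
  sds <- sqrt(model$variances)
  d <- model_dim(model)
  A <- with_seed(seed, {
    A <- matrix(stats::rnorm(m * d), m, d)
    if (is.finite(sd_trunc)) A <- pmin(pmax(A, -sd_trunc), sd_trunc)
    A
  })
  A <- sweep(A, 2, sds, "*")
  lapply(seq_len(m), function(i)
    synthesise(model, A[i, ], id = sprintf("synth_%05d", i)))
}

# run code under a local, seeded RNG without disturbing the global stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
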