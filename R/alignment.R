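#' Similarity transform
#'
#' A rigid rotation plus isotropic scale and translation,
#' \eqn{x \mapsto s R x + t}. The unit removed by Procrustes alignment.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param scale positive scalar.
#' @param translation length-3 vector (mm).
#' @return Object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det = +1)")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar")
  if (length(translation) != 3L) stop("translation must be length 3")
  structure(list(rotation = rotation, scale = as.numeric(scale),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param transform `similarity_transform`.
#' @param x points: k x 3 matrix, `trimesh`, or `flat_shape`.
#' @return Same container type as `x`, transformed.
#' @export
apply_transform <- function(transform, x) {
  tf <- function(v)
    sweep(v %*% t(transform$rotation) * transform$scale, 2,
          transform$translation, "+")
  if (inherits(x, "trimesh")) {
    x$vertices <- tf(x$vertices); return(x)
  }
  if (inherits(x, "flat_shape")) return(flatten(tf(shape_coords(x))))
  tf(as.matrix(x))
}

#' Compose s2 R2 (s1 R1 x + t1) + t2 into one similarity transform
#' @noRd
compose_transform <- function(second, first) {
  similarity_transform(second$rotation %*% first$rotation,
                       second$scale * first$scale,
                       second$scale * as.vector(second$rotation %*%
                                                  first$translation) +
                         second$translation)
}

centroid_size <- function(v) {
  v <- shape_coords(v)
  sqrt(sum(sweep(v, 2, colMeans(v))^2))
}

#' Orthogonal Procrustes fit of one point set onto another
#'
#' Closed-form similarity transform minimising
#' \eqn{\sum_i \| s R \, source_i + t - target_i \|^2} via SVD of the
#' cross-covariance, determinant-corrected so the rotation is proper (no
#' reflection).
#'
#' @param source,target k x 3 point sets in correspondence (k >= 3, not all
#'   collinear).
#' @param with_scale estimate isotropic scale (`TRUE`) or fix it at 1.
#' @return `similarity_transform` mapping source onto target.
#' @export
procrustes_pair <- function(source, target, with_scale = TRUE) {
  X <- shape_coords(source); Y <- shape_coords(target)
  if (nrow(X) != nrow(Y))
    stop("point sets differ in size: ", nrow(X), " vs ", nrow(Y))
  if (nrow(X) < 3L) stop("need at least 3 points")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  # rank check on the centred source: collinear/degenerate configurations
  if (svd(Xc)$d[2] < 1e-10 * max(svd(Xc)$d[1], 1))
    stop("degenerate (rank < 2) point configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (with_scale) sum(sv$d * c(1, 1, d)) / sum(Xc^2) else 1
  t <- my - s * as.vector(R %*% mx)
  similarity_transform(R, s, t)
}

#' Canonical orientation of a centred shape by its principal axes
#'
#' Rotates a centred shape so its vertex principal axes coincide with the
#' coordinate axes, with axis signs fixed by the third moment of the
#' coordinates (falling back to the largest-magnitude coordinate when the
#' moment vanishes) and handedness corrected to a proper rotation. The
#' result depends only on the shape itself, so it serves as an
#' orientation gauge that is invariant to how the input was posed.
#' @noRd
canonical_orientation <- function(v) {
  v <- shape_coords(v)
  e <- eigen(crossprod(v), symmetric = TRUE)
  R <- e$vectors  # columns: principal axes, descending variance
  w <- v %*% R
  for (j in 1:3) {
    s <- sum(w[, j]^3)
    if (abs(s) < 1e-9) s <- w[which.max(abs(w[, j])), j]
    if (s < 0) { R[, j] <- -R[, j]; w[, j] <- -w[, j] }
  }
  if (det(R) < 0) { R[, 3] <- -R[, 3] }  # enforce right-handedness
  t(R)  # rotation to apply: v %*% t(rot) with rot = t(R)
}

#' Generalised Procrustes analysis of a shape collection
#'
#' Removes similarity effects (rotation, translation, scale) from a set of
#' corresponded shapes, leaving only shape. Iterative scheme: centre all
#' shapes (and normalise to unit centroid size when `with_scale`), take
#' their mean as the initial reference, then repeatedly align every shape
#' to the current mean and recompute the mean until the mean moves by less
#' than `tol` (AED between successive means) or `max_iter` is reached.
#'
#' Two post-processing choices close the similarity gauge that GPA leaves
#' open: the consensus orientation is fixed either by the mean's own
#' principal axes (`gauge = "pca"`, default; invariant to how the inputs
#' were posed) or by rotating the mean onto the first input shape
#' (`gauge = "first"`), and the size removed during alignment is either
#' restored as the mean centroid size of the inputs so model units remain
#' mm (`scale_mode = "restore_mean"`, default) or left at unit centroid
#' size (`scale_mode = "unit"`).
#'
#' @param shapes list of corresponded shapes (`flat_shape`, `trimesh`, or
#'   n x 3 matrices), all with the same vertex count.
#' @param max_iter maximum alignment iterations (default 100).
#' @param tol convergence tolerance on mean-shape change, mm (default 1e-6).
#' @param with_scale remove scale as well as rotation/translation.
#' @param scale_mode `"restore_mean"` or `"unit"` (see Details).
#' @param gauge `"pca"` or `"first"` orientation gauge.
#' @return Object of class `aligned_set`: `shapes` (list of `flat_shape`),
#'   `transforms` (per-input `similarity_transform`, input -> aligned),
#'   `mean_shape` (`flat_shape`), `iterations_run`, `converged`.
#' @export
generalised_procrustes <- function(shapes, max_iter = 100, tol = 1e-6,
                                   with_scale = TRUE,
                                   scale_mode = c("restore_mean", "unit"),
                                   gauge = c("pca", "first")) {
  scale_mode <- match.arg(scale_mode)
  gauge <- match.arg(gauge)
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  raw <- lapply(shapes, shape_coords)
  n <- nrow(raw[[1]])
  if (!all(vapply(raw, nrow, 0L) == n))
    stop("vertex-count mismatch across shapes")
  sizes <- vapply(raw, centroid_size, 0)
  cur <- lapply(raw, function(v) {
    v <- sweep(v, 2, colMeans(v))
    if (with_scale) v / centroid_size(v) else v
  })
  mean_of <- function(lst) Reduce(`+`, lst) / length(lst)
  # initial reference: the raw mean of the centred shapes, so a set that is
  # already aligned is recognised as a fixed point on the first iteration
  ref <- mean_of(cur)
  if (with_scale) ref <- ref / centroid_size(ref)
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    cur <- lapply(cur, function(v) {
      tf <- procrustes_pair(v, ref, with_scale = with_scale)
      v <- apply_transform(tf, v)
      # stay centred on the unit pre-shape sphere: scaling to the mean is
      # allowed during alignment, but centroids and sizes are re-imposed
      # explicitly so floating-point drift cannot compound over iterations
      if (with_scale) {
        v <- sweep(v, 2, colMeans(v))
        v / centroid_size(v)
      } else v
    })
    newref <- mean_of(cur)
    newref <- sweep(newref, 2, colMeans(newref))
    if (with_scale) newref <- newref / centroid_size(newref)
    delta <- aed(newref, ref)
    ref <- newref
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalised Procrustes did not converge in ", max_iter,
            " iterations")
  # close the rotation gauge
  if (gauge == "pca") {
    R <- canonical_orientation(ref)
    g <- similarity_transform(R, 1, c(0, 0, 0))
  } else {
    first <- sweep(raw[[1]], 2, colMeans(raw[[1]]))
    tf <- procrustes_pair(ref, first, with_scale = FALSE)
    g <- similarity_transform(tf$rotation, 1, c(0, 0, 0))
  }
  cur <- lapply(cur, function(v) apply_transform(g, v))
  ref <- apply_transform(g, ref)
  if (with_scale && scale_mode == "restore_mean") {
    s <- mean(sizes)
    cur <- lapply(cur, function(v) v * s)
    ref <- ref * s
  }
  transforms <- mapply(function(orig, fin)
    procrustes_pair(orig, fin, with_scale = with_scale),
    raw, cur, SIMPLIFY = FALSE)
  structure(list(shapes = lapply(cur, flatten),
                 transforms = transforms,
                 mean_shape = flatten(ref),
                 iterations_run = iterations,
                 converged = converged),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf(
    "aligned_set: %d shapes x %d vertices, %d iterations (%s)\n",
    length(x$shapes), x$shapes[[1]]$n_vertices, x$iterations_run,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
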