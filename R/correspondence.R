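#' Configuration for non-rigid ICP template registration
#'
#' Controls the coarse-to-fine deformation schedule. Registration runs one
#' outer step per stiffness value, from stiff (near-global motion) to
#' compliant (local detail), with the landmark term decaying in parallel so
#' sparse landmarks guide the coarse stages and the surface term dominates
#' the fine ones. Defaults are this package's choices for face-scale meshes
#' (units mm).
#'
#' @param stiffness_schedule strictly decreasing positive stiffness weights,
#'   one outer step each.
#' @param landmark_weight_schedule non-negative landmark weights, same
#'   length as `stiffness_schedule`.
#' @param max_inner_iter maximum inner iterations per stiffness step. A
#'   small cap (default 3) is deliberate: each closest-point reassignment
#'   can only pull vertices along the target surface, so long inner loops
#'   accumulate tangential drift of the correspondence while improving the
#'   surface fit negligibly.
#' @param inner_tol inner-loop convergence: stop when mean vertex motion
#'   falls below this (mm).
#' @param correspondence_cutoff discard closest-point matches farther than
#'   this (mm).
#' @param normals_agreement_cutoff discard matches whose template/target
#'   normals have a dot product below this (default cos 60 degrees).
#' @param exclude_boundary discard matches whose closest point lies on a
#'   triangle touching the target's open boundary. Useful when the target
#'   is cropped or has holes near the rim; off by default because when the
#'   template spans the whole target, border matches legitimately pin the
#'   template edge.
#' @param gamma weight of the affine translation column in the stiffness
#'   penalty.
#' @return Object of class `nicp_config`.
#' @export
nicp_config <- function(stiffness_schedule = c(50, 20, 5, 2, 0.8, 0.5,
                                               0.35, 0.2),
                        landmark_weight_schedule =
                          seq(5, 0, length.out = length(stiffness_schedule)),
                        max_inner_iter = 3L,
                        inner_tol = 1e-3,
                        correspondence_cutoff = 10,
                        normals_agreement_cutoff = 0.5,
                        exclude_boundary = FALSE,
                        gamma = 1) {
  if (any(diff(stiffness_schedule) >= 0) || any(stiffness_schedule <= 0))
    stop("stiffness_schedule must be strictly decreasing and positive")
  if (length(landmark_weight_schedule) != length(stiffness_schedule))
    stop("schedules must have equal length")
  if (any(landmark_weight_schedule < 0))
    stop("landmark weights must be non-negative")
  if (normals_agreement_cutoff < -1 || normals_agreement_cutoff > 1)
    stop("normals_agreement_cutoff must lie in [-1, 1]")
  structure(list(stiffness_schedule = as.numeric(stiffness_schedule),
                 landmark_weight_schedule =
                   as.numeric(landmark_weight_schedule),
                 max_inner_iter = as.integer(max_inner_iter),
                 inner_tol = inner_tol,
                 correspondence_cutoff = correspondence_cutoff,
                 normals_agreement_cutoff = normals_agreement_cutoff,
                 exclude_boundary = isTRUE(exclude_boundary),
                 gamma = gamma),
            class = "nicp_config")
}

#' Area-weighted vertex normals
#'
#' @param mesh `trimesh` (or vertex matrix with `faces` supplied).
#' @param faces triangulation when `mesh` is a bare matrix.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh, faces = NULL) {
  if (inherits(mesh, "trimesh")) { v <- mesh$vertices; f <- mesh$faces }
  else { v <- as.matrix(mesh); f <- faces }
  fn <- face_normals_raw(v, f)  # area-weighted (unnormalised cross products)
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    acc <- rowsum(fn, group = f[, j], reorder = FALSE)
    rows <- as.integer(rownames(acc))
    n[rows, ] <- n[rows, ] + acc
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_normals_raw <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

face_normals <- function(v, f) {
  n <- face_normals_raw(v, f)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# triangles containing an edge shared by no second triangle (open border)
boundary_triangles <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1L))
  tri_of_edge <- rep(seq_len(nrow(faces)), 3L)
  sort(unique(tri_of_edge[key %in% once]))
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# connected components of the template's vertex graph (BFS over edges)
graph_components <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[u]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

closest_points <- function(query, target_vertices, target_faces) {
  .closest_point_on_mesh(query, target_vertices, target_faces)
}

# map template landmark points to their nearest template vertex indices
landmark_vertex_indices <- function(template, lms) {
  d2 <- outer(rowSums(lms$points^2), rep(1, nrow(template$vertices))) -
    2 * lms$points %*% t(template$vertices) +
    outer(rep(1, nrow(lms$points)), rowSums(template$vertices^2))
  apply(d2, 1, which.min)
}

#' Non-rigid ICP registration of a template mesh onto a target scan
#'
#' Deforms the template onto the target surface with a locally-affine
#' deformation model: each template vertex carries a 3 x 4 affine transform,
#' solved jointly from a sparse linear system that balances (i) distance
#' from deformed template vertices to their closest compatible points on
#' the target surface, (ii) sparse landmark mismatch, and (iii) a stiffness
#' penalty on transform differences across template edges. The outer loop
#' lowers the stiffness (see [nicp_config()]); the inner loop alternates
#' closest-point search and the linear solve until vertex motion stalls.
#' Closest-point matches farther than the cutoff, or with disagreeing
#' normals, get zero data weight, so holes in the target are skipped rather
#' than attracting the template.
#'
#' @param template `trimesh` to deform (defines the shared triangulation).
#' @param target `trimesh` to register onto.
#' @param template_landmarks,target_landmarks optional `landmark_set`s with
#'   identical names guiding the coarse stages; `NULL` disables the
#'   landmark term.
#' @param config `nicp_config`.
#' @return List: `shape` (`flat_shape`, deformed template), `residual`
#'   (mean closest-point distance over retained correspondences, mm),
#'   `n_retained` (correspondences kept at the final step).
#' @export
nicp_register <- function(template, target, template_landmarks = NULL,
                          target_landmarks = NULL, config = nicp_config()) {
  stopifnot(inherits(template, "trimesh"), inherits(target, "trimesh"))
  use_lm <- !is.null(template_landmarks) && !is.null(target_landmarks)
  if (xor(is.null(template_landmarks), is.null(target_landmarks)))
    stop("provide landmarks for both meshes or neither")
  if (use_lm) {
    if (!setequal(template_landmarks$names, target_landmarks$names))
      stop("landmark sets do not share names")
    ord <- match(template_landmarks$names, target_landmarks$names)
    target_lm_pts <- target_landmarks$points[ord, , drop = FALSE]
    lm_idx <- landmark_vertex_indices(template, template_landmarks)
  }
  n <- nrow(template$vertices)
  edges <- mesh_edges(template$faces)
  comp <- graph_components(n, edges)
  if (max(comp) > 1L)
    stop("template mesh is disconnected (", max(comp),
         " components; e.g. vertex ", which(comp == 2L)[1],
         " unreachable from vertex 1): stiffness system would be singular")

  # constant sparse blocks
  ne <- nrow(edges)
  G <- c(1, 1, 1, config$gamma)
  # kron(incidence, diag(G)): rows 4 per edge
  ii <- rep(seq_len(4L * ne), 2L)
  jj <- c(4L * rep(edges[, 1] - 1L, each = 4L) + rep(1:4, ne),
          4L * rep(edges[, 2] - 1L, each = 4L) + rep(1:4, ne))
  xx <- c(rep(-G, ne), rep(G, ne))
  MG <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(4L * ne, 4L * n))
  K <- Matrix::crossprod(MG)  # stiffness normal-equation block

  Dmat <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 4L),
    j = c(4L * (seq_len(n) - 1L) + 1L, 4L * (seq_len(n) - 1L) + 2L,
          4L * (seq_len(n) - 1L) + 3L, 4L * (seq_len(n) - 1L) + 4L),
    x = c(template$vertices[, 1], template$vertices[, 2],
          template$vertices[, 3], rep(1, n)),
    dims = c(n, 4L * n))

  tgt_fn <- face_normals(target$vertices, target$faces)
  tgt_border <- if (config$exclude_boundary)
    boundary_triangles(target$faces) else integer(0)

  # initialise with per-vertex identity transforms
  X <- matrix(0, 4L * n, 3)
  X[seq(1, 4L * n, by = 4L), 1] <- 1
  X[seq(2, 4L * n, by = 4L), 2] <- 1
  X[seq(3, 4L * n, by = 4L), 3] <- 1

  deformed <- as.matrix(Dmat %*% X)
  residual <- NA_real_
  n_retained <- n
  for (step in seq_along(config$stiffness_schedule)) {
    alpha <- config$stiffness_schedule[step]
    beta <- if (use_lm) config$landmark_weight_schedule[step] else 0
    for (inner in seq_len(config$max_inner_iter)) {
      cp <- closest_points(deformed, target$vertices, target$faces)
      vn <- vertex_normals(deformed, template$faces)
      agree <- rowSums(vn * tgt_fn[cp$triangle, , drop = FALSE])
      w <- as.numeric(cp$distance <= config$correspondence_cutoff &
                        agree >= config$normals_agreement_cutoff &
                        !cp$triangle %in% tgt_border)
      U <- cp$points
      U[w == 0, ] <- deformed[w == 0, ]  # zero-weight rows: inert targets
      WD <- Dmat * w
      AtA <- alpha^2 * K + Matrix::crossprod(WD)
      AtB <- Matrix::crossprod(WD, U * w)
      if (beta > 0) {
        DL <- Dmat[lm_idx, , drop = FALSE]
        AtA <- AtA + beta^2 * Matrix::crossprod(DL)
        AtB <- AtB + beta^2 * Matrix::crossprod(DL, target_lm_pts)
      }
      X <- as.matrix(Matrix::solve(AtA, AtB))
      newdef <- as.matrix(Dmat %*% X)
      motion <- mean(sqrt(rowSums((newdef - deformed)^2)))
      deformed <- newdef
      if (motion < config$inner_tol) break
    }
    cp <- closest_points(deformed, target$vertices, target$faces)
    vn <- vertex_normals(deformed, template$faces)
    agree <- rowSums(vn * tgt_fn[cp$triangle, , drop = FALSE])
    keep <- cp$distance <= config$correspondence_cutoff &
      agree >= config$normals_agreement_cutoff &
      !cp$triangle %in% tgt_border
    n_retained <- sum(keep)
    residual <- if (n_retained > 0) mean(cp$distance[keep]) else Inf
  }
  list(shape = flatten(deformed), residual = residual,
       n_retained = n_retained)
}

#' A corresponded mesh collection
#'
#' @param template_faces shared triangulation.
#' @param shapes list of `flat_shape` deformed templates, one per scan.
#' @param residuals per-scan registration residual (mm).
#' @param ids scan identifiers.
#' @param failures named list of per-scan error messages for scans that
#'   failed to register.
#' @return Object of class `corresponded_set`.
#' @export
corresponded_set <- function(template_faces, shapes, residuals = NULL,
                             ids = NULL, failures = list()) {
  if (length(shapes)) {
    nv <- vapply(shapes, function(s) as_flat(s)$n_vertices, 0L)
    if (length(unique(nv)) > 1L)
      stop("shapes disagree on vertex count")
    shapes <- lapply(shapes, as_flat)
  }
  if (is.null(residuals)) residuals <- rep(NA_real_, length(shapes))
  if (is.null(ids)) ids <- sprintf("scan_%03d", seq_along(shapes))
  if (!is.null(residuals) && length(residuals) &&
      any(residuals[!is.na(residuals)] < 0))
    stop("residuals must be non-negative")
  structure(list(template_faces = template_faces, shapes = shapes,
                 residuals = residuals, ids = as.character(ids),
                 failures = failures),
            class = "corresponded_set")
}

#' @export
print.corresponded_set <- function(x, ...) {
  cat(sprintf("corresponded_set: %d shapes%s\n", length(x$shapes),
              if (length(x$shapes))
                sprintf(" x %d vertices", x$shapes[[1]]$n_vertices) else ""))
  if (length(x$failures))
    cat("  failed scans:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Register a template onto every scan in a collection
#'
#' Each scan is first similarity-aligned into template space using its
#' sparse landmarks ([procrustes_pair()] with scale), then densely
#' registered with [nicp_register()]. Scans that fail are recorded and the
#' batch continues; output order matches input order.
#'
#' @param template `trimesh` template (e.g. from [make_template()] or a
#'   cohort mean face).
#' @param scans list of `trimesh` scans.
#' @param landmarks list of per-scan `landmark_set`s (same order as
#'   `scans`).
#' @param template_landmarks `landmark_set` on the template.
#' @param config `nicp_config`.
#' @param verbose print per-scan residuals.
#' @return `corresponded_set` (one `flat_shape` per successful scan, in
#'   template space).
#' @export
build_correspondence <- function(template, scans, landmarks,
                                 template_landmarks,
                                 config = nicp_config(), verbose = FALSE) {
  if (length(scans) == 0L)
    return(corresponded_set(template$faces, list(), numeric(0),
                            character(0)))
  if (length(landmarks) != length(scans))
    stop("need one landmark set per scan")
  shapes <- list(); residuals <- numeric(0); ids <- character(0)
  failures <- list()
  for (i in seq_along(scans)) {
    id <- tryCatch(scans[[i]]$id, error = function(e) sprintf("scan_%d", i))
    res <- tryCatch({
      scan <- scans[[i]]
      lm <- landmarks[[i]]
      ord <- match(template_landmarks$names, lm$names)
      if (any(is.na(ord)))
        stop("scan landmarks missing names: ",
             paste(setdiff(template_landmarks$names, lm$names),
                   collapse = ", "))
      pre <- procrustes_pair(lm$points[ord, , drop = FALSE],
                             template_landmarks$points, with_scale = TRUE)
      scan_al <- apply_transform(pre, scan)
      lm_al <- landmark_set(lm$mesh_id,
                            apply_transform(pre,
                                            lm$points[ord, , drop = FALSE]),
                            template_landmarks$names)
      nicp_register(template, scan_al, template_landmarks, lm_al, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      if (verbose) message("  ", id, ": FAILED (", failures[[id]], ")")
    } else {
      shapes <- c(shapes, list(res$shape))
      residuals <- c(residuals, res$residual)
      ids <- c(ids, id)
      if (verbose)
        message(sprintf("  %s: residual %.3f mm", id, res$residual))
    }
  }
  corresponded_set(template$faces, shapes, residuals, ids, failures)
}
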