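#' Compactness: cumulative variance retained per component count
#'
#' \eqn{c(k) = \sum_{i \le k} \lambda_i / \sum_i \lambda_i} over the model's
#' full-rank variance spectrum; non-decreasing and 1 at full rank.
#'
#' @param model `morphable_model`.
#' @return Numeric vector, `c[k]` = fraction of total variance captured by
#'   the first k components.
#' @export
compactness <- function(model) {
  v <- model$variances_full
  cumsum(v) / sum(v)
}

#' Generalisation: leave-one-out reconstruction error of unseen faces
#'
#' For each evaluation shape, a model is fitted to all shapes but that one
#' and the held-out shape is projected with the leading k components; the
#' error is the average Euclidean distance (mm) between the held-out shape
#' and its reconstruction. Within a fold the error is non-increasing in k
#' (nested projections). When `eval_ids` is a subset (e.g. patients within
#' a mixed cohort), only those shapes are held out while all remaining
#' shapes still train each fold's model.
#'
#' @param shapes `corresponded_set`/`aligned_set` or m x 3n matrix.
#' @param k_grid component counts to evaluate.
#' @param eval_ids indices (or ids, for a `corresponded_set`) of the shapes
#'   to hold out; default all.
#' @return List: `summary` (data.frame k / mean / sd, mm) and `per_fold`
#'   (folds x k matrix of AEDs).
#' @export
generalisation <- function(shapes, k_grid, eval_ids = NULL) {
  ids <- NULL
  if (inherits(shapes, c("corresponded_set", "aligned_set"))) {
    ids <- if (!is.null(shapes$ids)) shapes$ids else NULL
    X <- do.call(rbind, lapply(shapes$shapes, function(s) as_flat(s)$x))
  } else X <- as.matrix(shapes)
  m <- nrow(X)
  if (m < 3L) stop("need at least 3 shapes for leave-one-out")
  if (is.null(eval_ids)) eval_idx <- seq_len(m)
  else if (is.character(eval_ids)) {
    if (is.null(ids)) stop("character eval_ids need a set with ids")
    eval_idx <- match(eval_ids, ids)
    if (any(is.na(eval_idx)))
      stop("unknown eval ids: ",
           paste(eval_ids[is.na(eval_idx)], collapse = ", "))
  } else eval_idx <- as.integer(eval_ids)
  k_grid <- as.integer(k_grid)
  per_fold <- matrix(NA_real_, length(eval_idx), length(k_grid),
                     dimnames = list(NULL, paste0("k", k_grid)))
  for (f in seq_along(eval_idx)) {
    i <- eval_idx[f]
    fold_model <- fit_pca(X[-i, , drop = FALSE])
    avail <- model_dim(fold_model)
    kk <- pmin(k_grid, avail)
    if (any(k_grid > avail))
      warning("fold ", f, ": k clipped to ", avail, " available components")
    for (j in seq_along(kk)) {
      pr <- project(fold_model, X[i, ], n_components = kk[j])
      per_fold[f, j] <- aed(pr$projection, X[i, ])
    }
  }
  summary <- data.frame(k = k_grid,
                        mean = colMeans(per_fold),
                        sd = apply(per_fold, 2, stats::sd))
  list(summary = summary, per_fold = per_fold)
}

#' Specificity: distance from synthesised faces to the nearest real face
#'
#' Randomly synthesises `n_synth` faces from the model and, for each,
#' computes the exact minimum average Euclidean distance (mm) over all real
#' shapes. Low values mean synthetic faces resemble real ones. The
#' neighbour search is exhaustive, so the minimum is exact.
#'
#' @param model `morphable_model`.
#' @param real_shapes `corresponded_set`/`aligned_set` or m x 3n matrix of
#'   ground-truth shapes (same vertex count as the model).
#' @param n_synth number of synthesised faces.
#' @param seed RNG seed for synthesis.
#' @param sd_trunc optional truncation of coefficient draws (see
#'   [sample_faces()]).
#' @return List: `mean`, `sd` (mm), `minima` (per-synthesised-face nearest
#'   distances).
#' @export
specificity <- function(model, real_shapes, n_synth = 1000, seed = 1L,
                        sd_trunc = Inf) {
  if (inherits(real_shapes, c("corresponded_set", "aligned_set")))
    R <- do.call(rbind, lapply(real_shapes$shapes, function(s) as_flat(s)$x))
  else R <- as.matrix(real_shapes)
  if (nrow(R) < 1L) stop("real shape set is empty")
  synth <- sample_faces(model, n_synth, seed = seed, sd_trunc = sd_trunc)
  minima <- vapply(synth, function(s) {
    sx <- as_flat(if (inherits(s, "trimesh")) flatten(s) else s)$x
    min(vapply(seq_len(nrow(R)), function(i) {
      d <- matrix(sx - R[i, ], ncol = 3, byrow = TRUE)
      mean(sqrt(rowSums(d^2)))
    }, 0))
  }, 0)
  list(mean = mean(minima), sd = stats::sd(minima), minima = minima,
       n_synth = n_synth, seed = seed)
}

#' Full intrinsic metrics report for a model
#'
#' Convenience wrapper producing the standard validation triple.
#'
#' @param model `morphable_model`.
#' @param shapes training/evaluation shapes (see [generalisation()]).
#' @param k_grid component counts.
#' @param eval_ids held-out subset for generalisation.
#' @param n_synth,seed specificity settings.
#' @return Object of class `metrics_report` with `compactness`,
#'   `generalisation`, `specificity`.
#' @export
model_metrics <- function(model, shapes, k_grid = NULL, eval_ids = NULL,
                          n_synth = 500, seed = 1L) {
  if (is.null(k_grid)) {
    d <- length(model$variances_full)
    k_grid <- unique(pmin(c(1, 2, 5, 10, 20, 50, 100, d), d))
  }
  structure(list(compactness = compactness(model),
                 generalisation = generalisation(shapes, k_grid,
                                                 eval_ids = eval_ids),
                 specificity = specificity(model, shapes, n_synth = n_synth,
                                           seed = seed),
                 k_grid = k_grid, n_synth = n_synth, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  c10 <- x$compactness[min(10, length(x$compactness))]
  cat(sprintf("metrics_report\n  compactness at 10 components: %.1f%%\n",
              100 * c10))
  g <- x$generalisation$summary
  cat(sprintf("  generalisation at k=%d: %.3f +/- %.3f mm\n",
              g$k[nrow(g)], g$mean[nrow(g)], g$sd[nrow(g)]))
  cat(sprintf("  specificity (n=%d): %.3f +/- %.3f mm\n", x$n_synth,
              x$specificity$mean, x$specificity$sd))
  invisible(x)
}
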