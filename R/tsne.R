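#' t-SNE embedding of shape vectors
#'
#' Maps high-dimensional shape coefficients to two dimensions for manifold
#' visualisation, preserving local neighbourhoods. This is the exact
#' (non-Barnes-Hut) t-distributed stochastic neighbour embedding: Gaussian
#' input affinities calibrated per point to the requested perplexity by
#' binary search, Student-t output affinities, gradient descent with
#' momentum, adaptive gains and early exaggeration. Deterministic under a
#' fixed seed. Cohort sizes here (hundreds of faces) are well within reach
#' of the exact algorithm.
#'
#' @param alphas m x d matrix of shape coefficients (one row per face), or
#'   a list of `shape_vector`s.
#' @param labels optional length-m group labels (e.g. volunteer / preop /
#'   postop) carried into the output table.
#' @param perplexity effective neighbourhood size; requires
#'   `m >= 3 * perplexity`.
#' @param n_iter gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @param ids optional row identifiers.
#' @return data.frame with columns `id`, `label`, `x`, `y` (one row per
#'   face).
#' @export
tsne_embed <- function(alphas, labels = NULL, perplexity = 30,
                       n_iter = 1000, seed = 1L, ids = NULL) {
  if (is.list(alphas) && !is.matrix(alphas))
    alphas <- do.call(rbind, lapply(alphas, coef_vec))
  X <- as.matrix(alphas)
  m <- nrow(X)
  if (m < 3 * perplexity)
    stop("too few points (", m, ") for perplexity ", perplexity,
         " (need at least ", ceiling(3 * perplexity), ")")
  if (is.null(labels)) labels <- rep("face", m)
  if (is.null(ids)) ids <- sprintf("face_%04d", seq_len(m))

  P <- .tsne_affinities(X, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(m * 2, sd = 1e-4), m, 2))

  momentum <- 0.5; final_momentum <- 0.8
  # conservative learning rate: large steps destabilise the early
  # exaggeration phase at cohort-scale point counts
  eta <- max(50, m / 12)
  gains <- matrix(1, m, 2)
  inc <- matrix(0, m, 2)
  P4 <- P * 4  # early exaggeration
  eps <- .Machine$double.eps
  for (iter in seq_len(n_iter)) {
    Pi <- if (iter <= 100) P4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), eps)
    L <- (Pi - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- final_momentum
  }
  data.frame(id = ids, label = as.character(labels), x = Y[, 1], y = Y[, 2],
             stringsAsFactors = FALSE)
}

# symmetrised input affinities at a given perplexity (binary search on the
# Gaussian bandwidth per point)
.tsne_affinities <- function(X, perplexity) {
  m <- nrow(X)
  sumX <- rowSums(X^2)
  D2 <- outer(sumX, sumX, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  target <- log(perplexity)
  P <- matrix(0, m, m)
  for (i in seq_len(m)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(s) + beta * sum(di * p) / s
        p <- p / s
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * m)
  pmax(P, .Machine$double.eps)
}

#' Hyper-parameter sweep driver for t-SNE
#'
#' Runs [tsne_embed()] over grids of perplexity and iteration count and
#' returns one labelled embedding per combination.
#'
#' @inheritParams tsne_embed
#' @param perplexities numeric grid of perplexity values.
#' @param n_iters integer grid of iteration counts.
#' @return Named list of embeddings (`perp<P>_iter<N>`).
#' @export
tsne_sweep <- function(alphas, labels = NULL, perplexities = c(2, 30, 100),
                       n_iters = 1000, seed = 1L, ids = NULL) {
  out <- list()
  for (p in perplexities)
    for (ni in n_iters)
      out[[sprintf("perp%g_iter%d", p, ni)]] <-
        tsne_embed(alphas, labels, perplexity = p, n_iter = ni,
                   seed = seed, ids = ids)
  out
}
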