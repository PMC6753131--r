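# small corresponded cohort in exact correspondence (no registration),
# reused across the metric tests
eval_cohort <- function(n = 25, seed = 1, resolution = 10) {
  co <- sample_cohort(generator_config(resolution = resolution,
                                       n_volunteers = n, n_patients = 0,
                                       seed = seed))
  do.call(rbind, lapply(co$ground_truth$true_vertices, function(v)
    flatten(v)$x))
}

test_that("compactness matches constructed variances and the Gram oracle", {
  # rank-2 data with component sample variances exactly 4 and 1
  set.seed(1)
  U <- qr.Q(qr(matrix(rnorm(60 * 2), ncol = 2)))
  m <- 11
  a1 <- scale(rnorm(m), center = TRUE, scale = FALSE)
  a2 <- scale(rnorm(m), center = TRUE, scale = FALSE)
  a2 <- a2 - a1 * sum(a1 * a2) / sum(a1^2)          # orthogonalise
  a1 <- a1 / sqrt(sum(a1^2) / (m - 1)) * 2           # variance 4
  a2 <- a2 / sqrt(sum(a2^2) / (m - 1)) * 1           # variance 1
  X <- cbind(a1, a2) %*% t(U)
  mdl <- fit_pca(X)
  cc <- compactness(mdl)
  expect_equal(cc[1], 0.8, tolerance = 1e-10)
  expect_equal(cc[2], 1.0, tolerance = 1e-10)
  # any model reaches exactly 1 at full rank
  X2 <- eval_cohort(20, seed = 2)
  mdl2 <- fit_pca(X2)
  cc2 <- compactness(mdl2)
  expect_equal(cc2[length(cc2)], 1, tolerance = 1e-12)
  expect_true(all(diff(cc2) >= -1e-12))
  # Gram-matrix eigenvalue oracle
  Xc <- sweep(X2, 2, colMeans(X2))
  ev <- eigen(Xc %*% t(Xc), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[seq_along(cc2)]
  expect_equal(cc2, cumsum(ev) / sum(ev), tolerance = 1e-8)
})

test_that("generalisation equals a naive leave-one-out loop", {
  X <- eval_cohort(12, seed = 3)
  k_grid <- c(1, 3, 5)
  got <- generalisation(X, k_grid)
  # literal re-implementation: loop folds, fresh PCA, truncated basis
  naive <- matrix(0, nrow(X), length(k_grid))
  for (i in seq_len(nrow(X))) {
    Xi <- X[-i, , drop = FALSE]
    mu <- colMeans(Xi)
    sv <- svd(sweep(Xi, 2, mu), nu = 0)
    for (j in seq_along(k_grid)) {
      U <- sv$v[, seq_len(k_grid[j]), drop = FALSE]
      rec <- mu + as.vector(U %*% crossprod(U, X[i, ] - mu))
      naive[i, j] <- aed_loop(shape_coords(rec), shape_coords(X[i, ]))
    }
  }
  expect_equal(unname(got$per_fold), naive, tolerance = 1e-8)
  expect_equal(got$summary$mean, colMeans(naive), tolerance = 1e-8)
})

test_that("generalisation is non-increasing in k for every fold", {
  X <- eval_cohort(15, seed = 4)
  got <- generalisation(X, k_grid = c(1, 2, 4, 8, 12))
  for (f in seq_len(nrow(got$per_fold)))
    expect_true(all(diff(got$per_fold[f, ]) <= 1e-10))
  # a face inside the span of the rest reconstructs exactly at full rank
  X2 <- eval_cohort(10, seed = 5)
  X2[10, ] <- colMeans(X2[1:9, ]) + 0.3 * (X2[1, ] - colMeans(X2[1:9, ]))
  g2 <- generalisation(X2, k_grid = 8, eval_ids = 10)
  expect_lt(g2$per_fold[1, 1], 1e-8)
})

test_that("generalisation restricted to an evaluation subset works", {
  X <- eval_cohort(14, seed = 6)
  sub <- c(2, 5, 9)
  got <- generalisation(X, k_grid = c(2, 5), eval_ids = sub)
  expect_identical(nrow(got$per_fold), length(sub))
  full <- generalisation(X, k_grid = c(2, 5))
  expect_equal(got$per_fold, full$per_fold[sub, ], tolerance = 1e-12)
})

test_that("specificity equals the exhaustive double-loop oracle", {
  X <- eval_cohort(20, seed = 7)
  mdl <- fit_pca(X)
  got <- specificity(mdl, X, n_synth = 50, seed = 8)
  synth <- sample_faces(mdl, 50, seed = 8)
  minima <- numeric(50)
  for (s in seq_len(50)) {
    sx <- shape_coords(synth[[s]])
    best <- Inf
    for (i in seq_len(nrow(X)))
      best <- min(best, aed_loop(sx, shape_coords(X[i, ])))
    minima[s] <- best
  }
  expect_equal(got$minima, minima, tolerance = 1e-8)
  expect_equal(got$mean, mean(minima), tolerance = 1e-8)
  # determinism under the seed
  again <- specificity(mdl, X, n_synth = 50, seed = 8)
  expect_identical(got$minima, again$minima)
  expect_error(specificity(mdl, X[0, , drop = FALSE], 10), "empty")
})

test_that("specificity decreases weakly as the real set grows", {
  X <- eval_cohort(24, seed = 9)
  mdl <- fit_pca(X[1:12, , drop = FALSE])
  small <- specificity(mdl, X[1:12, , drop = FALSE], n_synth = 40,
                       seed = 10)
  large <- specificity(mdl, X, n_synth = 40, seed = 10)
  expect_true(all(large$minima <= small$minima + 1e-12))
})

test_that("t-SNE separates well-separated blobs and is seeded", {
  set.seed(11)
  A <- rbind(matrix(rnorm(25 * 4), 25, 4),
             matrix(rnorm(25 * 4, mean = 10), 25, 4))
  labels <- rep(c("volunteer", "preop"), each = 25)
  e1 <- tsne_embed(A, labels, perplexity = 8, n_iter = 300, seed = 12)
  e2 <- tsne_embed(A, labels, perplexity = 8, n_iter = 300, seed = 12)
  expect_identical(e1, e2)
  expect_gt(silhouette_mean(as.matrix(e1[, c("x", "y")]), labels), 0.5)
  expect_identical(nrow(e1), 50L)
  expect_error(tsne_embed(A, labels, perplexity = 30), "too few points")
})

test_that("the t-SNE sweep driver emits one embedding per grid point", {
  set.seed(13)
  A <- matrix(rnorm(40 * 3), 40, 3)
  got <- tsne_sweep(A, perplexities = c(2, 5, 10), n_iters = 100,
                    seed = 14)
  expect_length(got, 3)
  expect_named(got, c("perp2_iter100", "perp5_iter100", "perp10_iter100"))
  for (e in got) expect_identical(nrow(e), 40L)
})

test_that("the combined metrics report is coherent", {
  X <- eval_cohort(12, seed = 15)
  mdl <- fit_pca(X)
  rep <- model_metrics(mdl, X, k_grid = c(2, 5, 10), n_synth = 20,
                       seed = 16)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$compactness[length(rep$compactness)], 1,
               tolerance = 1e-12)
  expect_true(all(rep$generalisation$summary$mean >= 0))
  expect_gte(rep$specificity$mean, 0)
  expect_output(print(rep), "compactness")
})
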