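# helper: random aligned shape matrix from a known low-rank generator
make_lowrank_data <- function(m, n_vertices, rank, sds, seed = 1) {
  set.seed(seed)
  mu <- as.vector(t(matrix(rnorm(3 * n_vertices, sd = 10), n_vertices)))
  U <- qr.Q(qr(matrix(rnorm(3 * n_vertices * rank), ncol = rank)))
  A <- matrix(rnorm(m * rank), m) %*% diag(sds, rank)
  list(X = rep(1, m) %o% mu + A %*% t(U), mu = mu, U = U, A = A)
}

test_that("PCA recovers an exact low-rank generative subspace", {
  g <- make_lowrank_data(20, 40, 2, c(4, 2), seed = 1)
  mdl <- fit_pca(g$X)
  expect_lt(max_principal_angle(mdl$basis[, 1:2], g$U), 1e-6)
  # all variance in two components
  expect_equal(sum(mdl$variances_full[1:2]) / sum(mdl$variances_full), 1,
               tolerance = 1e-10)
  # basis orthonormal
  expect_lt(max(abs(crossprod(mdl$basis) - diag(ncol(mdl$basis)))), 1e-8)
  # variances descending
  expect_true(all(diff(mdl$variances) <= 0))
})

test_that("two training shapes give one component along their difference", {
  set.seed(2)
  a <- rnorm(30)
  b <- rnorm(30)
  mdl <- fit_pca(rbind(a, b))
  expect_identical(ncol(mdl$basis), 1L)
  d <- (a - b) / sqrt(sum((a - b)^2))
  expect_equal(abs(sum(mdl$basis[, 1] * d)), 1, tolerance = 1e-10)
})

test_that("full-rank PCA reconstructs every training face exactly", {
  co <- sample_cohort(generator_config(resolution = 10, n_volunteers = 50,
                                       n_patients = 0, seed = 3))
  X <- do.call(rbind, lapply(co$ground_truth$true_vertices, function(v)
    flatten(v)$x))
  mdl <- fit_pca(X)
  for (i in c(1, 25, 50)) {
    pr <- project(mdl, X[i, ])
    expect_lt(aed(pr$projection, shape_coords(X[i, ])), 1e-8)
  }
})

test_that("projection satisfies the shape-space identities", {
  g <- make_lowrank_data(15, 30, 5, c(5, 4, 3, 2, 1), seed = 4)
  mdl <- fit_pca(g$X)
  set.seed(5)
  for (rep in 1:5) {
    x <- rnorm(90, sd = 10)
    pr <- project(mdl, x)
    # idempotence
    pr2 <- project(mdl, pr$projection)
    expect_lt(max(abs(pr2$alpha$alpha - pr$alpha$alpha)), 1e-10)
    expect_lt(max(abs(pr2$projection$x - pr$projection$x)), 1e-10)
    # Pythagoras decomposition
    lhs <- sum((x - mdl$mean$x)^2)
    rhs <- sum((pr$projection$x - mdl$mean$x)^2) +
      sum((x - pr$projection$x)^2)
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
  # mean projects to zero coefficients
  pr0 <- project(mdl, mdl$mean)
  expect_lt(max(abs(pr0$alpha$alpha)), 1e-10)
  # unit-basis displacement is read back exactly
  x1 <- mdl$mean$x + 5 * mdl$basis[, 1]
  a1 <- project(mdl, x1)$alpha$alpha
  expect_equal(a1[1], 5, tolerance = 1e-10)
  expect_lt(max(abs(a1[-1])), 1e-10)
})

test_that("the projection is the least-squares optimum (random probes)", {
  g <- make_lowrank_data(12, 25, 4, c(4, 3, 2, 1), seed = 6)
  mdl <- fit_pca(g$X)
  set.seed(7)
  x <- rnorm(75, sd = 8)
  pr <- project(mdl, x)
  best <- sum((x - pr$projection$x)^2)
  d <- ncol(mdl$basis)
  for (i in 1:1000) {
    beta <- pr$alpha$alpha + rnorm(d, sd = 0.5)
    cand <- mdl$mean$x + as.vector(mdl$basis %*% beta)
    expect_gte(sum((x - cand)^2), best - 1e-10)
  }
})

test_that("synthesis implements mean-plus-basis exactly", {
  co <- sample_cohort(generator_config(resolution = 10, n_volunteers = 12,
                                       n_patients = 0, seed = 8))
  X <- do.call(rbind, lapply(co$ground_truth$true_vertices, function(v)
    flatten(v)$x))
  mdl <- fit_pca(X, template_faces = co$template$mesh$faces)
  # zero coefficients give the mean face
  m0 <- synthesise(mdl, numeric(0))
  expect_equal(flatten(m0)$x, mdl$mean$x)
  # +3 sigma / -3 sigma faces are symmetric about the mean
  v <- 3 * sqrt(mdl$variances[1])
  plus <- flatten(synthesise(mdl, c(v)))$x
  minus <- flatten(synthesise(mdl, c(-v)))$x
  expect_equal(plus + minus, 2 * mdl$mean$x, tolerance = 1e-10)
  expect_error(synthesise(mdl, rep(0, ncol(mdl$basis) + 1)), "longer")
  # project -> synthesise round-trip inside the subspace
  x <- mdl$mean$x + as.vector(mdl$basis %*% rnorm(ncol(mdl$basis)))
  pr <- project(mdl, x)
  expect_lt(aed(synthesise(mdl, pr$alpha), shape_coords(x)), 1e-10)
})

test_that("clipping and degenerate inputs are handled", {
  g <- make_lowrank_data(5, 20, 2, c(3, 1), seed = 9)
  expect_warning(mdl <- fit_pca(g$X, n_components = 10), "clipped")
  expect_identical(ncol(mdl$basis), 4L)
  expect_error(fit_pca(g$X[1, , drop = FALSE]), "at least 2")
  mdl2 <- fit_pca(g$X)
  expect_error(project(mdl2, rnorm(30)), "vertex count")
})

test_that("random synthesis is seeded and matches the model variances", {
  g <- make_lowrank_data(30, 20, 2, c(6, 2), seed = 10)
  mdl <- fit_pca(g$X, n_components = 2)
  s1 <- sample_faces(mdl, 5, seed = 11)
  s2 <- sample_faces(mdl, 5, seed = 11)
  expect_identical(s1, s2)
  expect_length(sample_faces(mdl, 1, seed = 1), 1)
  # law of large numbers: sample variance within 5% at m = 10000
  draws <- sample_faces(mdl, 10000, seed = 12)
  A <- t(vapply(draws, function(s) project(mdl, s)$alpha$alpha, numeric(2)))
  v <- apply(A, 2, var)
  expect_lt(max(abs(v / mdl$variances - 1)), 0.05)
})

test_that("parameter recovery from a sampled population is accurate", {
  sds <- c(6, 5, 4, 3, 2.5)
  g <- make_lowrank_data(500, 40, 5, sds, seed = 13)
  noisy <- g$X + matrix(rnorm(length(g$X), sd = 0.1), nrow(g$X))
  mdl <- fit_pca(noisy, n_components = 5)
  expect_lt(max_principal_angle(mdl$basis, g$U), 2)
  expect_lt(max(abs(mdl$variances / sds^2 - 1)), 0.15)
})
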