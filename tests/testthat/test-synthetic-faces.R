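test_that("the template is a manifold grid with consistent winding", {
  tpl <- make_template(generator_config(resolution = 20))
  m <- tpl$mesh
  expect_identical(nrow(m$vertices), 400L)
  expect_identical(nrow(m$faces), 722L)  # 2 * 19^2
  # consistent winding: all face normals point towards +z (anterior)
  fn <- morphface:::face_normals(m$vertices, m$faces)
  expect_true(all(fn[, 3] > 0))
  # every interior edge is shared by exactly two triangles
  e <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) <= 2))
  # deterministic
  expect_identical(make_template(generator_config(resolution = 20)), tpl)
})

test_that("the pronasale is the global z-maximum by construction", {
  tpl <- make_template(generator_config(resolution = 16))
  i <- attr(tpl$landmarks, "vertex_index")[
    match("pronasale", tpl$landmarks$names)]
  expect_identical(which.max(tpl$mesh$vertices[, 3]), i)
  expect_gte(length(tpl$landmarks$names), 5)
  expect_true(check_landmarks(tpl$landmarks, tpl$mesh))
})

test_that("cohorts are reproducible bit-for-bit under one seed", {
  cfg <- generator_config(resolution = 10, n_volunteers = 5,
                          n_patients = 3, seed = 99)
  c1 <- sample_cohort(cfg)
  c2 <- sample_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- sample_cohort(generator_config(resolution = 10, n_volunteers = 5,
                                       n_patients = 3, seed = 100))
  expect_false(identical(c1$meshes, c3$meshes))
})

test_that("every patient preop has a paired postop scan", {
  co <- sample_cohort(generator_config(resolution = 10, n_volunteers = 4,
                                       n_patients = 113, seed = 1))
  ct <- co$cohort
  expect_identical(sum(ct$group == "preop"), 113L)
  expect_identical(sum(ct$group == "postop"), 113L)
  pre <- ct[ct$group == "preop", ]
  post <- ct[ct$group == "postop", ]
  expect_setequal(pre$pair_id, post$pair_id)
  expect_identical(anyDuplicated(pre$pair_id), 0L)
})

test_that("zero effect size makes patients and volunteers exchangeable", {
  co <- sample_cohort(generator_config(resolution = 10, n_volunteers = 25,
                                       n_patients = 25, seed = 5,
                                       effect_size = 0, nose_residual = 0,
                                       surgical_shrink = 1,
                                       surgical_mixing = 0,
                                       surgical_sd = 0))
  X <- do.call(rbind, lapply(co$ground_truth$true_vertices, function(v)
    flatten(v)$x))
  rownames(X) <- names(co$ground_truth$true_vertices)
  mdl <- fit_pca(X)
  A <- t(apply(X, 1, function(r) project(mdl, r)$alpha$alpha))
  rownames(A) <- rownames(X)
  rep <- classify_diagnosis(co$cohort, A, split_spec(0.8, 60, seed = 6))
  expect_gt(rep$accuracy, 0.3)
  expect_lt(rep$accuracy, 0.7)
})

test_that("noiseless unjittered cohorts recover the generative subspace", {
  co <- sample_cohort(generator_config(resolution = 10, n_volunteers = 40,
                                       n_patients = 0, seed = 7,
                                       noise_sd = 0, rot_max_deg = 0,
                                       trans_max = 0, scale_jitter = 0))
  X <- do.call(rbind, lapply(co$meshes, function(m) flatten(m)$x))
  mdl <- fit_pca(X, n_components = co$config$rank)
  expect_lt(max_principal_angle(mdl$basis, co$ground_truth$basis),
            180 / pi * 1e-6)  # helper reports degrees
})

test_that("observed meshes are the stored truth under the stored jitter", {
  co <- sample_cohort(generator_config(resolution = 10, n_volunteers = 3,
                                       n_patients = 2, seed = 8,
                                       noise_sd = 0))
  for (id in names(co$meshes)) {
    rebuilt <- apply_transform(co$ground_truth$transforms[[id]],
                               co$ground_truth$true_vertices[[id]])
    expect_lt(aed(rebuilt, co$meshes[[id]]$vertices), 1e-10)
  }
  # landmarks ride with their vertices
  lm_idx <- attr(co$template$landmarks, "vertex_index")
  for (id in names(co$meshes))
    expect_equal(co$landmarks[[id]]$points,
                 co$meshes[[id]]$vertices[lm_idx, , drop = FALSE],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the patient effect localises to the jaw dipole", {
  # cohort sizes large enough for the group means to average out the
  # generative variation (200 volunteers, 113 patient pairs)
  co <- sample_cohort(generator_config(resolution = 12, n_volunteers = 200,
                                       n_patients = 113, seed = 9))
  gt <- lapply(co$ground_truth$true_vertices, flatten)
  al <- generalised_procrustes(gt)
  X <- do.call(rbind, lapply(al$shapes, function(s) s$x))
  grp <- co$cohort$group
  mean_pre <- colMeans(X[grp == "preop", , drop = FALSE])
  mean_vol <- colMeans(X[grp == "volunteer", , drop = FALSE])
  sem <- signed_error_map(shape_coords(mean_pre), shape_coords(mean_vol))
  mask <- jaw_mask(co, expand = TRUE)
  expect_gte(sum(abs(sem[mask])) / sum(abs(sem)), 0.8)
  # dipole polarity: lower jaw protrudes (+z), upper jaw recedes (-z)
  w <- co$ground_truth$jaw_weights
  expect_gt(mean(sem[w > 0.5]), 0)
  expect_lt(mean(sem[w < -0.5]), 0)
})

test_that("the surgical operator removes most of the jaw displacement", {
  # silence every other variation source so the pre/post difference in the
  # jaw region isolates the operator's effect on the dipole itself
  co <- sample_cohort(generator_config(resolution = 12, n_volunteers = 2,
                                       n_patients = 10, seed = 10,
                                       basis_sd = rep(1e-9, 10),
                                       surgical_sd = 0, noise_sd = 0))
  gt <- co$ground_truth
  mask <- jaw_mask(co, expand = FALSE)
  tplv <- co$template$mesh$vertices
  pre_dev <- post_dev <- 0
  for (p in sprintf("pat_%04d", 1:10)) {
    pre <- gt$true_vertices[[paste0(p, "_pre")]]
    post <- gt$true_vertices[[paste0(p, "_post")]]
    pre_dev <- pre_dev + mean(sqrt(rowSums((pre - tplv)[mask, ]^2)))
    post_dev <- post_dev + mean(sqrt(rowSums((post - tplv)[mask, ]^2)))
  }
  # default jaw_residual is 0.1; the small persisting nose effect overlaps
  # the upper-jaw fringe, so allow some slack above the pure residual
  expect_lt(post_dev, 0.3 * pre_dev)
})

test_that("generator_config validates its inputs", {
  expect_error(generator_config(resolution = 4), "at least 8")
  expect_error(generator_config(effect_size = -1), "non-negative")
  expect_error(generator_config(rank = 3, basis_sd = c(1, 2, 3)),
               "positive and non-increasing")
  expect_error(generator_config(rank = 2, basis_sd = 1),
               "one value per rank")
})
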