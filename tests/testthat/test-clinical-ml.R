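# shared fixture: corresponded cohort + model + coefficients, built once
ml_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- sample_cohort(generator_config(resolution = 12,
                                         n_volunteers = 30,
                                         n_patients = 15, seed = 21))
    X <- do.call(rbind, lapply(co$ground_truth$true_vertices, function(v)
      flatten(v)$x))
    rownames(X) <- names(co$ground_truth$true_vertices)
    al <- generalised_procrustes(lapply(seq_len(nrow(X)), function(i)
      shape_coords(X[i, ])))
    Xa <- do.call(rbind, lapply(al$shapes, function(s) s$x))
    rownames(Xa) <- rownames(X)
    mdl <- fit_pca(Xa, template_faces = co$template$mesh$faces)
    A <- t(apply(Xa, 1, function(r) project(mdl, r)$alpha$alpha))
    rownames(A) <- rownames(Xa)
    shapes <- corresponded_set(co$template$mesh$faces,
                               lapply(seq_len(nrow(Xa)), function(i)
                                 flatten(shape_coords(Xa[i, ]))),
                               ids = rownames(Xa))
    cache <<- list(co = co, model = mdl, alphas = A, shapes = shapes)
    cache
  }
})

test_that("cohort_table enforces ids, labels and pairing", {
  expect_error(cohort_table(c("a", "a")), "duplicate")
  expect_error(cohort_table("a", group = "patient"), "unknown group")
  expect_error(cohort_table(c("a", "b"), group = c("postop", "volunteer"),
                            pair_id = c("p1", NA)),
               "without a matching preop")
  ct <- cohort_table(c("a", "b"), group = c("preop", "postop"),
                     pair_id = c("p1", "p1"))
  expect_s3_class(ct, "cohort_table")
})

test_that("stratified split arithmetic reproduces the 140/280 case", {
  ct <- cohort_table(sprintf("s%03d", 1:420),
                     group = rep(c("preop", "volunteer"), c(140, 280)))
  spec <- split_spec(0.8, n_iterations = 5, seed = 1)
  splits <- make_splits(ct, spec)
  y <- ifelse(ct$group == "preop", "patient", "non-patient")
  names(y) <- ct$scan_id
  for (sp in splits) {
    expect_identical(sum(y[sp$train] == "patient"), 112L)
    expect_identical(sum(y[sp$train] == "non-patient"), 224L)
    expect_identical(sum(y[sp$test] == "patient"), 28L)
    expect_identical(sum(y[sp$test] == "non-patient"), 56L)
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("splits are seeded and degenerate fractions are rejected", {
  expect_error(split_spec(1.0), "strictly")
  expect_error(split_spec(0), "strictly")
  ct <- cohort_table(sprintf("s%02d", 1:30),
                     group = rep(c("preop", "volunteer"), c(10, 20)))
  s1 <- make_splits(ct, split_spec(0.6, 50, seed = 7))
  s2 <- make_splits(ct, split_spec(0.6, 50, seed = 7))
  expect_identical(s1, s2)
  s3 <- make_splits(ct, split_spec(0.6, 50, seed = 8))
  expect_false(identical(s1, s3))
  one <- cohort_table(c("a", "b", "c"),
                      group = c("preop", "volunteer", "volunteer"))
  expect_error(make_splits(one, split_spec(0.5, 1)), "fewer than 2")
})

test_that("a separable cohort classifies almost perfectly", {
  fx <- ml_fixture()
  rep <- classify_diagnosis(fx$co$cohort, fx$alphas,
                            split_spec(0.8, 100, seed = 31))
  expect_gt(rep$accuracy, 0.95)
  expect_identical(rep$n_iterations, 100L)
  # confusion marginals equal the test-partition class counts everywhere
  expect_true(all(rep$per_iteration[, "TP"] + rep$per_iteration[, "FN"] ==
                    3))   # round(0.2 * 15)
  expect_true(all(rep$per_iteration[, "TN"] + rep$per_iteration[, "FP"] ==
                    6))   # round(0.2 * 30)
  # stored metrics recompute from the stored mean confusion matrix
  cm <- rep$mean_confusion
  expect_equal(rep$sensitivity, unname(cm["TP"] / (cm["TP"] + cm["FN"])))
  expect_equal(rep$ppv, unname(cm["TP"] / (cm["TP"] + cm["FP"])))
  expect_equal(rep$accuracy, unname((cm["TP"] + cm["TN"]) / sum(cm)))
})

test_that("permuted labels drop a balanced cohort to chance level", {
  fx <- ml_fixture()
  ids <- c(fx$co$cohort$scan_id[fx$co$cohort$group == "preop"],
           fx$co$cohort$scan_id[fx$co$cohort$group == "volunteer"][1:15])
  set.seed(33)
  perm <- cohort_table(ids, group = sample(rep(c("preop", "volunteer"),
                                               each = 15)))
  rep <- classify_diagnosis(perm, fx$alphas[ids, ],
                            split_spec(0.8, 100, seed = 34))
  expect_gt(rep$accuracy, 0.4)
  expect_lt(rep$accuracy, 0.6)
})

test_that("accuracy sweep over component counts returns one row per k", {
  fx <- ml_fixture()
  sw <- sweep_classification(fx$co$cohort, fx$alphas,
                             split_spec(0.8, 20, seed = 35),
                             k_grid = c(2, 5, 10))
  expect_identical(sw$k, c(2, 5, 10))
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
})

test_that("the noiseless design matrix is identified exactly by OLS", {
  set.seed(41)
  k <- 6; n <- 40
  A_true <- diag(runif(k, 0.8, 1.1))
  A_true[1, 2] <- 0.15
  X <- matrix(rnorm(n * k, sd = 5), n, k)
  Y <- X %*% A_true
  reg <- fit_surgery_regressor("lr", X, Y, k = k)
  expect_lt(max(abs(reg$W - A_true)), 1e-8)
  expect_lt(max(abs(reg$intercept)), 1e-8)
  expect_lt(max(abs(predict(reg, X[1, ]) - Y[1, ])), 1e-8)
})

test_that("ridge approaches the identity fit as its penalty vanishes", {
  set.seed(42)
  k <- 4; n <- 30
  X <- matrix(rnorm(n * k, sd = 5), n, k)
  err <- vapply(c(10, 1, 1e-4), function(a) {
    reg <- fit_surgery_regressor("rr", X, X, k = k,
                                 hyper = list(rr_alpha = a))
    mean(abs(predict(reg, X) - X))
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-6)
})

test_that("one-step LARS keeps a single predictor per output", {
  set.seed(43)
  k <- 5; n <- 50
  X <- matrix(rnorm(n * k, sd = c(8, 6, 4, 3, 2)), n, k, byrow = TRUE)
  Y <- X %*% diag(c(1, 0.9, 1.1, 0.95, 1)) +
    matrix(rnorm(n * k, sd = 0.05), n, k)
  reg <- fit_surgery_regressor("lars", X, Y, k = k)
  nz <- colSums(abs(reg$W) > 1e-12)
  expect_true(all(nz <= 1))
  # the dominant predictor of output i is input i here
  expect_identical(unname(apply(abs(reg$W), 2, which.max)), 1:5)
})

test_that("regularised methods beat OLS when k approaches sample size", {
  fx <- ml_fixture()
  rep <- evaluate_regression(fx$model, fx$co$cohort, fx$shapes,
                             k_grid = c(5, 13))
  s <- rep$summary[rep$summary$k == 13, ]
  lr <- s$aed_mean[s$method == "lr"]
  expect_gt(lr, s$aed_mean[s$method == "rr"])
  expect_gt(lr, s$aed_mean[s$method == "lasso"])
  expect_gt(lr, s$aed_mean[s$method == "lars"])
})

test_that("predictions are patient-specific, not population averages", {
  fx <- ml_fixture()
  rep <- evaluate_regression(fx$model, fx$co$cohort, fx$shapes,
                             methods = c("rr"), k_grid = 10)
  s <- rep$summary
  expect_lt(s$aed_mean, s$aed_vs_mean_face)
  expect_lt(s$aed_mean, s$aed_vs_mean_postop)
})

test_that("leave-one-out bookkeeping is complete and leak-free", {
  fx <- ml_fixture()
  methods <- c("lr", "rr")
  k_grid <- c(3, 6)
  rep <- evaluate_regression(fx$model, fx$co$cohort, fx$shapes,
                             methods = methods, k_grid = k_grid)
  expect_identical(dim(rep$per_fold), c(2L, 2L, 15L))
  expect_identical(nrow(rep$summary), 4L)
  # held-out pair never appears in its own training set
  for (p in seq_len(15))
    expect_false(rep$pairs$pair_id[p] %in% rep$train_ids[[p]])
  # every training set holds the other 14 pairs exactly
  expect_true(all(vapply(rep$train_ids, length, 0L) == 14L))
  ext <- simulation_extremes(rep, method = "rr")
  expect_identical(ext$case, c("best", "worst"))
  expect_lte(ext$aed[1], ext$aed[2])
})

test_that("simulate_postop composes projection, map and synthesis", {
  fx <- ml_fixture()
  k <- 8
  pre_ids <- fx$co$cohort$scan_id[fx$co$cohort$group == "preop"]
  x <- fx$shapes$shapes[[match(pre_ids[1], fx$shapes$ids)]]
  # identity regressor returns the k-component projection
  ident <- structure(list(method = "lr", k = k, W = diag(k),
                          intercept = rep(0, k), hyper = list(),
                          n_pairs = 10), class = "surgery_regressor")
  out <- simulate_postop(fx$model, ident, x)
  pr <- project(fx$model, x, n_components = k)
  expect_lt(aed(out, pr$projection), 1e-10)
  # zero regressor returns the mean face
  zero <- structure(list(method = "lr", k = k, W = matrix(0, k, k),
                         intercept = rep(0, k), hyper = list(),
                         n_pairs = 10), class = "surgery_regressor")
  out0 <- simulate_postop(fx$model, zero, x)
  expect_lt(aed(out0, fx$model$mean), 1e-10)
  # a fitted regressor predicts the paired postop within the noise budget:
  # twice the irreducible floor (surgical outcome variability plus sensor
  # noise) covers estimation error at this cohort size
  rep <- evaluate_regression(fx$model, fx$co$cohort, fx$shapes,
                             methods = "rr", k_grid = 10)
  gen <- fx$co$config
  expect_lt(rep$summary$aed_mean, 2 * (gen$surgical_sd + gen$noise_sd))
})

test_that("evaluate_regression validates pairing", {
  fx <- ml_fixture()
  ct <- fx$co$cohort
  broken <- ct[ct$scan_id != "pat_0003_post", ]
  broken$pair_id[broken$scan_id == "pat_0003_pre"] <- "orphan"
  expect_error(evaluate_regression(fx$model,
                                   cohort_table(broken$scan_id,
                                                broken$subject_id,
                                                broken$group,
                                                broken$pair_id),
                                   fx$shapes),
               "orphan")
})
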