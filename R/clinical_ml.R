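#' Per-scan cohort metadata table
#'
#' One row per scan: identifier, subject, group label (volunteer /
#' preoperative / postoperative), and an optional pairing key linking a
#' subject's preoperative and postoperative scans.
#'
#' @param scan_id unique scan identifiers.
#' @param subject_id subject identifiers.
#' @param group factor/character: `"volunteer"`, `"preop"`, or `"postop"`.
#' @param pair_id pairing key (`NA` for unpaired scans); every postop scan
#'   with a pair key must have a preop scan with the same key.
#' @param age,sex,ethnicity optional demographics.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(scan_id, subject_id = scan_id,
                         group = c("volunteer"), pair_id = NA,
                         age = NA, sex = NA, ethnicity = NA) {
  df <- data.frame(scan_id = as.character(scan_id),
                   subject_id = as.character(subject_id),
                   group = as.character(group),
                   pair_id = as.character(pair_id),
                   age = age, sex = sex, ethnicity = ethnicity,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$scan_id))
    stop("duplicate scan_id: ",
         paste(unique(df$scan_id[duplicated(df$scan_id)]), collapse = ", "))
  bad <- !df$group %in% c("volunteer", "preop", "postop")
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(df$group[bad]),
                                           collapse = ", "))
  po <- df[df$group == "postop" & !is.na(df$pair_id), ]
  pre_keys <- df$pair_id[df$group == "preop" & !is.na(df$pair_id)]
  orphan <- setdiff(po$pair_id, pre_keys)
  if (length(orphan))
    stop("postop scans without a matching preop pair: ",
         paste(orphan, collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Monte-Carlo cross-validation split specification
#'
#' @param train_fraction fraction of each class used for training, in
#'   (0, 1).
#' @param n_iterations number of random splits.
#' @param stratified preserve class proportions (per-class counts are
#'   `round(fraction * class size)` in every iteration).
#' @param seed RNG seed making the whole split sequence reproducible.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, n_iterations = 1000,
                       stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)")
  structure(list(train_fraction = train_fraction,
                 n_iterations = as.integer(n_iterations),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

# diagnosis label: preop scans are the patient class, volunteers the
# non-patient class; postop scans are excluded from classification
diagnosis_labels <- function(cohort) {
  keep <- cohort$group %in% c("preop", "volunteer")
  y <- ifelse(cohort$group[keep] == "preop", "patient", "non-patient")
  names(y) <- cohort$scan_id[keep]
  factor(y, levels = c("non-patient", "patient"))
}

#' Generate stratified Monte-Carlo train/test splits
#'
#' Each iteration draws a fresh random split; with stratification, every
#' class contributes `round(train_fraction * class size)` scans to
#' training and the remainder to testing, so e.g. 140 patient + 280
#' non-patient scans at 80-20 give 112/224 training and 28/56 test scans
#' in every iteration.
#'
#' @param cohort `cohort_table` (classification uses preop vs volunteer
#'   scans), or a named factor of labels.
#' @param spec `split_spec`.
#' @return List of `n_iterations` elements, each
#'   `list(train = scan ids, test = scan ids)`.
#' @export
make_splits <- function(cohort, spec) {
  y <- if (inherits(cohort, "cohort_table")) diagnosis_labels(cohort)
       else as.factor(cohort)
  if (nlevels(droplevels(y)) < 2L)
    stop("need two classes present to split")
  tab <- table(droplevels(y))
  if (any(tab < 2L))
    stop("class with fewer than 2 members: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  n_train <- round(spec$train_fraction * tab)
  if (any(n_train == 0) || any(n_train == tab))
    stop("split leaves an empty partition for class ",
         paste(names(tab)[n_train == 0 | n_train == tab], collapse = ", "))
  ids_by_class <- split(names(y), droplevels(y))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_iterations), function(it) {
      if (spec$stratified) {
        tr <- unlist(lapply(names(ids_by_class), function(cl)
          sample(ids_by_class[[cl]], n_train[[cl]])), use.names = FALSE)
      } else {
        all_ids <- unlist(ids_by_class, use.names = FALSE)
        tr <- sample(all_ids, round(spec$train_fraction * length(all_ids)))
      }
      list(train = tr, test = setdiff(names(y), tr))
    })
  })
}

#' Linear-SVM diagnosis of patient versus non-patient face shape
#'
#' Monte-Carlo cross-validated classification in shape-coefficient space:
#' per iteration a fresh stratified split is drawn, a linear support vector
#' machine (cost C = 1, coefficients used raw) is trained on the training
#' partition's leading `n_components` coefficients, and the test partition
#' is predicted. Confusion counts (patient = positive class) and per-scan
#' misclassification tallies are accumulated over iterations.
#'
#' @param cohort `cohort_table`.
#' @param alphas matrix of shape coefficients, rownames = scan_id.
#' @param spec `split_spec`.
#' @param n_components number of leading coefficients to use (default all).
#' @param scale standardise features inside the SVM (default `FALSE`:
#'   coefficients enter raw).
#' @return Object of class `classifier_report`: mean confusion matrix
#'   (`TP`, `FP`, `FN`, `TN`), `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, per-iteration confusion counts, per-scan
#'   misclassification counts, iterations used/skipped.
#' @export
classify_diagnosis <- function(cohort, alphas, spec, n_components = NULL,
                               scale = FALSE) {
  y_all <- diagnosis_labels(cohort)
  ids <- intersect(names(y_all), rownames(alphas))
  if (length(ids) < 4L) stop("too few labelled scans with coefficients")
  y_all <- y_all[ids]
  X <- alphas[ids, , drop = FALSE]
  if (!is.null(n_components)) {
    if (n_components > ncol(X))
      stop("n_components exceeds available coefficients")
    X <- X[, seq_len(n_components), drop = FALSE]
  }
  splits <- make_splits(droplevels(y_all), spec)
  conf <- matrix(0L, length(splits), 4,
                 dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  miscls <- stats::setNames(integer(length(ids)), ids)
  tested <- stats::setNames(integer(length(ids)), ids)
  used <- logical(length(splits))
  for (it in seq_along(splits)) {
    tr <- splits[[it]]$train; te <- splits[[it]]$test
    if (nlevels(droplevels(y_all[tr])) < 2L) next  # degenerate: skip, log
    fit <- e1071::svm(X[tr, , drop = FALSE], y_all[tr], kernel = "linear",
                      cost = 1, scale = scale)
    pred <- stats::predict(fit, X[te, , drop = FALSE])
    truth <- y_all[te]
    conf[it, "TP"] <- sum(pred == "patient" & truth == "patient")
    conf[it, "FP"] <- sum(pred == "patient" & truth == "non-patient")
    conf[it, "FN"] <- sum(pred == "non-patient" & truth == "patient")
    conf[it, "TN"] <- sum(pred == "non-patient" & truth == "non-patient")
    wrong <- te[pred != truth]
    miscls[wrong] <- miscls[wrong] + 1L
    tested[te] <- tested[te] + 1L
    used[it] <- TRUE
  }
  if (!any(used)) stop("every iteration had a single-class training set")
  cm <- colMeans(conf[used, , drop = FALSE])
  rep <- list(mean_confusion = cm,
              accuracy = (cm["TP"] + cm["TN"]) / sum(cm),
              sensitivity = cm["TP"] / (cm["TP"] + cm["FN"]),
              specificity = cm["TN"] / (cm["TN"] + cm["FP"]),
              ppv = cm["TP"] / (cm["TP"] + cm["FP"]),
              npv = cm["TN"] / (cm["TN"] + cm["FN"]),
              per_iteration = conf[used, , drop = FALSE],
              misclassified = miscls, times_tested = tested,
              n_iterations = sum(used), n_skipped = sum(!used),
              n_components = ncol(X))
  rep[c("accuracy", "sensitivity", "specificity", "ppv", "npv")] <-
    lapply(rep[c("accuracy", "sensitivity", "specificity", "ppv", "npv")],
           unname)
  structure(rep, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    paste0("classifier_report: %d iterations, %d components\n",
           "  accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, ",
           "PPV %.1f%%, NPV %.1f%%\n"),
    x$n_iterations, x$n_components, 100 * x$accuracy, 100 * x$sensitivity,
    100 * x$specificity, 100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' Classification accuracy as a function of component count
#'
#' @inheritParams classify_diagnosis
#' @param k_grid component counts to evaluate.
#' @return data.frame: k, accuracy, sensitivity, specificity.
#' @export
sweep_classification <- function(cohort, alphas, spec, k_grid) {
  rows <- lapply(k_grid, function(k) {
    r <- classify_diagnosis(cohort, alphas, spec, n_components = k)
    data.frame(k = k, accuracy = r$accuracy, sensitivity = r$sensitivity,
               specificity = r$specificity)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Surgery-simulation regression: preop coefficients -> postop coefficients
# ---------------------------------------------------------------------------

#' Fit the preoperative-to-postoperative design matrix
#'
#' Learns the multivariate linear map from the leading `k` preoperative
#' shape coefficients to the `k` postoperative ones, under the chosen
#' penalty:
#' * `"lr"` ordinary least squares;
#' * `"rr"` ridge (penalty weight 0.5, intercept unpenalised);
#' * `"lasso"` L1 (penalty weight 0.1);
#' * `"lars"` least-angle regression stopped at one nonzero coefficient
#'   per output component (in practice postop component i is predicted
#'   from its dominant preop component).
#'
#' @param method `"lr"`, `"rr"`, `"lasso"`, or `"lars"`.
#' @param preop_alphas,postop_alphas n_pairs x d coefficient matrices,
#'   rows paired (same patient).
#' @param k number of components to map (default all columns).
#' @param hyper list of penalty settings: `rr_alpha` (default 0.5),
#'   `lasso_alpha` (default 0.1), `lars_nonzero` (default 1).
#' @return Object of class `surgery_regressor`: `W` (k x k; `W[i, j]` is
#'   the weight of preop component i on postop component j), `intercept`
#'   (length k), `method`, `k`.
#' @export
fit_surgery_regressor <- function(method = c("lr", "rr", "lasso", "lars"),
                                  preop_alphas, postop_alphas, k = NULL,
                                  hyper = list()) {
  method <- match.arg(method)
  hy <- utils::modifyList(list(rr_alpha = 0.5, lasso_alpha = 0.1,
                               lars_nonzero = 1L), hyper)
  Xf <- as.matrix(preop_alphas); Yf <- as.matrix(postop_alphas)
  if (nrow(Xf) != nrow(Yf)) stop("preop/postop pair counts differ")
  if (nrow(Xf) < 2L) stop("need at least 2 preop/postop pairs")
  if (is.null(k)) k <- min(ncol(Xf), ncol(Yf))
  if (k > ncol(Xf) || k > ncol(Yf))
    stop("k = ", k, " exceeds available components")
  X <- Xf[, seq_len(k), drop = FALSE]
  Y <- Yf[, seq_len(k), drop = FALSE]
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  W <- switch(method,
    lr = {
      fit <- stats::lm.fit(Xc, Yc)
      as.matrix(stats::coef(fit))
    },
    rr = {
      # sklearn-style objective ||Y - XW||^2 + a ||W||^2, closed form
      solve(crossprod(Xc) + hy$rr_alpha * diag(k), crossprod(Xc, Yc))
    },
    lasso = {
      n <- nrow(X)
      vapply(seq_len(k), function(j) {
        if (k >= 2) {
          fit <- glmnet::glmnet(Xc, Yc[, j], alpha = 1,
                                lambda = hy$lasso_alpha,
                                standardize = FALSE, intercept = FALSE,
                                thresh = 1e-12)
          as.numeric(fit$beta)
        } else {
          # univariate soft threshold for objective
          # 1/(2n)||y - xw||^2 + a|w|
          num <- sum(Xc * Yc[, j]) / n
          den <- sum(Xc^2) / n
          sign(num) * max(0, abs(num) - hy$lasso_alpha) / den
        }
      }, numeric(k))
    },
    lars = {
      vapply(seq_len(k), function(j)
        lars_one_step(Xc, Yc[, j]), numeric(k))
    })
  W[is.na(W)] <- 0  # rank-deficient OLS: unidentified directions get 0
  dimnames(W) <- NULL
  intercept <- ybar - as.vector(crossprod(W, xbar))
  structure(list(method = method, k = k, W = W, intercept = intercept,
                 hyper = hy, n_pairs = nrow(X)), class = "surgery_regressor")
}

# single least-angle-regression step: advance the most-correlated predictor
# until a second one would enter, leaving exactly one nonzero coefficient
lars_one_step <- function(Xc, yc) {
  k <- ncol(Xc)
  cvec <- as.vector(crossprod(Xc, yc))
  j <- which.max(abs(cvec))
  C <- abs(cvec[j]); s <- sign(cvec[j])
  if (C == 0) return(numeric(k))
  nj <- sqrt(sum(Xc[, j]^2))
  if (nj == 0) return(numeric(k))
  u <- s * Xc[, j] / nj              # equiangular direction
  a <- as.vector(crossprod(Xc, u))   # inactive projections
  gamma <- C / nj                    # full OLS step if nothing else enters
  for (m in seq_len(k)[-j]) {
    for (g in c((C - cvec[m]) / (nj - a[m]), (C + cvec[m]) / (nj + a[m])))
      if (is.finite(g) && g > 1e-12 && g < gamma) gamma <- g
  }
  beta <- numeric(k)
  beta[j] <- gamma * s / nj
  beta
}

#' Predict postoperative coefficients from preoperative ones
#'
#' @param object `surgery_regressor`.
#' @param alpha length-k vector (or n x k matrix) of preoperative
#'   coefficients.
#' @param ... unused.
#' @return Predicted postoperative coefficients, same shape as `alpha`.
#' @export
predict.surgery_regressor <- function(object, alpha, ...) {
  a <- if (inherits(alpha, "shape_vector")) alpha$alpha else alpha
  if (is.matrix(a)) {
    if (ncol(a) != object$k) stop("coefficient dimension mismatch")
    sweep(a %*% object$W, 2, object$intercept, "+")
  } else {
    if (length(a) != object$k) stop("coefficient dimension mismatch")
    as.vector(crossprod(object$W, a)) + object$intercept
  }
}

#' Simulate the postoperative face shape from a preoperative scan
#'
#' Projects the (corresponded) preoperative scan onto the model, truncates
#' to the regressor's k leading coefficients, maps them through the learnt
#' design matrix, and synthesises the predicted postoperative mesh.
#'
#' @param model `morphable_model`.
#' @param regressor `surgery_regressor`.
#' @param preop_scan corresponded preoperative shape.
#' @param id id for the predicted mesh.
#' @return Predicted postoperative `trimesh`.
#' @export
simulate_postop <- function(model, regressor, preop_scan,
                            id = "simulated_postop") {
  pr <- project(model, preop_scan, n_components = regressor$k)
  post <- predict(regressor, pr$alpha$alpha[seq_len(regressor$k)])
  synthesise(model, post, id = id)
}

#' Leave-one-out evaluation of surgery-simulation regression
#'
#' For every preop/postop pair and every component count k: fit the design
#' matrix on all remaining pairs, simulate the held-out patient's
#' postoperative shape, and record the average Euclidean distance (mm)
#' against (i) the ground-truth postoperative shape, (ii) the cohort mean
#' face (is the prediction better than ignoring the patient?), and
#' (iii) the mean postoperative face (is it patient-specific rather than
#' an average surgical result?).
#'
#' @param model `morphable_model` (typically the global model).
#' @param cohort `cohort_table` providing preop/postop pairing.
#' @param shapes `corresponded_set` whose `ids` match `cohort$scan_id`.
#' @param methods subset of `c("lr", "rr", "lasso", "lars")`.
#' @param k_grid component counts to evaluate.
#' @param hyper penalty settings (see [fit_surgery_regressor()]).
#' @return Object of class `regression_report`: `summary` data.frame
#'   (method, k, mean/sd AED vs truth, vs mean face, vs mean postop face),
#'   `per_fold` (method x k x pair array of AEDs vs truth), `pairs`,
#'   `predictions` (per-patient predicted `flat_shape` at the largest k,
#'   per method), `train_ids` (per-fold training pair keys, for leakage
#'   audits).
#' @export
evaluate_regression <- function(model, cohort, shapes,
                                methods = c("lr", "rr", "lasso", "lars"),
                                k_grid = NULL, hyper = list()) {
  pre <- cohort[cohort$group == "preop" & !is.na(cohort$pair_id), ]
  post <- cohort[cohort$group == "postop" & !is.na(cohort$pair_id), ]
  keys <- intersect(pre$pair_id, post$pair_id)
  orphans <- c(setdiff(pre$pair_id, post$pair_id),
               setdiff(post$pair_id, pre$pair_id))
  if (length(orphans))
    stop("scans without a complete preop/postop pair: ",
         paste(orphans, collapse = ", "))
  if (length(keys) < 3L) stop("need at least 3 preop/postop pairs")
  id_pre <- pre$scan_id[match(keys, pre$pair_id)]
  id_post <- post$scan_id[match(keys, post$pair_id)]
  missing <- setdiff(c(id_pre, id_post), shapes$ids)
  if (length(missing))
    stop("paired scans missing from the corresponded set: ",
         paste(missing, collapse = ", "))
  shape_of <- function(id) shapes$shapes[[match(id, shapes$ids)]]
  d <- model_dim(model)
  if (is.null(k_grid)) k_grid <- unique(pmin(c(2, 5, 10, d), d))
  k_grid <- sort(unique(pmin(as.integer(k_grid), d)))

  A_pre <- t(vapply(id_pre, function(id)
    project(model, shape_of(id))$alpha$alpha, numeric(d)))
  A_post <- t(vapply(id_post, function(id)
    project(model, shape_of(id))$alpha$alpha, numeric(d)))
  gt_post <- lapply(id_post, shape_of)
  mean_face <- model$mean
  mean_postop <- flatten(shape_coords(
    rowMeans(vapply(gt_post, function(s) s$x, numeric(length(mean_face$x))))))

  n <- length(keys)
  per_fold <- array(NA_real_, c(length(methods), length(k_grid), n),
                    dimnames = list(methods, paste0("k", k_grid), keys))
  vs_mean <- vs_meanpost <- per_fold
  predictions <- stats::setNames(vector("list", length(methods)), methods)
  train_ids <- vector("list", n)
  for (p in seq_len(n)) {
    train_ids[[p]] <- keys[-p]
    for (mi in seq_along(methods)) {
      predictions[[methods[mi]]] <- c(predictions[[methods[mi]]], list(NULL))
      for (ki in seq_along(k_grid)) {
        k <- k_grid[ki]
        reg <- fit_surgery_regressor(methods[mi],
                                     A_pre[-p, , drop = FALSE],
                                     A_post[-p, , drop = FALSE],
                                     k = k, hyper = hyper)
        pred_a <- predict(reg, A_pre[p, seq_len(k)])
        pred <- synthesise(model, pred_a)
        per_fold[mi, ki, p] <- aed(pred, gt_post[[p]])
        vs_mean[mi, ki, p] <- aed(pred, mean_face)
        vs_meanpost[mi, ki, p] <- aed(pred, mean_postop)
        if (ki == length(k_grid))
          predictions[[methods[mi]]][[p]] <- as_flat(pred)
      }
    }
  }
  for (mi in seq_along(methods))
    names(predictions[[methods[mi]]]) <- keys
  rows <- list()
  for (mi in seq_along(methods))
    for (ki in seq_along(k_grid))
      rows[[length(rows) + 1L]] <- data.frame(
        method = methods[mi], k = k_grid[ki],
        aed_mean = mean(per_fold[mi, ki, ]),
        aed_sd = stats::sd(per_fold[mi, ki, ]),
        aed_vs_mean_face = mean(vs_mean[mi, ki, ]),
        aed_vs_mean_postop = mean(vs_meanpost[mi, ki, ]))
  structure(list(summary = do.call(rbind, rows), per_fold = per_fold,
                 vs_mean_face = vs_mean, vs_mean_postop = vs_meanpost,
                 pairs = data.frame(pair_id = keys, preop = id_pre,
                                    postop = id_post),
                 predictions = predictions, train_ids = train_ids,
                 k_grid = k_grid, methods = methods),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("regression_report (leave-one-out,", dim(x$per_fold)[3], "pairs)\n")
  kmax <- paste0("k", max(x$k_grid))
  for (m in x$methods)
    cat(sprintf("  %-5s at %s: %.3f +/- %.3f mm\n", m, kmax,
                mean(x$per_fold[m, kmax, ]), stats::sd(x$per_fold[m, kmax, ])))
  invisible(x)
}

#' Best- and worst-simulated patients from a regression report
#'
#' @param report `regression_report`.
#' @param method which regressor to inspect.
#' @param k component count (default: largest evaluated).
#' @return data.frame with the pair ids and errors of the minimum- and
#'   maximum-error simulations.
#' @export
simulation_extremes <- function(report, method = "rr", k = NULL) {
  if (is.null(k)) k <- max(report$k_grid)
  e <- report$per_fold[method, paste0("k", k), ]
  data.frame(case = c("best", "worst"),
             pair_id = c(names(which.min(e)), names(which.max(e))),
             aed = c(min(e), max(e)), row.names = NULL)
}
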