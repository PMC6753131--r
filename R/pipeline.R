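#' Pipeline run configuration
#'
#' A single serialisable configuration object driving the staged pipeline
#' commands. Every stage setting has a default, so `run_config(out = dir)`
#' is a complete desk-scale run. The resolved configuration is written as
#' YAML beside each command's outputs, making runs self-describing and
#' repeatable.
#'
#' @param out output/working directory shared by the stages.
#' @param mesh_dir,landmark_dir,cohort_file input locations; default to the
#'   locations [cmd_synth()] writes under `out`, so a fully synthetic run
#'   needs no paths at all.
#' @param template_mesh,template_landmarks template files for dense
#'   correspondence; default to the synthetic template written by
#'   [cmd_synth()].
#' @param seed master seed for every random stage.
#' @param generator list of [generator_config()] overrides.
#' @param nicp list of [nicp_config()] overrides.
#' @param split list of [split_spec()] overrides.
#' @param n_components components for classification (default all).
#' @param k_grid component counts for metrics/regression sweeps.
#' @param metrics_n_synth synthesised faces for specificity.
#' @param tsne list: `perplexities`, `n_iters` sweep grids.
#' @param regression_methods regression methods to evaluate.
#' @param log_level `"quiet"` or `"info"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out = "morphface_run",
                       mesh_dir = file.path(out, "meshes"),
                       landmark_dir = file.path(out, "landmarks"),
                       cohort_file = file.path(out, "cohort.csv"),
                       template_mesh = file.path(out, "template.ply"),
                       template_landmarks = file.path(out, "template_landmarks.txt"),
                       seed = 1L,
                       generator = list(),
                       nicp = list(),
                       split = list(),
                       n_components = NULL,
                       k_grid = NULL,
                       metrics_n_synth = 200L,
                       tsne = list(perplexities = c(2, 30), n_iters = 500L),
                       regression_methods = c("lr", "rr", "lasso", "lars"),
                       log_level = c("info", "quiet")) {
  structure(list(out = out, mesh_dir = mesh_dir,
                 landmark_dir = landmark_dir, cohort_file = cohort_file,
                 template_mesh = template_mesh,
                 template_landmarks = template_landmarks,
                 seed = as.integer(seed), generator = generator,
                 nicp = nicp, split = split, n_components = n_components,
                 k_grid = k_grid, metrics_n_synth = as.integer(metrics_n_synth),
                 tsne = tsne, regression_methods = regression_methods,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of `run_config` fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

write_resolved_config <- function(config, stage) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  plain <- unclass(config)
  plain$log_level <- as.character(plain$log_level)
  yaml::write_yaml(plain,
                   file.path(config$out, sprintf("config_%s.yaml", stage)))
}

pipe_log <- function(config, ...) {
  if (config$log_level != "quiet") message(sprintf(...))
}

resolved_generator <- function(config)
  do.call(generator_config, utils::modifyList(list(seed = config$seed),
                                              config$generator))

#' Pipeline stage: generate and write a synthetic cohort
#'
#' Writes one ASCII PLY mesh and one landmark file per scan, the template,
#' the cohort table (CSV), and the generator ground truth (JSON), then the
#' resolved configuration.
#'
#' @param config `run_config`.
#' @return The `synthetic_cohort`, invisibly.
#' @export
cmd_synth <- function(config) {
  gen <- resolved_generator(config)
  cohort <- sample_cohort(gen)
  dir.create(config$mesh_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(config$landmark_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$meshes)) {
    write_mesh(cohort$meshes[[id]],
               file.path(config$mesh_dir, paste0(id, ".ply")))
    write_landmarks(cohort$landmarks[[id]],
                    file.path(config$landmark_dir, paste0(id, ".txt")))
  }
  write_mesh(cohort$template$mesh, config$template_mesh)
  write_landmarks(cohort$template$landmarks, config$template_landmarks)
  utils::write.csv(as.data.frame(cohort$cohort), config$cohort_file,
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(list(betas = gt$betas,
                            surgical_operator = gt$surgical_operator,
                            coef_sd = gt$coef_sd),
                       file.path(config$out, "ground_truth.json"),
                       digits = NA)
  write_resolved_config(config, "synth")
  pipe_log(config, "synth: wrote %d meshes to %s", length(cohort$meshes),
           config$mesh_dir)
  invisible(cohort)
}

read_cohort_inputs <- function(config) {
  if (!file.exists(config$cohort_file))
    stop("cohort table not found: ", config$cohort_file,
         " (run cmd_synth or point cohort_file at your data)")
  if (!file.exists(config$template_mesh))
    stop("template mesh not found: ", config$template_mesh)
  df <- utils::read.csv(config$cohort_file, stringsAsFactors = FALSE)
  cohort <- cohort_table(df$scan_id, df$subject_id, df$group, df$pair_id,
                         age = df$age, sex = df$sex,
                         ethnicity = df$ethnicity)
  mesh_paths <- file.path(config$mesh_dir, paste0(cohort$scan_id, ".ply"))
  lm_paths <- file.path(config$landmark_dir, paste0(cohort$scan_id, ".txt"))
  miss <- c(mesh_paths[!file.exists(mesh_paths)],
            lm_paths[!file.exists(lm_paths)])
  if (length(miss))
    stop("missing input files: ", paste(utils::head(miss, 5),
                                        collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  list(cohort = cohort,
       scans = lapply(mesh_paths, read_mesh),
       landmarks = lapply(lm_paths, read_landmarks),
       template = read_mesh(config$template_mesh),
       template_landmarks = read_landmarks(config$template_landmarks))
}

#' Pipeline stage: correspondence, alignment, and the three shape models
#'
#' Registers the template onto every scan, aligns the corresponded set by
#' generalised Procrustes analysis, and fits three morphable models from
#' cohort-table filters: global (all scans), bespoke preoperative, and
#' bespoke postoperative. Writes the model bundle (`build.rds`), a
#' registration report, a compactness table, and signed-error PLY maps of
#' the mean preoperative and postoperative faces against the mean
#' volunteer face.
#'
#' @param config `run_config`.
#' @return List with the aligned set, cohort, and models, invisibly.
#' @export
cmd_build <- function(config) {
  inp <- read_cohort_inputs(config)
  nicp <- do.call(nicp_config, config$nicp)
  pipe_log(config, "build: registering %d scans", length(inp$scans))
  corr <- build_correspondence(inp$template, inp$scans, inp$landmarks,
                               inp$template_landmarks, nicp,
                               verbose = config$log_level == "info")
  if (length(corr$failures))
    warning("registration failed for: ",
            paste(names(corr$failures), collapse = ", "))
  aligned <- generalised_procrustes(corr$shapes)
  ok_ids <- corr$ids
  cohort <- inp$cohort[match(ok_ids, inp$cohort$scan_id), ]
  X <- do.call(rbind, lapply(aligned$shapes, function(s) s$x))
  rownames(X) <- ok_ids
  sel <- function(groups) X[cohort$group %in% groups, , drop = FALSE]
  fit_or_fail <- function(groups, label) {
    M <- sel(groups)
    if (nrow(M) < 2L)
      stop("cohort filter '", label, "' selects ", nrow(M),
           " scan(s); need at least 2")
    fit_pca(M, template_faces = corr$template_faces)
  }
  models <- list(global = fit_or_fail(c("volunteer", "preop", "postop"),
                                      "global"),
                 preop = fit_or_fail("preop", "bespoke preoperative"),
                 postop = fit_or_fail("postop", "bespoke postoperative"))
  bundle <- list(models = models, aligned = X,
                 template_faces = corr$template_faces,
                 residuals = corr$residuals, ids = ok_ids,
                 cohort = as.data.frame(cohort), seed = config$seed)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle, file.path(config$out, "build.rds"))
  utils::write.csv(data.frame(scan_id = ok_ids,
                              residual_mm = corr$residuals),
                   file.path(config$out, "registration_report.csv"),
                   row.names = FALSE)
  comp <- do.call(rbind, lapply(names(models), function(nm)
    data.frame(model = nm,
               k = seq_along(models[[nm]]$variances_full),
               compactness = compactness(models[[nm]]))))
  utils::write.csv(comp, file.path(config$out, "compactness.csv"),
                   row.names = FALSE)
  # Mean-face difference colourmaps against the mean volunteer face
  mean_of <- function(groups) colMeans(sel(groups))
  vol_mean <- mean_of("volunteer")
  for (grp in c("preop", "postop")) {
    gm <- mean_of(grp)
    sem <- signed_error_map(shape_coords(gm), shape_coords(vol_mean))
    write_mesh(unflatten(gm, corr$template_faces,
                         id = paste0("mean_", grp)),
               file.path(config$out,
                         sprintf("mean_%s_vs_volunteer.ply", grp)),
               quality = sem)
  }
  write_resolved_config(config, "build")
  pipe_log(config, "build: models global(%d) preop(%d) postop(%d)",
           models$global$n_training, models$preop$n_training,
           models$postop$n_training)
  invisible(list(aligned = X, cohort = cohort, models = models,
                 corr = corr))
}

read_bundle <- function(config) {
  path <- file.path(config$out, "build.rds")
  if (!file.exists(path))
    stop("model bundle not found: ", path, " (run cmd_build first)")
  readRDS(path)
}

bundle_alphas <- function(bundle, model = "global") {
  mdl <- bundle$models[[model]]
  A <- t(apply(bundle$aligned, 1, function(x)
    project(mdl, x)$alpha$alpha))
  rownames(A) <- bundle$ids
  A
}

#' Pipeline stage: intrinsic model metrics
#'
#' Compactness, generalisation (leave-one-out over the patient scans, as
#' in clinical evaluation of a mixed-cohort model) and specificity for the
#' global and bespoke preoperative models; written as CSV.
#'
#' @param config `run_config`.
#' @return Named list of `metrics_report`s, invisibly.
#' @export
cmd_metrics <- function(config) {
  bundle <- read_bundle(config)
  cohort <- bundle$cohort
  out <- list()
  rows <- list()
  for (nm in c("global", "preop")) {
    mdl <- bundle$models[[nm]]
    ids <- if (nm == "global") bundle$ids else
      cohort$scan_id[cohort$group == "preop"]
    X <- bundle$aligned[ids, , drop = FALSE]
    eval_ids <- which(ids %in% cohort$scan_id[cohort$group == "preop"])
    # cap at the rank available inside a leave-one-out fold (N - 2)
    d <- min(length(mdl$variances_full), nrow(X) - 2L)
    k_grid <- if (is.null(config$k_grid))
      unique(pmin(c(1, 2, 5, 10, 20, d), d)) else
        unique(pmin(config$k_grid, d))
    rep <- model_metrics(mdl, X, k_grid = k_grid, eval_ids = eval_ids,
                         n_synth = config$metrics_n_synth,
                         seed = config$seed)
    out[[nm]] <- rep
    rows[[nm]] <- data.frame(model = nm, k = k_grid,
                             compactness = rep$compactness[k_grid],
                             generalisation_mm = rep$generalisation$summary$mean,
                             generalisation_sd = rep$generalisation$summary$sd,
                             specificity_mm = rep$specificity$mean,
                             specificity_sd = rep$specificity$sd)
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config$out, "metrics.csv"), row.names = FALSE)
  write_resolved_config(config, "metrics")
  pipe_log(config, "metrics: written to %s",
           file.path(config$out, "metrics.csv"))
  invisible(out)
}

#' Pipeline stage: t-SNE manifold embedding
#'
#' Embeds the global-model shape coefficients over the configured
#' perplexity/iteration sweep and writes one labelled scatter CSV per
#' combination.
#'
#' @param config `run_config`.
#' @return Named list of embedding data.frames, invisibly.
#' @export
cmd_embed <- function(config) {
  bundle <- read_bundle(config)
  A <- bundle_alphas(bundle)
  labels <- bundle$cohort$group[match(bundle$ids, bundle$cohort$scan_id)]
  sweeps <- tsne_sweep(A, labels,
                       perplexities = config$tsne$perplexities,
                       n_iters = config$tsne$n_iters,
                       seed = config$seed, ids = bundle$ids)
  for (nm in names(sweeps))
    utils::write.csv(sweeps[[nm]],
                     file.path(config$out, sprintf("tsne_%s.csv", nm)),
                     row.names = FALSE)
  write_resolved_config(config, "embed")
  pipe_log(config, "embed: %d embeddings written", length(sweeps))
  invisible(sweeps)
}

#' Pipeline stage: SVM diagnosis
#'
#' Monte-Carlo cross-validated linear-SVM classification of preoperative
#' patient versus volunteer scans in global-model coefficient space;
#' writes the averaged confusion matrix and metrics (JSON) and the
#' per-scan misclassification table (CSV).
#'
#' @param config `run_config`.
#' @return `classifier_report`, invisibly.
#' @export
cmd_diagnose <- function(config) {
  bundle <- read_bundle(config)
  cohort <- cohort_table(bundle$cohort$scan_id, bundle$cohort$subject_id,
                         bundle$cohort$group, bundle$cohort$pair_id)
  A <- bundle_alphas(bundle)
  spec <- do.call(split_spec, utils::modifyList(list(seed = config$seed),
                                                config$split))
  rep <- classify_diagnosis(cohort, A, spec,
                            n_components = config$n_components)
  jsonlite::write_json(list(n_iterations = rep$n_iterations,
                            n_components = rep$n_components,
                            mean_confusion = as.list(rep$mean_confusion),
                            accuracy = rep$accuracy,
                            sensitivity = rep$sensitivity,
                            specificity = rep$specificity,
                            ppv = rep$ppv, npv = rep$npv),
                       file.path(config$out, "diagnosis.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(scan_id = names(rep$misclassified),
                              misclassified = rep$misclassified,
                              times_tested = rep$times_tested),
                   file.path(config$out, "misclassification.csv"),
                   row.names = FALSE)
  write_resolved_config(config, "diagnose")
  pipe_log(config, "diagnose: accuracy %.1f%% over %d iterations",
           100 * rep$accuracy, rep$n_iterations)
  invisible(rep)
}

#' Pipeline stage: surgery-simulation regression
#'
#' Leave-one-out evaluation of the preop-to-postop design-matrix
#' regressors on the global model; writes the per-method/per-k error
#' curves (CSV) and the best/worst simulated cases (JSON).
#'
#' @param config `run_config`.
#' @return `regression_report`, invisibly.
#' @export
cmd_simulate <- function(config) {
  bundle <- read_bundle(config)
  cohort <- cohort_table(bundle$cohort$scan_id, bundle$cohort$subject_id,
                         bundle$cohort$group, bundle$cohort$pair_id)
  shapes <- corresponded_set(bundle$template_faces,
                             lapply(seq_len(nrow(bundle$aligned)),
                                    function(i) flatten(
                                      shape_coords(bundle$aligned[i, ]))),
                             ids = bundle$ids)
  rep <- evaluate_regression(bundle$models$global, cohort, shapes,
                             methods = config$regression_methods,
                             k_grid = config$k_grid)
  utils::write.csv(rep$summary, file.path(config$out, "simulation.csv"),
                   row.names = FALSE)
  ext <- simulation_extremes(rep,
                             method = if ("rr" %in% rep$methods) "rr" else
                               rep$methods[1])
  jsonlite::write_json(ext, file.path(config$out,
                                      "simulation_extremes.json"),
                       digits = NA)
  write_resolved_config(config, "simulate")
  pipe_log(config, "simulate: best %.2f mm (%s), worst %.2f mm (%s)",
           ext$aed[1], ext$pair_id[1], ext$aed[2], ext$pair_id[2])
  invisible(rep)
}

#' Run the full synthetic pipeline end to end
#'
#' `synth -> build -> metrics -> embed -> diagnose -> simulate`, all
#' driven by one `run_config`; every output lands under `config$out`.
#'
#' @param config `run_config`.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  invisible(list(synth = cmd_synth(config),
                 build = cmd_build(config),
                 metrics = cmd_metrics(config),
                 embed = cmd_embed(config),
                 diagnose = cmd_diagnose(config),
                 simulate = cmd_simulate(config)))
}
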