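#' Configuration for an end-to-end pipeline run
#'
#' Bundles everything a run needs — cohort configuration, windowing,
#' model menu, weighting cases, allocation constraints and sign mode —
#' so a run is reproducible from its config alone. All randomness flows
#' from the single root seed: the cohort uses it directly and each model
#' fit derives its stream from it.
#'
#' @param cohort A [cohort_config()].
#' @param window_len,stride Windowing parameters in samples.
#' @param models Character vector of model kinds (see [model_spec()]);
#'   the first one listed drives the activation profile.
#' @param profile_model Model whose pooled LOSO predictions feed the
#'   optimizer (default `"xgb"`).
#' @param constraints An [allocation_constraints()].
#' @param sign_mode Objective sign convention, see [allocation_objective()].
#' @param seed Root seed for model fits (the cohort seed lives in
#'   `cohort`).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       window_len = 250L, stride = window_len,
                       models = c("xgb", "svr", "knn", "adaboost"),
                       profile_model = "xgb",
                       constraints = allocation_constraints(),
                       sign_mode = "goal-consistent",
                       seed = 1L) {
  stopifnot(profile_model %in% models)
  structure(list(cohort = cohort, window_len = as.integer(window_len),
                 stride = as.integer(stride), models = models,
                 profile_model = profile_model, constraints = constraints,
                 sign_mode = sign_mode, seed = as.integer(seed)),
            class = "run_config")
}

plan_as_list <- function(plan) {
  list(exercise = names(plan$x), minutes = unname(plan$x),
       minutes_rounded = unname(plan$minutes_rounded),
       objective_value = plan$objective_value,
       ws = plan$weights$ws, wd = plan$weights$wd,
       case_label = plan$weights$case_label, sign_mode = plan$sign_mode,
       method = plan$method,
       total_minutes = plan$constraints$total_minutes,
       diagnostics = plan$diagnostics)
}

#' Run the full pipeline: simulate, extract, validate, profile, optimize
#'
#' Executes every stage in order and persists each intermediate into
#' `out_dir`: `features.csv` (the windowed RMS table), `cv_report.json`
#' (fold results, grand means, dispersion, hyperparameter record),
#' `profile.json` (per-exercise s/d activations), one
#' `plan_case_*.json` per weighting case, and `run.log` (config, seeds,
#' per-stage wall time). A failing stage aborts with the stage name;
#' already-persisted intermediates are kept.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts (`features`,
#'   `cv_report`, `profile`, `plans`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(sprintf("emgdose pipeline run, %s", format(Sys.time())),
                 sprintf("R %s, emgdose %s", getRversion(),
                         as.character(utils::packageVersion("emgdose"))),
                 sprintf("root seed %d, cohort seed %d", config$seed,
                         config$cohort$seed),
                 sprintf("models: %s (profile from %s), sign mode %s",
                         paste(config$models, collapse = ", "),
                         config$profile_model, config$sign_mode),
                 sprintf("window %d, stride %d samples", config$window_len,
                         config$stride),
                 paste0("cohort: ", config$cohort$n_subjects, " subjects x ",
                        config$cohort$n_sessions, " sessions x ",
                        length(config$cohort$movements), " movements, ",
                        config$cohort$duration_per_trial, " s at ",
                        config$cohort$sampling_rate, " Hz"))
  flush_log <- function() writeLines(log_lines, log_path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("stage '%s' FAILED: %s", name,
                              conditionMessage(e)))
      flush_log()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage '%s' done in %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    flush_log()
    out
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))

  features <- stage("extract", {
    tab <- build_feature_table(cohort, config$window_len, config$stride)
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    tab
  })

  cv_report <- stage("validate", {
    specs <- lapply(config$models, function(k)
      model_spec(k, seed = config$seed))
    rep <- run_comparison(features, specs,
                          keep_predictions = TRUE)
    jsonlite::write_json(
      list(grand = rep$grand, folds = rep$folds,
           hyperparameters = rep$hyperparameters,
           aggregation = rep$aggregation),
      file.path(out_dir, "cv_report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    rep
  })

  profile <- stage("profile", {
    preds <- cv_report$predictions
    preds <- preds[preds$model == config$profile_model, ]
    prof <- activation_profile(preds, config$cohort$layer_map,
                               config$cohort$movements)
    jsonlite::write_json(as.data.frame(prof),
                         file.path(out_dir, "profile.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    prof
  })

  plans <- stage("optimize", {
    pl <- run_cases(profile, config$constraints, config$sign_mode)
    for (lab in names(pl)) {
      fname <- sprintf("plan_case_%s.json", gsub("/", "_", lab))
      jsonlite::write_json(plan_as_list(pl[[lab]]),
                           file.path(out_dir, fname),
                           auto_unbox = TRUE, digits = NA)
    }
    pl
  })

  log_lines <- c(log_lines, "run complete")
  flush_log()
  invisible(list(features = features, cv_report = cv_report,
                 profile = profile, plans = plans, out_dir = out_dir))
}

#' Render summary tables from a completed run directory
#'
#' Reads the persisted artifacts and produces the three report surfaces:
#' the per-model comparison table (grand MSE, R-squared, training time),
#' the per-muscle table grouped by anatomical layer for the
#' profile-driving model, and the per-case allocation table.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List of class `emgdose_report` with data.frames
#'   `model_comparison`, `per_muscle` and `allocations`.
#' @export
render_report <- function(run_dir) {
  need <- c("cv_report.json", "profile.json")
  for (f in need)
    if (!file.exists(file.path(run_dir, f)))
      stop("incomplete run: missing artifact '", f, "'", call. = FALSE)
  plan_files <- list.files(run_dir, pattern = "^plan_case_.*\\.json$",
                           full.names = TRUE)
  if (!length(plan_files))
    stop("incomplete run: missing artifact 'plan_case_*.json'",
         call. = FALSE)

  cv <- jsonlite::read_json(file.path(run_dir, "cv_report.json"),
                            simplifyVector = TRUE)
  comparison <- cv$grand
  folds <- cv$folds
  best <- comparison$model[1] # grand table is ranked by R2, then MSE
  agg <- stats::aggregate(cbind(mse, r2) ~ model + target_muscle,
                          data = folds[folds$model == best, , drop = FALSE],
                          FUN = mean)
  agg$layer <- unname(muscle_layer_map()[agg$target_muscle])
  per_muscle <- agg[order(agg$layer == "deep", agg$target_muscle), ]
  rownames(per_muscle) <- NULL

  allocations <- do.call(rbind, lapply(plan_files, function(f) {
    p <- jsonlite::read_json(f, simplifyVector = TRUE)
    data.frame(case = p$case_label, exercise = p$exercise,
               minutes = p$minutes, minutes_rounded = p$minutes_rounded,
               objective_value = p$objective_value)
  }))

  structure(list(model_comparison = comparison, per_muscle = per_muscle,
                 allocations = allocations),
            class = "emgdose_report")
}

#' @export
print.emgdose_report <- function(x, digits = 4, ...) {
  cat("== Model comparison (LOSO grand means) ==\n")
  print(format(x$model_comparison, digits = digits), row.names = FALSE)
  cat("\n== Per-muscle performance (by anatomical layer) ==\n")
  print(format(x$per_muscle, digits = digits), row.names = FALSE)
  cat("\n== Optimized time allocations ==\n")
  print(format(x$allocations, digits = digits), row.names = FALSE)
  invisible(x)
}
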