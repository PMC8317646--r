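#' Configuration of a full pipeline run
#'
#' Collects every tunable of the end-to-end pipeline with defaults that
#' reproduce the study protocol: 23 participants, all four regressor families
#' and all four interpolation methods, 5-fold grid-search cross-validation
#' seeded with 0, 75 uV outlier threshold, 30-s feature smoothing and a 0.25
#' Tukey taper.
#'
#' @param seed master seed; participant seeds are derived from it.
#' @param n_participants cohort size.
#' @param families regressor families to fit (subset of `ridge`,
#'   `random_forest`, `mlp`, `svr`).
#' @param interpolations interpolation methods for the SPSL trace (subset of
#'   `linear`, `pchip`, `spline`, `nearest`).
#' @param folds cross-validation folds.
#' @param model_seed seed passed to every stochastic model component
#'   (default 0).
#' @param cv_shuffle shuffle training rows before fold assignment.
#' @param clip_predictions clip test predictions to the 1-5 scale.
#' @param threshold_uv outlier amplitude threshold (uV).
#' @param smooth_window_s feature smoothing window (s).
#' @param taper_alpha Tukey taper fraction for the PSD.
#' @param mlp_maxit L-BFGS iteration cap for MLP fits (default 100; the 3-4 neuron networks converge well within it).
#' @param synth named list of overrides passed to [synth_config()] (the seed
#'   field is supplied per participant).
#' @param schedule a [session_schedule()].
#' @param out_dir optional directory; when set, per-participant feature
#'   matrices, traces and results are written there as delimited tables.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 0,
                       n_participants = 23,
                       families = c("ridge", "random_forest", "mlp", "svr"),
                       interpolations = c("linear", "pchip", "spline", "nearest"),
                       folds = 5,
                       model_seed = 0,
                       cv_shuffle = FALSE,
                       clip_predictions = FALSE,
                       threshold_uv = 75,
                       smooth_window_s = 30,
                       taper_alpha = 0.25,
                       mlp_maxit = 100,
                       synth = list(),
                       schedule = build_default_schedule(),
                       out_dir = NULL) {
  families <- match.arg(families, several.ok = TRUE)
  interpolations <- match.arg(interpolations, several.ok = TRUE)
  structure(
    list(seed = seed, n_participants = n_participants, families = families,
         interpolations = interpolations, folds = folds,
         model_seed = model_seed, cv_shuffle = cv_shuffle,
         clip_predictions = clip_predictions, threshold_uv = threshold_uv,
         smooth_window_s = smooth_window_s, taper_alpha = taper_alpha,
         mlp_maxit = mlp_maxit, synth = synth, schedule = schedule,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `seed` is a
#' top-level key and `synth` a nested mapping of [synth_config()] overrides.
#'
#' @param path YAML file path; see
#'   `system.file("extdata", "example-config.yaml", package = "stresseeg")`
#'   for a template.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "schedule")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline for one synthetic participant
#'
#' Simulates a session, preprocesses it, extracts the smoothed feature
#' matrix, interpolates the participant's surveys with every configured
#' method, and fits and evaluates every configured regressor family on each
#' trace: simulate -> preprocess -> features -> labels -> fit -> evaluate. A
#' failure in any stage aborts with the failing stage named.
#'
#' @param config a [run_config()].
#' @param participant_seed seed for this participant's simulation.
#' @param participant_id identifier recorded in the results.
#' @param keep_fits also return the fitted `stress_fit` objects.
#' @return List with `results` (data.frame, one [evaluate_predictions()] row
#'   per family x interpolation), `features` (the session `feature_matrix`),
#'   `truth`, and optionally `fits`.
#' @export
run_participant <- function(config, participant_seed,
                            participant_id = participant_seed,
                            keep_fits = FALSE) {
  stopifnot(inherits(config, "run_config"))
  sched <- config$schedule
  scfg <- stage("simulate",
                do.call(synth_config, c(list(seed = participant_seed),
                                        config$synth)))
  sess <- stage("simulate", simulate_session(sched, scfg))
  epochs <- stage("preprocess",
                  preprocess_session(sess$recordings, sched,
                                     threshold_uv = config$threshold_uv))
  fm <- stage("features",
              extract_features(epochs, window_s = config$smooth_window_s,
                               taper_alpha = config$taper_alpha))
  surveys <- stage("labels", survey_series(sess$truth$surveys))
  knots <- stage("labels", map_surveys_to_epochs(sched))
  n_ep <- nrow(fm$values)

  results <- list(); fits <- list()
  for (ip in config$interpolations) {
    trace <- stage("labels",
                   interpolate_spsl(surveys, knots, n = n_ep, method = ip))
    split <- make_split(trace)
    for (fam in config$families) {
      fit <- stage("fit", grid_search_fit(
        fam, fm$values, trace$values, split, folds = config$folds,
        seed = config$model_seed, shuffle = config$cv_shuffle,
        clip_predictions = config$clip_predictions,
        mlp_maxit = config$mlp_maxit
      ))
      res <- stage("evaluate", evaluate_predictions(
        y_test = as.numeric(surveys$spsl), y_pred = fit$predictions,
        participant = participant_id, family = fam, interpolation = ip
      ))
      results[[paste(fam, ip, sep = ".")]] <- res
      if (keep_fits) fits[[paste(fam, ip, sep = ".")]] <- fit
      if (!is.null(config$out_dir))
        write_fit_report(fit, file.path(config$out_dir,
                                        sprintf("p%s_fit_%s_%s.yaml",
                                                participant_id, fam, ip)))
    }
    if (!is.null(config$out_dir))
      write_trace(trace, file.path(config$out_dir,
                                   sprintf("p%s_trace_%s.csv",
                                           participant_id, ip)))
  }
  if (!is.null(config$out_dir)) {
    write_feature_matrix(fm, file.path(config$out_dir,
                                       sprintf("p%s_features.csv",
                                               participant_id)))
    write_surveys(sess$truth$surveys,
                  file.path(config$out_dir,
                            sprintf("p%s_surveys.csv", participant_id)))
  }
  out <- list(results = do.call(rbind, results), features = fm,
              truth = sess$truth)
  rownames(out$results) <- NULL
  if (keep_fits) out$fits <- fits
  out
}

#' Derive per-participant seeds from the master seed
#'
#' @param seed master seed.
#' @param n number of participants.
#' @return Integer vector of `n` distinct seeds.
#' @export
participant_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Run the pipeline over a synthetic cohort
#'
#' Runs [run_participant()] for `n_participants` deterministic seeds derived
#' from the master seed and aggregates the per-participant scores into the
#' cohort report (mean and SEM of MSPE and R2 per regressor x interpolation
#' cell, plus the per-survey absolute error profile of the best cell).
#'
#' @param config a [run_config()].
#' @param progress print one line per participant to stderr.
#' @return List with `results` (all per-participant rows) and `report` (the
#'   [aggregate_results()] report).
#' @export
run_cohort <- function(config, progress = interactive()) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_participants < 1) stop("cohort size must be >= 1")
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- participant_seeds(config$seed, config$n_participants)
  all_res <- vector("list", config$n_participants)
  for (i in seq_along(seeds)) {
    if (progress)
      message(sprintf("participant %d/%d (seed %d)", i, length(seeds),
                      seeds[i]))
    all_res[[i]] <- run_participant(config, seeds[i],
                                    participant_id = i)$results
  }
  results <- do.call(rbind, all_res)
  report <- aggregate_results(results)
  if (!is.null(config$out_dir)) {
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(format_report_table(report),
                     file.path(config$out_dir, "report.csv"),
                     row.names = FALSE)
  }
  list(results = results, report = report)
}
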