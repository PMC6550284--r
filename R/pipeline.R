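#' Assemble a pipeline run configuration
#'
#' Exactly one input source must be given: a \code{\link{synth_config}} for a
#' simulated cohort, or \code{input_dir} pointing at a directory of subject
#' CSVs in the public dataset's dialect.
#'
#' @param output_dir directory for the run's artifacts (created if needed).
#' @param synth a \code{\link{synth_config}}, or \code{NULL}.
#' @param input_dir directory with \code{condition/}, \code{control/} and a
#'   scores table, or \code{NULL}.
#' @param scores path to the scores CSV when \code{input_dir} is used.
#' @param classify,regress \code{\link{model_config}} objects for the two
#'   prediction tasks.
#' @param permutations number of label permutations for the significance test
#'   of the classification kappa (0 disables the test).
#' @param permutation_seed seed for the permutation draws.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(output_dir, synth = NULL, input_dir = NULL,
                       scores = if (!is.null(input_dir))
                         file.path(input_dir, "scores.csv"),
                       classify = model_config("classify"),
                       regress = model_config("regress"),
                       permutations = 0, permutation_seed = 1) {
  if (is.null(synth) == is.null(input_dir))
    stop("exactly one input source required: synth or input_dir")
  if (!is.null(synth)) validate_synth_config(synth)
  stopifnot(inherits(classify, "model_config"), classify$task == "classify",
            inherits(regress, "model_config"), regress$task == "regress",
            permutations >= 0)
  structure(list(output_dir = output_dir, synth = synth,
                 input_dir = input_dir, scores = scores,
                 classify = classify, regress = regress,
                 permutations = as.integer(permutations),
                 permutation_seed = as.integer(permutation_seed)),
            class = "run_config")
}

log_line <- function(con, quiet, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  if (!quiet) message(msg)
}

#' Run the full biomarker pipeline
#'
#' Simulate (or load) the cohort, truncate to the common length, extract the
#' digital-biomarker matrix, run leave-one-subject-out boosted-tree
#' classification of diagnostic group on all subjects and regression of
#' pre-post MADRS change on patients, optionally permutation-test the
#' classification kappa, and write \code{features.tsv}, \code{metrics.json}
#' and \code{run.log} to the output directory. Identical configurations yield
#' byte-identical \code{metrics.json}.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress console progress (the run.log is always written).
#' @return Invisibly, a list with the cohort, features, both fits, any
#'   permutation result, and the metrics list written to JSON.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(logfile), add = TRUE)
  log_line(logfile, quiet, "actibiomark ", as.character(packageVersion("actibiomark")),
           " | R ", R.version$major, ".", R.version$minor,
           " | xgboost ", as.character(packageVersion("xgboost")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  cohort <- stage("input", {
    if (!is.null(config$synth)) {
      log_line(logfile, quiet, "simulating cohort (seed ", config$synth$seed, ", ",
               config$synth$n_patients, " patients + ",
               config$synth$n_controls, " controls, ",
               config$synth$n_minutes, " min)")
      co <- generate_cohort(config$synth)
      write_cohort(co, file.path(config$output_dir, "cohort"))
      co
    } else {
      log_line(logfile, quiet, "loading cohort from ", config$input_dir)
      load_cohort(config$input_dir, config$scores)
    }
  })
  cohort <- stage("truncate", truncate_to_common_length(cohort))
  log_line(logfile, quiet, "common length: ", cohort$common_length, " min")

  features <- stage("features", build_matrix(cohort))
  write_feature_tsv(features, file.path(config$output_dir, "features.tsv"))
  log_line(logfile, quiet, "feature matrix: ", nrow(features$x), " x ",
           ncol(features$x))

  cls <- stage("classify", loocv_boost(features, config$classify))
  log_line(logfile, quiet, sprintf("classification: accuracy %.3f, kappa %.3f",
                            cls$metrics$accuracy, cls$metrics$kappa))

  patients <- subset_patients(features)
  reg <- if (nrow(patients$x) >= 3 && !anyNA(patients$change)) {
    r <- stage("regress", loocv_boost(patients, config$regress))
    log_line(logfile, quiet, sprintf("regression: r %.3f (n = %d)",
                              r$metrics$r, r$metrics$n))
    r
  } else {
    log_line(logfile, quiet, "regression skipped: fewer than 3 patients with scores")
    NULL
  }

  perm <- if (config$permutations > 0) {
    p <- stage("permtest",
               permutation_test(features, config$classify, "kappa",
                                b = config$permutations,
                                seed = config$permutation_seed))
    log_line(logfile, quiet, sprintf("permutation test: p = %.4g (b = %d)",
                              p$p_empirical, p$b))
    p
  } else NULL

  metrics <- list(
    n_subjects = nrow(features$x),
    n_features = ncol(features$x),
    common_length = cohort$common_length,
    classification = cls$metrics[c("positive_class", "tp", "fn", "fp", "tn",
                                   "accuracy", "kappa", "sensitivity",
                                   "specificity", "nir", "nir_pvalue")],
    predictions = list(subject = cls$subjects,
                       observed = cls$observed,
                       predicted = cls$predicted,
                       probability = unname(cls$probability)))
  if (!is.null(reg))
    metrics$regression <- list(r = reg$metrics$r, p = reg$metrics$p,
                               n = reg$metrics$n,
                               predicted = unname(reg$predicted),
                               observed = unname(reg$observed))
  if (!is.null(perm))
    metrics$permutation <- list(statistic = perm$statistic,
                                observed = perm$observed, b = perm$b,
                                p_empirical = perm$p_empirical)

  json <- jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(config$output_dir, "metrics.json"))
  log_line(logfile, quiet, "wrote metrics.json")

  invisible(list(cohort = cohort, features = features, classification = cls,
                 regression = reg, permutation = perm, metrics = metrics))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the configuration objects: an optional \code{synth}
#' section (fields of \code{\link{synth_config}}), or \code{input_dir} /
#' \code{scores}; optional \code{classify} and \code{regress} sections
#' (fields of \code{\link{model_config}}); \code{output_dir};
#' \code{permutations}; \code{permutation_seed}.
#'
#' @param path YAML file path.
#' @param seed optional master seed overriding \code{synth$seed} and the model
#'   seeds (convenience for command-line reruns).
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) {
    if (!is.null(seed)) y$synth$seed <- seed
    do.call(synth_config, y$synth)
  }
  mk <- function(task, section) {
    args <- c(list(task = task), section)
    if (!is.null(seed)) args$seed <- seed
    do.call(model_config, args)
  }
  run_config(output_dir = y$output_dir %||% "actibiomark-run",
             synth = synth,
             input_dir = y$input_dir,
             scores = y$scores %||% (if (!is.null(y$input_dir))
               file.path(y$input_dir, "scores.csv")),
             classify = mk("classify", y$classify),
             regress = mk("regress", y$regress),
             permutations = y$permutations %||% 0,
             permutation_seed = y$permutation_seed %||% (seed %||% 1))
}
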