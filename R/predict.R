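#' Boosted-tree model configuration
#'
#' Hyperparameters for the gradient-boosted tree ensembles fit inside
#' leave-one-subject-out cross-validation. Defaults favour stability in the
#' small-n / high-p regime typical of cohort actigraphy studies: shallow
#' trees, shrinkage, an L2 penalty, and row subsampling.
#'
#' @param task \code{"classify"} (diagnostic group) or \code{"regress"}
#'   (pre-post MADRS change).
#' @param rounds boosting rounds (default 200).
#' @param max_depth maximum tree depth (default 3).
#' @param learning_rate shrinkage per round, > 0 (default 0.1).
#' @param l2_penalty L2 regularization on leaf weights (default 1).
#' @param subsample row subsampling fraction per round, in (0, 1]
#'   (default 0.8).
#' @param seed integer base seed; fold i uses \code{seed + i} so every fold's
#'   fit is reproducible in isolation.
#' @return A validated list of class \code{model_config}.
#' @export
model_config <- function(task = c("classify", "regress"), rounds = 200,
                         max_depth = 3, learning_rate = 0.1, l2_penalty = 1.0,
                         subsample = 0.8, seed = 1) {
  task <- match.arg(task)
  if (rounds < 1) stop("rounds must be at least 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (subsample <= 0 || subsample > 1) stop("subsample must lie in (0, 1]")
  if (max_depth < 1) stop("max_depth must be at least 1")
  if (l2_penalty < 0) stop("l2_penalty must be non-negative")
  structure(list(task = task, rounds = as.integer(rounds),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, l2_penalty = l2_penalty,
                 subsample = subsample, seed = as.integer(seed)),
            class = "model_config")
}

xgb_params <- function(config) {
  list(objective = if (config$task == "classify") "binary:logistic"
                   else "reg:squarederror",
       max_depth = config$max_depth,
       eta = config$learning_rate,
       lambda = config$l2_penalty,
       subsample = config$subsample,
       nthread = 1)
}

fit_fold <- function(x_train, y_train, x_test, config, fold_seed) {
  set.seed(fold_seed)
  booster <- xgboost::xgb.train(
    params = xgb_params(config),
    data = xgboost::xgb.DMatrix(x_train, label = y_train),
    nrounds = config$rounds, verbose = 0)
  predict(booster, xgboost::xgb.DMatrix(x_test))
}

#' Leave-one-subject-out boosted-tree prediction
#'
#' For each subject, a fresh gradient-boosted tree ensemble is fit on the
#' remaining subjects and applied to the held-out row, so no subject ever
#' contributes to its own prediction. Classification predicts the diagnostic
#' group from all subjects; regression predicts the pre-post MADRS change and
#' is run on a patient-only matrix (see \code{\link{subset_patients}}).
#'
#' Class probabilities are converted to labels with the deterministic rule
#' that a probability of exactly 0.5 goes to the positive class.
#'
#' @param features an \code{\link{acti_features}} object with at least 3
#'   subjects. For \code{task = "classify"} both groups must have at least two
#'   members (otherwise some training fold would contain a single class); for
#'   \code{task = "regress"} every row needs an observed change score.
#' @param config a \code{\link{model_config}}.
#' @param positive_class reference class for probabilities, tie-breaks and
#'   downstream metrics (default \code{"control"}).
#' @return An object of class \code{acti_loocv} with the per-subject
#'   predictions, the observed outcomes and task metrics
#'   (\code{\link{classification_metrics}} or
#'   \code{\link{regression_metrics}}).
#' @seealso \code{\link{permutation_test}} for significance of the resulting
#'   statistic under outcome shuffling.
#' @export
loocv_boost <- function(features, config = model_config(),
                        positive_class = "control") {
  stopifnot(inherits(features, "acti_features"),
            inherits(config, "model_config"))
  n <- nrow(features$x)
  if (n < 3L) stop("leave-one-out prediction needs at least 3 subjects")

  if (config$task == "classify") {
    counts <- table(factor(features$group, c("control", "patient")))
    if (any(counts == 0)) stop("classification needs both classes present")
    if (any(counts < 2))
      stop("each class needs at least 2 subjects, otherwise a training fold ",
           "would contain a single class")
    y <- as.numeric(features$group == positive_class)
  } else {
    if (anyNA(features$change))
      stop("regression needs an observed change score for every subject ",
           "(use subset_patients)")
    y <- features$change
  }

  raw <- vapply(seq_len(n), function(i) {
    fit_fold(features$x[-i, , drop = FALSE], y[-i],
             features$x[i, , drop = FALSE], config,
             fold_seed = config$seed + i)
  }, numeric(1))

  other <- setdiff(c("control", "patient"), positive_class)
  if (config$task == "classify") {
    predicted <- ifelse(raw >= 0.5, positive_class, other)
    metrics <- classification_metrics(predicted, features$group,
                                      positive_class = positive_class)
  } else {
    predicted <- raw
    metrics <- regression_metrics(predicted, y)
  }

  structure(list(task = config$task, subjects = features$subjects,
                 predicted = predicted, probability = if (config$task ==
                   "classify") stats::setNames(raw, features$subjects),
                 observed = if (config$task == "classify") features$group else y,
                 positive_class = if (config$task == "classify") positive_class,
                 metrics = metrics, config = config, n = n),
            class = "acti_loocv")
}

#' Confusion matrix and agreement metrics for group prediction
#'
#' Builds the 2x2 confusion matrix for a designated positive class and reports
#' accuracy, Cohen's kappa (chance-corrected agreement computed from the
#' row/column marginals), sensitivity, specificity, the no-information rate
#' (the largest observed class proportion), and a one-sided exact binomial
#' p-value for accuracy exceeding the no-information rate,
#' \code{P(X >= correct | n, nir)}.
#'
#' @param predicted,observed equal-length vectors of \code{"patient"} /
#'   \code{"control"} labels.
#' @param positive_class the class counted as positive (default
#'   \code{"control"}).
#' @return Object of class \code{acti_classmetrics}: confusion counts
#'   (\code{tp}, \code{fn}, \code{fp}, \code{tn}) plus \code{accuracy},
#'   \code{kappa}, \code{sensitivity}, \code{specificity}, \code{nir},
#'   \code{nir_pvalue}.
#' @export
classification_metrics <- function(predicted, observed,
                                   positive_class = "control") {
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  valid <- c("patient", "control")
  if (!all(c(predicted, observed) %in% valid))
    stop("unknown label: ",
         paste(setdiff(unique(c(predicted, observed)), valid), collapse = ", "))
  if (!positive_class %in% valid) stop("unknown positive class")
  other <- setdiff(valid, positive_class)

  n <- length(observed)
  tp <- sum(predicted == positive_class & observed == positive_class)
  fn <- sum(predicted == other & observed == positive_class)
  fp <- sum(predicted == positive_class & observed == other)
  tn <- sum(predicted == other & observed == other)

  p_o <- (tp + tn) / n
  # expected agreement from marginal products
  p_e <- ((tp + fn) / n) * ((tp + fp) / n) + ((fp + tn) / n) * ((fn + tn) / n)
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)

  nir <- max(table(factor(observed, valid))) / n
  nir_p <- stats::binom.test(tp + tn, n, p = nir,
                             alternative = "greater")$p.value

  structure(list(positive_class = positive_class,
                 tp = tp, fn = fn, fp = fp, tn = tn, n = n,
                 accuracy = p_o, kappa = kappa,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
                 nir = nir, nir_pvalue = nir_p),
            class = "acti_classmetrics")
}

#' Correlation metrics for predicted vs observed symptom change
#'
#' Pearson correlation between predicted and observed change scores with a
#' two-sided p-value from the t transform \code{t = r sqrt(n - 2) /
#' sqrt(1 - r^2)} on \code{n - 2} degrees of freedom. Both vectors are also
#' returned sample-standardized (z-scores) for plotting.
#'
#' @param predicted,observed equal-length numeric vectors, n >= 3, each with
#'   positive variance.
#' @return Object of class \code{acti_regmetrics}: \code{r}, \code{p},
#'   \code{n}, \code{predicted_z}, \code{observed_z}.
#' @export
regression_metrics <- function(predicted, observed) {
  predicted <- as.numeric(predicted)
  observed <- as.numeric(observed)
  n <- length(observed)
  if (length(predicted) != n) stop("predicted and observed must match in length")
  if (n < 3L) stop("correlation needs at least 3 pairs")
  if (!all(is.finite(predicted)) || !all(is.finite(observed)))
    stop("non-finite values in change scores")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop("zero variance: correlation undefined")

  r <- cor(predicted, observed)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n - 2)
  }
  z <- function(v) (v - mean(v)) / sd(v)
  structure(list(r = r, p = p, n = n,
                 predicted_z = z(predicted), observed_z = z(observed)),
            class = "acti_regmetrics")
}

#' Sample-standardized pre-post difference scores
#'
#' Change is evaluated as \code{pre - post} (positive = improvement), centered
#' and scaled to unit sample variance.
#'
#' @param scores_pre,scores_post equal-length numeric vectors, n >= 2.
#' @return Numeric vector of z-scored change values.
#' @export
standardize_change <- function(scores_pre, scores_post) {
  if (length(scores_pre) != length(scores_post))
    stop("pre and post scores must match in length")
  if (length(scores_pre) < 2L) stop("standardization needs at least 2 subjects")
  d <- scores_pre - scores_post
  s <- sd(d)
  if (s == 0) stop("zero variance in change scores: cannot standardize")
  (d - mean(d)) / s
}

#' Permutation test of a cross-validated prediction statistic
#'
#' Shuffles the outcome column (group labels for \code{kappa}/\code{accuracy},
#' change scores for \code{pearson_r}) \code{b} times and re-runs the full
#' leave-one-out boosted-tree pipeline on each shuffled copy, so the null
#' distribution reflects the entire fitting procedure and the empirical
#' p-value controls for overfitting:
#' \code{p = (1 + #\{null >= observed\}) / (b + 1)}.
#'
#' @param features an \code{\link{acti_features}} object.
#' @param config a \code{\link{model_config}} whose task matches the
#'   statistic.
#' @param statistic \code{"kappa"}, \code{"accuracy"} (classification) or
#'   \code{"pearson_r"} (regression).
#' @param b number of permutations, >= 1.
#' @param seed integer seed for the permutation draws (independent of the
#'   model-fitting seeds in \code{config}).
#' @param positive_class passed to \code{\link{loocv_boost}}.
#' @return Object of class \code{acti_permutation}: \code{observed},
#'   \code{null_draws}, \code{b}, \code{p_empirical}, \code{seed},
#'   \code{statistic}.
#' @export
permutation_test <- function(features, config, statistic = c("kappa",
                             "accuracy", "pearson_r"), b = 99, seed = 1,
                             positive_class = "control") {
  statistic <- match.arg(statistic)
  stopifnot(inherits(features, "acti_features"),
            inherits(config, "model_config"))
  if (b < 1) stop("b must be at least 1")
  needed <- if (statistic == "pearson_r") "regress" else "classify"
  if (config$task != needed)
    stop("statistic '", statistic, "' requires task '", needed, "'")

  stat_of <- function(f) {
    fit <- loocv_boost(f, config, positive_class = positive_class)
    switch(statistic,
           kappa = fit$metrics$kappa,
           accuracy = fit$metrics$accuracy,
           pearson_r = fit$metrics$r)
  }

  observed <- stat_of(features)
  null_draws <- vapply(seq_len(b), function(j) {
    set.seed(mix_seed(seed, j))
    perm <- sample.int(nrow(features$x))
    f <- features
    if (needed == "classify") f$group <- f$group[perm]
    else f$change <- f$change[perm]
    stat_of(f)
  }, numeric(1))

  structure(list(observed = observed, null_draws = null_draws,
                 b = as.integer(b),
                 p_empirical = (1 + sum(null_draws >= observed)) / (b + 1),
                 seed = as.integer(seed), statistic = statistic),
            class = "acti_permutation")
}
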