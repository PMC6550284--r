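#' @export
print.acti_classmetrics <- function(x, ...) {
  other <- setdiff(c("patient", "control"), x$positive_class)
  cat("Confusion matrix (positive class: ", x$positive_class, ")\n", sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c(x$positive_class, other),
                              observed = c(x$positive_class, other)))
  print(t(m))
  cat(sprintf("\nAccuracy     %.3f   (NIR %.3f, exact binomial p = %.3g)\n",
              x$accuracy, x$nir, x$nir_pvalue))
  cat(sprintf("Kappa        %.3f\nSensitivity  %.3f\nSpecificity  %.3f\n",
              x$kappa, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.acti_regmetrics <- function(x, ...) {
  cat(sprintf("Predicted vs observed change: r = %.3f, p = %.3g (n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' @export
print.acti_loocv <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out boosted trees (%s, n = %d, %d rounds)\n\n",
              x$task, x$n, x$config$rounds))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.acti_loocv <- function(object, ...) {
  print(object)
  cat("\nPer-subject predictions:\n")
  df <- data.frame(subject = object$subjects,
                   observed = object$observed,
                   predicted = object$predicted)
  if (object$task == "classify")
    df$probability <- round(unname(object$probability), 3)
  print(df, row.names = FALSE)
  invisible(df)
}

#' @export
fitted.acti_loocv <- function(object, ...) {
  stats::setNames(object$predicted, object$subjects)
}

#' Residuals of a leave-one-out regression fit
#'
#' Observed minus predicted change scores; defined for the regression task
#' only.
#'
#' @param object an \code{acti_loocv} fit with \code{task = "regress"}.
#' @param ... unused.
#' @export
residuals.acti_loocv <- function(object, ...) {
  if (object$task != "regress")
    stop("residuals are defined for the regression task only")
  stats::setNames(object$observed - object$predicted, object$subjects)
}

#' Plot a leave-one-out fit
#'
#' For regression, plots sample-standardized predicted against observed change
#' scores with the identity line. For classification, plots the held-out
#' positive-class probability per subject, colored by observed group, with the
#' 0.5 decision threshold.
#'
#' @param x an \code{acti_loocv} fit.
#' @param ... passed to the underlying plot call.
#' @export
plot.acti_loocv <- function(x, ...) {
  if (x$task == "regress") {
    m <- x$metrics
    plot(m$observed_z, m$predicted_z,
         xlab = "Observed change (z)", ylab = "Predicted change (z)",
         main = sprintf("Predicted vs observed symptom change (r = %.2f)", m$r),
         pch = 19, ...)
    abline(0, 1, lty = 2)
  } else {
    grp <- factor(x$observed, c("control", "patient"))
    plot(seq_len(x$n), x$probability, col = c("#1b6ca8", "#c0392b")[grp],
         pch = 19, xlab = "Subject", ylim = c(0, 1),
         ylab = sprintf("P(%s)", x$positive_class),
         main = sprintf("Held-out class probabilities (kappa = %.2f)",
                        x$metrics$kappa), ...)
    abline(h = 0.5, lty = 2)
    legend("right", legend = levels(grp), col = c("#1b6ca8", "#c0392b"),
           pch = 19, bty = "n")
  }
  invisible(x)
}

#' @export
print.acti_permutation <- function(x, ...) {
  cat(sprintf("Permutation test of %s: observed %.3f\n", x$statistic,
              x$observed))
  cat(sprintf("  %d shuffled re-runs; null range [%.3f, %.3f]\n", x$b,
              min(x$null_draws), max(x$null_draws)))
  cat(sprintf("  empirical p = %.4g\n", x$p_empirical))
  invisible(x)
}
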