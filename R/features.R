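#' Smallest 5-smooth padded length
#'
#' Returns the smallest integer \code{>= n} whose prime factors are all at
#' most 5. Padding the series to such a length keeps the discrete Fourier
#' transform fast and fixes the spectral feature grid; at the study length of
#' 19,299 minutes the padded length is 19,440 and the spectral family has
#' 9,720 bins.
#'
#' @param n positive integer.
#' @return The padded length, an integer.
#' @examples
#' pad_length(19299) # 19440
#' pad_length(1440)  # already 5-smooth
#' @export
pad_length <- function(n) {
  stopifnot(n >= 1)
  m <- as.integer(n)
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

#' Movement-intensity distribution features
#'
#' Seven summary statistics (minimum, maximum, mean, median, mode, skewness,
#' kurtosis) plus the 1st-99th percent quantiles of the per-minute activity
#' counts, 106 values in all. Quantiles use linear interpolation between order
#' statistics. Skewness is \code{m3 / m2^1.5} and kurtosis is excess kurtosis
#' \code{m4 / m2^2 - 3} (both defined as 0 for zero-variance input). The mode
#' is the most frequent value after rounding to the nearest integer, ties
#' resolved to the smallest value.
#'
#' @param series an \code{\link{actigraphy_series}} or numeric vector,
#'   length >= 2.
#' @return Named numeric vector of 106 features (\code{dist.*}).
#' @export
distribution_features <- function(series) {
  x <- series_values(series)
  n <- length(x)
  if (n < 2L) stop("distribution features need at least 2 observations")

  m <- mean(x)
  cx <- x - m
  m2 <- mean(cx^2)
  skew <- if (m2 > 0) mean(cx^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cx^4) / m2^2 - 3 else 0

  tab <- table(round(x))
  vals <- as.numeric(names(tab))
  mode_val <- min(vals[tab == max(tab)])

  q <- quantile(x, probs = (1:99) / 100, names = FALSE, type = 7)
  out <- c(min(x), max(x), m, stats::median(x), mode_val, skew, kurt, q)
  names(out) <- c("dist.min", "dist.max", "dist.mean", "dist.median",
                  "dist.mode", "dist.skewness", "dist.kurtosis",
                  paste0("dist.q", 1:99))
  out
}

#' Movement-intensity variability features
#'
#' Root mean square of successive differences at lags one and two minutes --
#' an index of sharp short-interval shifts in movement -- plus the sample
#' standard deviation (denominator n - 1).
#'
#' @param series an \code{\link{actigraphy_series}} or numeric vector,
#'   length >= 3.
#' @return Named numeric vector \code{var.rmssd_lag1}, \code{var.rmssd_lag2},
#'   \code{var.sd}.
#' @export
variability_features <- function(series) {
  x <- series_values(series)
  if (length(x) < 3L) stop("variability features need at least 3 observations")
  rmssd <- function(k) sqrt(mean(diff(x, lag = k)^2))
  c(var.rmssd_lag1 = rmssd(1L), var.rmssd_lag2 = rmssd(2L), var.sd = sd(x))
}

#' Smoothed autoregressive-lag features
#'
#' The consistency of movement 1 to \code{max_lag} minutes later, as a smooth
#' continuum over the lag axis: the sample autocorrelation function
#' (mean-centered, normalized by the lag-0 sum of squares) at integer lags
#' 1..\code{max_lag}, smoothed with a cubic smoothing spline whose smoothing
#' parameter is chosen by generalized cross-validation, evaluated back at the
#' integer lags. A zero-variance series yields all zeros.
#'
#' @param series an \code{\link{actigraphy_series}} or numeric vector of
#'   length >= \code{max_lag + 1}.
#' @param max_lag largest lag in minutes (default 100).
#' @return Named numeric vector \code{ar.lag1} .. \code{ar.lag<max_lag>}.
#' @export
autoregressive_features <- function(series, max_lag = 100L) {
  x <- series_values(series)
  max_lag <- as.integer(max_lag)
  if (length(x) < max_lag + 1L)
    stop("autoregressive features need at least max_lag + 1 observations")
  nm <- paste0("ar.lag", seq_len(max_lag))
  if (stats::sd(x) == 0)
    return(stats::setNames(numeric(max_lag), nm))
  r <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)[-1L]
  fit <- smooth.spline(seq_len(max_lag), r)   # GCV by default
  stats::setNames(predict(fit, seq_len(max_lag))$y, nm)
}

#' Periodogram spectral-density features
#'
#' The raw periodogram of the mean-removed series, zero-padded to the smallest
#' 5-smooth length \code{P = pad_length(N)}:
#' \code{I(f_k) = |DFT(x)_k|^2 / N} at the Fourier frequencies \code{k / P}
#' for \code{k = 1 .. floor(P / 2)} (the zero frequency is excluded; the
#' Nyquist bin is included when \code{P} is even). Feature names encode the
#' frequency index. For a 19,299-minute series this yields 9,720 bins.
#'
#' Parseval's identity holds in the padded form: the conjugate-symmetry
#' weighted bin sum equals \code{(P / N) * sum((x - mean(x))^2)}.
#'
#' @param series an \code{\link{actigraphy_series}} or numeric vector,
#'   length >= 2.
#' @return Named numeric vector of \code{floor(pad_length(N) / 2)} features
#'   (\code{spec.f000001}, ...).
#' @export
spectral_features <- function(series) {
  x <- series_values(series)
  n <- length(x)
  if (n < 2L) stop("spectral features need at least 2 observations")
  p <- pad_length(n)
  xc <- c(x - mean(x), numeric(p - n))
  d <- fft(xc)
  k <- seq_len(p %/% 2L)
  I <- Mod(d[k + 1L])^2 / n
  stats::setNames(I, sprintf("spec.f%06d", k))
}

#' Extract the full digital-biomarker vector for one series
#'
#' Concatenates the four feature families in fixed order: distribution (106),
#' variability (3), autoregressive lags (100), spectral densities
#' (\code{floor(pad_length(N) / 2)}). For the study length of 19,299 minutes
#' this gives 106 + 3 + 100 + 9,720 = 9,929 features. Every feature depends
#' only on relative time within the series, so the vector is invariant to the
#' recording's absolute start time.
#'
#' @param series an \code{\link{actigraphy_series}} or numeric vector of
#'   length >= 201.
#' @return Named numeric vector with attribute \code{source_length}.
#' @export
extract_features <- function(series) {
  x <- series_values(series)
  if (length(x) < 201L)
    stop("feature extraction needs at least 201 minutes of data")
  out <- c(distribution_features(x), variability_features(x),
           autoregressive_features(x), spectral_features(x))
  attr(out, "source_length") <- length(x)
  out
}

#' Feature-name registry
#'
#' Enumerates every feature name produced for a series of length \code{n},
#' with its family and a short description -- the stable column contract of
#' \code{\link{build_matrix}} and the feature TSV.
#'
#' @param n series length in minutes (default 19299).
#' @return data.frame with columns \code{name}, \code{family},
#'   \code{description}.
#' @export
feature_registry <- function(n = 19299) {
  p <- pad_length(n)
  rbind(
    data.frame(name = c("dist.min", "dist.max", "dist.mean", "dist.median",
                        "dist.mode", "dist.skewness", "dist.kurtosis",
                        paste0("dist.q", 1:99)),
               family = "distribution",
               description = c("minimum count", "maximum count", "mean count",
                               "median count",
                               "modal count (integer-rounded, smallest tie)",
                               "moment skewness", "excess kurtosis",
                               paste0(1:99, "% quantile (linear interpolation)"))),
    data.frame(name = c("var.rmssd_lag1", "var.rmssd_lag2", "var.sd"),
               family = "variability",
               description = c("RMSSD of counts 1 min apart",
                               "RMSSD of counts 2 min apart",
                               "sample standard deviation")),
    data.frame(name = paste0("ar.lag", 1:100),
               family = "autoregressive",
               description = paste0("GCV-spline-smoothed autocorrelation at lag ",
                                    1:100, " min")),
    data.frame(name = sprintf("spec.f%06d", seq_len(p %/% 2)),
               family = "spectral",
               description = sprintf("periodogram at frequency %d/%d cycles/min",
                                     seq_len(p %/% 2), p)))
}

#' Construct a feature matrix container
#'
#' @param x numeric matrix, one row per subject, stable feature columns.
#' @param group character/factor of \code{"patient"}/\code{"control"} labels.
#' @param change numeric vector of pre-post MADRS change scores (\code{NA} for
#'   controls).
#' @param source_length series length the rows were derived from.
#' @return Object of class \code{acti_features} with elements \code{subjects},
#'   \code{x}, \code{group}, \code{change}, \code{source_length}.
#' @export
acti_features <- function(x, group, change = rep(NA_real_, nrow(x)),
                          source_length = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (is.null(rownames(x))) stop("feature matrix needs subject-id rownames")
  group <- as.character(group)
  if (length(group) != nrow(x) || !all(group %in% c("patient", "control")))
    stop("group must give 'patient'/'control' for every row")
  if (length(change) != nrow(x))
    stop("change must have one entry per row")
  if (anyNA(x)) stop("feature matrix contains missing values")
  structure(list(subjects = rownames(x), x = x, group = group,
                 change = as.numeric(change),
                 source_length = source_length),
            class = "acti_features")
}

#' @export
print.acti_features <- function(x, ...) {
  cat(sprintf("<acti_features> %d subjects x %d features", nrow(x$x), ncol(x$x)))
  if (!is.null(x$source_length))
    cat(sprintf(" (from %d-min series)", x$source_length))
  cat(sprintf("\n  %d patients / %d controls; MADRS change for %d subjects\n",
              sum(x$group == "patient"), sum(x$group == "control"),
              sum(!is.na(x$change))))
  invisible(x)
}

#' @export
dim.acti_features <- function(x) dim(x$x)

#' Build the cohort feature matrix
#'
#' Extracts the full biomarker vector for each subject of a length-truncated
#' cohort and stacks them in cohort order with the group labels and, for
#' patients, the pre-post MADRS change (\code{madrs_pre - madrs_post};
#' positive change = improvement).
#'
#' @param cohort an \code{\link{acti_cohort}} that has been through
#'   \code{\link{truncate_to_common_length}} (identical \code{source_length}
#'   across rows is required for a rectangular matrix, so an untruncated
#'   cohort is an error).
#' @return An \code{\link{acti_features}} object.
#' @export
build_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "acti_cohort"))
  if (is.null(cohort$common_length))
    stop("cohort must be truncated to a common length first ",
         "(see truncate_to_common_length)")
  rows <- lapply(cohort$records, function(r) extract_features(r$series))
  x <- do.call(rbind, rows)
  rownames(x) <- cohort_ids(cohort)
  change <- vapply(cohort$records, function(r) {
    if (is.null(r$madrs_pre)) NA_real_ else r$madrs_pre - r$madrs_post
  }, numeric(1))
  acti_features(x, group = cohort_groups(cohort), change = change,
                source_length = cohort$common_length)
}

#' Restrict a feature matrix to patients
#'
#' Symptom-change regression is defined for patients only (controls carry no
#' MADRS scores), so the regression task runs on this subset.
#'
#' @param features an \code{\link{acti_features}} object.
#' @return The patient-only \code{acti_features}.
#' @export
subset_patients <- function(features) {
  stopifnot(inherits(features, "acti_features"))
  keep <- features$group == "patient"
  if (!any(keep)) stop("no patients in feature matrix")
  acti_features(features$x[keep, , drop = FALSE],
                group = features$group[keep],
                change = features$change[keep],
                source_length = features$source_length)
}
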