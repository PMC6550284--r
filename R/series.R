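#' Construct a minute-level actigraphy series
#'
#' One subject's equally spaced per-minute activity counts with a start time.
#' The sampling interval is fixed at one minute; values must be non-negative
#' and gap-free (the CSV loader enforces this on disk data).
#'
#' @param values numeric vector of non-negative activity counts, one per minute.
#' @param start_time \code{POSIXct} timestamp of the first minute (minute
#'   resolution; seconds are ignored by all downstream features, which use
#'   relative time only).
#' @param subject_id character scalar identifying the subject.
#' @return An object of class \code{actigraphy_series}: a list with elements
#'   \code{subject_id}, \code{start_time}, \code{values}.
#' @examples
#' s <- actigraphy_series(c(10, 0, 35), as.POSIXct("2004-05-01", tz = "UTC"), "control_1")
#' length(s)
#' @export
actigraphy_series <- function(values, start_time, subject_id = "subject") {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("actigraphy series must contain at least one value")
  if (anyNA(values))
    stop("actigraphy series contains missing values")
  if (any(values < 0))
    stop("activity counts must be non-negative (first offending index: ",
         which(values < 0)[1L], ")")
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L)
    stop("start_time must be a single POSIXct timestamp")
  structure(
    list(subject_id = as.character(subject_id),
         start_time = start_time,
         values = values),
    class = "actigraphy_series")
}

#' @export
length.actigraphy_series <- function(x) length(x$values)

#' @export
print.actigraphy_series <- function(x, ...) {
  v <- x$values
  cat(sprintf("<actigraphy_series> %s: %d min from %s\n", x$subject_id,
              length(v), format(x$start_time, "%Y-%m-%d %H:%M")))
  cat(sprintf("  counts: mean %.1f, sd %.1f, range [%g, %g], %.1f%% zero\n",
              mean(v), stats::sd(v), min(v), max(v), 100 * mean(v == 0)))
  invisible(x)
}

# accept either a series object or a bare numeric vector in feature extractors
series_values <- function(x) {
  if (inherits(x, "actigraphy_series")) x$values else as.numeric(x)
}

#' Construct a subject record
#'
#' Bundles a series with its diagnostic group and, for patients, pre/post
#' MADRS depression scores. Controls never carry MADRS scores (the scale is
#' administered to patients only).
#'
#' @param series an \code{\link{actigraphy_series}}.
#' @param group \code{"patient"} or \code{"control"}.
#' @param madrs_pre,madrs_post numeric MADRS scores, or \code{NULL}; allowed
#'   (and required together) only when \code{group == "patient"}.
#' @return An object of class \code{subject_record}.
#' @export
subject_record <- function(series, group, madrs_pre = NULL, madrs_post = NULL) {
  group <- match.arg(group, c("patient", "control"))
  if (!inherits(series, "actigraphy_series"))
    stop("series must be an actigraphy_series")
  if (group == "control" && (!is.null(madrs_pre) || !is.null(madrs_post)))
    stop("controls cannot carry MADRS scores")
  if (group == "patient" && (is.null(madrs_pre) != is.null(madrs_post)))
    stop("patients need both or neither MADRS score")
  structure(
    list(subject_id = series$subject_id, group = group, series = series,
         madrs_pre = madrs_pre, madrs_post = madrs_post),
    class = "subject_record")
}

#' Construct a cohort of subject records
#'
#' @param records list of \code{\link{subject_record}} objects with unique ids.
#' @param common_length integer or \code{NULL}; set by
#'   \code{\link{truncate_to_common_length}} once all series share a length.
#' @return An object of class \code{acti_cohort}.
#' @export
acti_cohort <- function(records, common_length = NULL) {
  if (!length(records)) stop("cohort must contain at least one subject")
  ok <- vapply(records, inherits, logical(1), "subject_record")
  if (!all(ok)) stop("all records must be subject_record objects")
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(common_length)) {
    lens <- vapply(records, function(r) length(r$series), integer(1))
    if (!all(lens == common_length))
      stop("common_length does not match all series lengths")
  }
  structure(list(records = records, common_length = common_length),
            class = "acti_cohort")
}

#' @export
length.acti_cohort <- function(x) length(x$records)

#' @export
print.acti_cohort <- function(x, ...) {
  grp <- vapply(x$records, `[[`, character(1), "group")
  cat(sprintf("<acti_cohort> %d subjects (%d patients, %d controls)\n",
              length(x$records), sum(grp == "patient"), sum(grp == "control")))
  if (is.null(x$common_length)) {
    lens <- vapply(x$records, function(r) length(r$series), integer(1))
    cat(sprintf("  series lengths %d..%d min (not yet truncated)\n",
                min(lens), max(lens)))
  } else {
    cat(sprintf("  common length: %d min\n", x$common_length))
  }
  invisible(x)
}

cohort_groups <- function(cohort)
  vapply(cohort$records, `[[`, character(1), "group")

cohort_ids <- function(cohort)
  vapply(cohort$records, `[[`, character(1), "subject_id")
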