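#' Read one subject's actigraphy CSV
#'
#' Expects the public dataset's dialect: header columns \code{timestamp}
#' (\code{YYYY-MM-DD HH:MM:SS}), \code{date} (\code{YYYY-MM-DD}) and
#' \code{activity} (non-negative number), rows in time order at exactly one
#' row per minute. The subject id is taken from the file stem
#' (\code{condition_12.csv} -> \code{condition_12}).
#'
#' @param path path to the CSV file.
#' @return An \code{\link{actigraphy_series}}.
#' @export
read_subject_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("timestamp", "date", "activity"))
    if (!col %in% names(df))
      stop("'", path, "': missing required column '", col, "'")
  if (nrow(df) < 1L) stop("'", path, "': no data rows")

  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  if (anyNA(ts))
    stop("'", path, "': unparseable timestamp at row ", which(is.na(ts))[1L])
  act <- suppressWarnings(as.numeric(df$activity))
  if (anyNA(act))
    stop("'", path, "': non-numeric activity at row ", which(is.na(act))[1L])
  if (any(act < 0))
    stop("'", path, "': negative activity at row ", which(act < 0)[1L])
  if (nrow(df) > 1L) {
    gaps <- as.numeric(diff(ts), units = "secs")
    bad <- which(gaps != 60)
    if (length(bad))
      stop("'", path, "': timestamps must advance by exactly 60 s; ",
           "violation at row ", bad[1L] + 1L,
           " (step of ", gaps[bad[1L]], " s)")
  }
  id <- sub("\\.[^.]*$", "", basename(path))
  actigraphy_series(act, ts[1L], id)
}

#' Write one subject's actigraphy CSV
#'
#' Emits exactly the dialect \code{\link{read_subject_csv}} accepts, with
#' timestamps advancing by 60 seconds per row.
#'
#' @param series an \code{\link{actigraphy_series}} of length >= 1.
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
write_subject_csv <- function(series, path) {
  if (!inherits(series, "actigraphy_series"))
    stop("series must be an actigraphy_series")
  n <- length(series$values)
  if (n < 1L) stop("cannot write an empty series")
  ts <- series$start_time + 60 * (seq_len(n) - 1)
  df <- data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   date = format(ts, "%Y-%m-%d", tz = "UTC"),
                   activity = series$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to disk in the dataset dialect
#'
#' Creates \code{condition/} and \code{control/} subdirectories of per-subject
#' CSVs plus a \code{scores.csv} with columns \code{number}, \code{group},
#' \code{madrs1}, \code{madrs2} (MADRS columns populated for patients only).
#'
#' @param cohort an \code{\link{acti_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "acti_cohort"))
  dir.create(file.path(dir, "condition"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "control"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$records, function(r) {
    sub <- if (r$group == "patient") "condition" else "control"
    write_subject_csv(r$series, file.path(dir, sub, paste0(r$subject_id, ".csv")))
    data.frame(number = r$subject_id, group = r$group,
               madrs1 = r$madrs_pre %||% NA_real_,
               madrs2 = r$madrs_post %||% NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Reads every subject CSV under \code{<dir>/condition} and
#' \code{<dir>/control}, assigning the group from the subdirectory, and
#' attaches MADRS pre/post scores from the scores table to condition subjects.
#' A condition subject without a scores row is an error; MADRS entries for a
#' control are dropped with a warning.
#'
#' @param dir directory holding \code{condition/} and \code{control/}.
#' @param scores path to the scores CSV (columns \code{number}, \code{madrs1},
#'   \code{madrs2}); defaults to \code{scores.csv} inside \code{dir}.
#' @return An \code{\link{acti_cohort}} (not yet length-truncated).
#' @export
load_cohort <- function(dir, scores = file.path(dir, "scores.csv")) {
  cond <- list.files(file.path(dir, "condition"), pattern = "\\.csv$",
                     full.names = TRUE)
  ctrl <- list.files(file.path(dir, "control"), pattern = "\\.csv$",
                     full.names = TRUE)
  if (!length(cond) && !length(ctrl))
    stop("no subjects found under '", dir, "'")
  sc <- if (file.exists(scores))
    utils::read.csv(scores, stringsAsFactors = FALSE) else NULL
  if (!is.null(sc) && !"number" %in% names(sc))
    stop("scores table must contain a 'number' column")

  make_record <- function(path, group) {
    series <- read_subject_csv(path)
    row <- if (!is.null(sc)) sc[sc$number == series$subject_id, , drop = FALSE]
           else NULL
    has_madrs <- !is.null(row) && nrow(row) == 1L &&
      all(c("madrs1", "madrs2") %in% names(row)) &&
      !is.na(row$madrs1) && !is.na(row$madrs2)
    if (group == "patient") {
      if (!has_madrs)
        stop("no MADRS scores found for condition subject '",
             series$subject_id, "'")
      subject_record(series, "patient",
                     madrs_pre = row$madrs1, madrs_post = row$madrs2)
    } else {
      if (has_madrs)
        warning("control subject '", series$subject_id,
                "' has MADRS scores in the scores table; dropped")
      subject_record(series, "control")
    }
  }
  records <- c(lapply(cond, make_record, group = "patient"),
               lapply(ctrl, make_record, group = "control"))
  acti_cohort(records)
}

#' Truncate every series to the cohort-wide minimum length
#'
#' Biomarkers are computed on the minimum number of minutes available for all
#' subjects, so no derived feature can be missing. The earliest minutes are
#' kept, preserving alignment to recording onset. Idempotent.
#'
#' @param cohort an \code{\link{acti_cohort}}.
#' @return The cohort with all series cut to the common length and
#'   \code{common_length} set.
#' @export
truncate_to_common_length <- function(cohort) {
  stopifnot(inherits(cohort, "acti_cohort"))
  lens <- vapply(cohort$records, function(r) length(r$series), integer(1))
  L <- min(lens)
  cohort$records <- lapply(cohort$records, function(r) {
    r$series$values <- r$series$values[seq_len(L)]
    r
  })
  cohort$common_length <- L
  cohort
}

#' Write a feature matrix as TSV
#'
#' One row per subject with \code{subject_id}, \code{group}, an optional
#' \code{madrs_change} column, then the features in their stable order.
#'
#' @param features an \code{\link{acti_features}} object.
#' @param path destination TSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  stopifnot(inherits(features, "acti_features"))
  df <- data.frame(subject_id = features$subjects,
                   group = features$group,
                   madrs_change = features$change,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(features$x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix TSV written by \code{\link{write_feature_tsv}}
#'
#' @param path TSV path.
#' @param source_length series length the features were derived from, if known
#'   (recovered from the spectral feature count when \code{NULL}).
#' @return An \code{\link{acti_features}} object.
#' @export
read_feature_tsv <- function(path, source_length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("subject_id", "group", "madrs_change")
  if (!all(meta %in% names(df)))
    stop("feature TSV must contain columns ", paste(meta, collapse = ", "))
  x <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(x) <- df$subject_id
  acti_features(x, group = df$group, change = df$madrs_change,
                source_length = source_length)
}
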