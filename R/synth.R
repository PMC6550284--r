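#' Configuration for the synthetic actigraphy cohort generator
#'
#' The generator produces minute-level activity counts with the structural
#' features real wrist actigraphy shows: a 1440-minute circadian cycle,
#' near-zero sleep-gated night activity, short-range AR(1) autocorrelation,
#' zero-inflation from clipping at zero, and integer counts from rounding.
#' Patients differ from controls by a multiplicative reduction of mean level
#' and circadian amplitude, and each patient additionally receives a random
#' level shift on the second half of the recording whose standardized value
#' drives the simulated MADRS change (so symptom change is recoverable from
#' the actigraphy itself, independently of diagnostic status).
#'
#' @param n_patients,n_controls subject counts per group.
#' @param n_minutes series length in minutes (default 19299, about 13.4 days).
#'   Must be at least 201 so every feature family is defined.
#' @param seed master integer seed; per-subject seeds are derived by stable
#'   hashing so cohorts are reproducible under reordering.
#' @param control_mean waking mean activity level for controls, counts/min.
#' @param patient_mean_ratio multiplier in (0, 1] applied to the mean for
#'   patients (psychomotor retardation lowers overall activity).
#' @param circadian_amplitude cosine amplitude for controls, counts.
#' @param patient_amplitude_ratio multiplier in (0, 1] applied to the
#'   amplitude for patients (blunted circadian rhythm).
#' @param acrophase_minutes minute-of-day of the activity peak (default 900,
#'   i.e. 15:00).
#' @param ar_coefficient AR(1) coefficient of the waking noise, in [0, 1).
#' @param noise_sd innovation standard deviation of the AR(1) noise, counts.
#' @param sleep_window length-2 vector of minutes-of-day (start, end) of the
#'   sleep gate; wraps around midnight when start > end (default 1380 -> 420,
#'   i.e. 23:00-07:00).
#' @param sleep_activity_rate mean counts/min of the Poisson low-rate regime
#'   while asleep.
#' @param level_shift_sd standard deviation, in counts, of the per-patient
#'   activity level shift applied to the second half of the recording; its
#'   standardized value is the latent driver of MADRS change. Set to 0 for an
#'   exchangeable null cohort.
#' @param madrs_pre_range length-2 numeric range for baseline MADRS scores.
#' @param madrs_change_coupling MADRS points of improvement per standardized
#'   unit of activity-level shift.
#' @param madrs_noise_sd residual sd of the simulated MADRS change, score units.
#' @return A validated list of class \code{synth_config}.
#' @examples
#' cfg <- synth_config(n_patients = 2, n_controls = 3, n_minutes = 1440, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
synth_config <- function(n_patients = 23, n_controls = 32, n_minutes = 19299,
                         seed = 1,
                         control_mean = 220, patient_mean_ratio = 0.6,
                         circadian_amplitude = 180, patient_amplitude_ratio = 0.6,
                         acrophase_minutes = 900,
                         ar_coefficient = 0.6, noise_sd = 80,
                         sleep_window = c(1380, 420), sleep_activity_rate = 5,
                         level_shift_sd = 15,
                         madrs_pre_range = c(18, 30),
                         madrs_change_coupling = 4, madrs_noise_sd = 2) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_minutes = as.integer(n_minutes),
              seed = as.integer(seed),
              control_mean = control_mean,
              patient_mean_ratio = patient_mean_ratio,
              circadian_amplitude = circadian_amplitude,
              patient_amplitude_ratio = patient_amplitude_ratio,
              acrophase_minutes = acrophase_minutes,
              ar_coefficient = ar_coefficient,
              noise_sd = noise_sd,
              sleep_window = as.numeric(sleep_window),
              sleep_activity_rate = sleep_activity_rate,
              level_shift_sd = level_shift_sd,
              madrs_pre_range = as.numeric(madrs_pre_range),
              madrs_change_coupling = madrs_change_coupling,
              madrs_noise_sd = madrs_noise_sd)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients < 0 || cfg$n_controls < 0)
    stop("subject counts must be non-negative")
  if (cfg$n_patients + cfg$n_controls < 1)
    stop("cohort must contain at least one subject")
  if (cfg$n_minutes < 201)
    stop("n_minutes must be at least 201 (longest feature lag + 1 must fit)")
  if (cfg$control_mean <= 0 || cfg$circadian_amplitude < 0)
    stop("control_mean must be positive and circadian_amplitude non-negative")
  for (nm in c("patient_mean_ratio", "patient_amplitude_ratio")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(nm, " must lie in (0, 1]")
  }
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  if (cfg$noise_sd < 0 || cfg$sleep_activity_rate < 0 || cfg$level_shift_sd < 0 ||
      cfg$madrs_noise_sd < 0)
    stop("standard deviations and rates must be non-negative")
  if (length(cfg$sleep_window) != 2L ||
      any(cfg$sleep_window < 0) || any(cfg$sleep_window >= 1440))
    stop("sleep_window must be two minutes-of-day in [0, 1440)")
  if (length(cfg$madrs_pre_range) != 2L ||
      cfg$madrs_pre_range[1] > cfg$madrs_pre_range[2])
    stop("madrs_pre_range must be an increasing interval")
  invisible(cfg)
}

# TRUE for minutes-of-day inside the (possibly midnight-wrapping) sleep window
in_sleep_window <- function(minute_of_day, window) {
  if (window[1] <= window[2])
    minute_of_day >= window[1] & minute_of_day < window[2]
  else
    minute_of_day >= window[1] | minute_of_day < window[2]
}

# deterministic waking-activity template: clipped (at zero) circadian cosine,
# zeroed during sleep, rounded to integer counts
activity_template <- function(cfg, group) {
  mu <- cfg$control_mean * if (group == "patient") cfg$patient_mean_ratio else 1
  amp <- cfg$circadian_amplitude *
    if (group == "patient") cfg$patient_amplitude_ratio else 1
  t <- seq_len(cfg$n_minutes) - 1
  tod <- t %% 1440
  circ <- mu + amp * cos(2 * pi * (t - cfg$acrophase_minutes) / 1440)
  circ[in_sleep_window(tod, cfg$sleep_window)] <- 0
  round(pmax(0, circ))
}

#' Simulate one subject's actigraphy record
#'
#' The waking process is a circadian cosine plus AR(1) noise, clipped at zero
#' and rounded to integer counts; minutes inside the sleep window are replaced
#' by a low-rate Poisson regime. Patients use the reduced mean and amplitude,
#' and an optional level shift is added to the second half of the recording.
#' Output is fully determined by \code{(config$seed, subject_seed)}.
#'
#' @param config a \code{\link{synth_config}}.
#' @param group \code{"patient"} or \code{"control"}.
#' @param subject_seed integer; distinct per subject, hashed with the master
#'   seed.
#' @param level_shift counts added to minutes in the second half of the
#'   recording before gating (used by \code{\link{generate_cohort}} for
#'   patients; default 0).
#' @param madrs_pre,madrs_post optional MADRS scores attached to the record.
#' @param subject_id optional id; defaults to \code{condition_<seed>} /
#'   \code{control_<seed>} in the public dataset's naming style.
#' @return A \code{\link{subject_record}}.
#' @export
generate_subject <- function(config, group, subject_seed, level_shift = 0,
                             madrs_pre = NULL, madrs_post = NULL,
                             subject_id = NULL) {
  validate_synth_config(config)
  if (!is.character(group) || length(group) != 1L ||
      !group %in% c("patient", "control"))
    stop("group must be \"patient\" or \"control\"")
  n <- config$n_minutes
  mu <- config$control_mean *
    if (group == "patient") config$patient_mean_ratio else 1
  amp <- config$circadian_amplitude *
    if (group == "patient") config$patient_amplitude_ratio else 1
  t <- seq_len(n) - 1
  tod <- t %% 1440
  circ <- mu + amp * cos(2 * pi * (t - config$acrophase_minutes) / 1440)
  shift <- ifelse(t >= n / 2, level_shift, 0)

  set.seed(mix_seed(config$seed, subject_seed))
  e <- if (config$noise_sd == 0) {
    numeric(n)
  } else if (config$ar_coefficient == 0) {
    rnorm(n, 0, config$noise_sd)
  } else {
    as.numeric(stats::filter(rnorm(n, 0, config$noise_sd),
                             config$ar_coefficient, method = "recursive"))
  }
  asleep <- in_sleep_window(tod, config$sleep_window)
  night <- if (config$sleep_activity_rate == 0) integer(n)
           else rpois(n, config$sleep_activity_rate)

  x <- round(pmax(0, circ + shift + e))
  x[asleep] <- night[asleep]

  id <- subject_id %||%
    paste0(if (group == "patient") "condition_" else "control_", subject_seed)
  series <- actigraphy_series(x, as.POSIXct("2004-05-01 00:00:00", tz = "UTC"), id)
  subject_record(series, group, madrs_pre = madrs_pre, madrs_post = madrs_post)
}

#' Simulate a full synthetic cohort
#'
#' Generates \code{n_patients + n_controls} subject records with unique ids.
#' Each patient receives a baseline MADRS score drawn uniformly from
#' \code{madrs_pre_range} (rounded to the integer scale) and a follow-up score
#' \code{madrs_post = madrs_pre - coupling * delta_i + noise}, where
#' \code{delta_i} is the patient's standardized simulated activity-level shift
#' between the first and second half of the recording. Positive shifts
#' (increasing activity) therefore translate into symptom improvement, making
#' the change score recoverable from the actigraphy independently of group.
#'
#' @param config a \code{\link{synth_config}}.
#' @return An \code{\link{acti_cohort}}; series lengths all equal
#'   \code{n_minutes} but \code{common_length} is unset until
#'   \code{\link{truncate_to_common_length}} is applied.
#' @export
generate_cohort <- function(config) {
  validate_synth_config(config)
  np <- config$n_patients
  nc <- config$n_controls

  # cohort-level draws (shifts, MADRS) are separate from per-subject series
  # seeds so reordering subjects cannot change any subject's series
  set.seed(mix_seed(config$seed, 0L))
  shifts <- if (np > 0) rnorm(np, 0, config$level_shift_sd) else numeric(0)
  pre <- if (np > 0) round(runif(np, config$madrs_pre_range[1],
                                 config$madrs_pre_range[2])) else numeric(0)
  mnoise <- if (np > 0) rnorm(np, 0, config$madrs_noise_sd) else numeric(0)

  delta <- if (np >= 2 && stats::sd(shifts) > 0)
    (shifts - mean(shifts)) / stats::sd(shifts) else numeric(np)
  post <- pre - config$madrs_change_coupling * delta + mnoise

  records <- vector("list", np + nc)
  for (i in seq_len(np)) {
    records[[i]] <- generate_subject(config, "patient", subject_seed = i,
                                     level_shift = shifts[i],
                                     madrs_pre = pre[i], madrs_post = post[i],
                                     subject_id = paste0("condition_", i))
  }
  for (j in seq_len(nc)) {
    # seeds offset by np so a patient and a control never share noise draws
    records[[np + j]] <- generate_subject(config, "control",
                                          subject_seed = np + j,
                                          subject_id = paste0("control_", j))
  }
  acti_cohort(records)
}
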