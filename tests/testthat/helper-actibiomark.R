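# shared fixtures, all generated in code

# fabricated feature container: one informative column separates the groups,
# the rest is noise; `change` is linear in the informative column for patients
make_fake_features <- function(n_patients = 6, n_controls = 6, p = 8,
                               separation = 10, seed = 42) {
  set.seed(seed)
  n <- n_patients + n_controls
  group <- c(rep("patient", n_patients), rep("control", n_controls))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0(substr(group, 1, 4), "_", seq_len(n)),
                              paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + separation * (group == "patient")
  change <- ifelse(group == "patient", 2 * x[, 2] + rnorm(n, 0, 0.1), NA_real_)
  acti_features(x, group = group, change = change, source_length = 1000L)
}

# small, quick synthetic cohort (n_minutes kept low for unit tests)
small_cohort <- function(n_patients = 3, n_controls = 4, n_minutes = 300,
                         seed = 7, ...) {
  generate_cohort(synth_config(n_patients = n_patients,
                               n_controls = n_controls,
                               n_minutes = n_minutes, seed = seed, ...))
}

# independent 5-smooth oracle: enumerate 2^a * 3^b * 5^c products directly
smooth5_at_least <- function(n, bound = 4L * n) {
  vals <- c()
  a <- 1
  while (a <= bound) {
    b <- a
    while (b <= bound) {
      c <- b
      while (c <= bound) { vals <- c(vals, c); c <- c * 5 }
      b <- b * 3
    }
    a <- a * 2
  }
  min(vals[vals >= n])
}

# deterministic waking template the generator must match in the noise-free case
cosine_template <- function(cfg, group = "control") {
  mu <- cfg$control_mean * if (group == "patient") cfg$patient_mean_ratio else 1
  amp <- cfg$circadian_amplitude *
    if (group == "patient") cfg$patient_amplitude_ratio else 1
  t <- seq_len(cfg$n_minutes) - 1
  tod <- t %% 1440
  asleep <- if (cfg$sleep_window[1] <= cfg$sleep_window[2])
    tod >= cfg$sleep_window[1] & tod < cfg$sleep_window[2]
  else
    tod >= cfg$sleep_window[1] | tod < cfg$sleep_window[2]
  x <- round(pmax(0, mu + amp * cos(2 * pi * (t - cfg$acrophase_minutes) / 1440)))
  x[asleep] <- 0
  x
}

write_lines_csv <- function(lines, path) {
  writeLines(lines, path)
  path
}
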