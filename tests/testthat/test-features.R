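test_that("pad_length matches an independent 5-smooth enumeration", {
  for (n in c(1:60, 97, 101, 719, 721, 1439, 1441, 2047)) {
    expect_identical(pad_length(n), as.integer(smooth5_at_least(n)),
                     info = paste("n =", n))
  }
  expect_identical(pad_length(1440), 1440L)   # 2^5 * 3^2 * 5
  expect_identical(pad_length(19299), 19440L)
})

test_that("distribution features match hand-computed and brute-force values", {
  d <- distribution_features(0:100)
  expect_length(d, 106)
  expect_false(anyDuplicated(names(d)) > 0)
  expect_equal(unname(d["dist.mean"]), 50)
  expect_equal(unname(d["dist.median"]), 50)
  expect_equal(unname(d["dist.q17"]), 17)   # linear-interpolation quantiles
  expect_equal(unname(d["dist.q99"]), 99)
  expect_equal(unname(d["dist.mode"]), 0)   # all tied, smallest wins

  d2 <- distribution_features(c(1, 1, 2, 9))
  expect_equal(unname(d2[c("dist.mode", "dist.max", "dist.mean")]),
               c(1, 9, 3.25))

  const <- distribution_features(rep(7, 50))
  expect_equal(unname(const["dist.skewness"]), 0)
  expect_equal(unname(const["dist.kurtosis"]), 0)
  expect_true(all(const[paste0("dist.q", 1:99)] == 7))
  expect_equal(unname(const[c("dist.min", "dist.max", "dist.mode")]),
               c(7, 7, 7))

  # moment-based skewness/kurtosis against direct formulas on random data
  set.seed(1)
  x <- rpois(500, 30)
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(distribution_features(x)["dist.skewness"]),
               mean((x - mean(x))^3) / m2^1.5, tolerance = 1e-12)
  expect_equal(unname(distribution_features(x)["dist.kurtosis"]),
               mean((x - mean(x))^4) / m2^2 - 3, tolerance = 1e-12)
  expect_error(distribution_features(5), "at least 2")
})

test_that("variability features equal hand-computed RMSSD values", {
  v <- variability_features(c(0, 3, 1, 5))
  expect_equal(unname(v["var.rmssd_lag1"]), sqrt(29 / 3))  # diffs 3,-2,4
  expect_equal(unname(v["var.rmssd_lag2"]), sqrt(5 / 2))   # diffs 1, 2
  expect_equal(unname(v["var.sd"]), sd(c(0, 3, 1, 5)))

  expect_equal(unname(variability_features(rep(4, 10))), c(0, 0, 0))

  alt <- rep(c(2, 9), 10)
  va <- variability_features(alt)
  expect_equal(unname(va["var.rmssd_lag1"]), 7)
  expect_equal(unname(va["var.rmssd_lag2"]), 0)
  expect_error(variability_features(c(1, 2)), "at least 3")
})

test_that("autoregressive features stay near zero for white noise and are bounded", {
  set.seed(4)
  a <- autoregressive_features(rnorm(19299))
  expect_length(a, 100)
  expect_true(all(abs(a) < 0.05))   # ~2/sqrt(n) envelope

  expect_equal(unname(autoregressive_features(rep(3, 500))), numeric(100))
  expect_error(autoregressive_features(rnorm(50)), "at least")

  # smoothing never pushes the lag continuum outside [-1.05, 1.05]
  for (seed in 1:5) {
    set.seed(seed)
    x <- as.numeric(stats::filter(rnorm(400), 0.9, method = "recursive"))
    expect_true(all(abs(autoregressive_features(x)) <= 1.05))
  }
})

test_that("spectral features concentrate a pure cosine and satisfy Parseval", {
  n <- 1440  # already 5-smooth, so Fourier frequencies are exact
  t <- seq_len(n) - 1
  s <- spectral_features(cos(2 * pi * 12 * t / n))
  expect_length(s, 720)
  expect_identical(names(which.max(s)), "spec.f000012")
  expect_gt(s["spec.f000012"], 100 * max(s[-12]))

  # Parseval in padded form: weighted bin sum = (P/N) * centered sum of squares
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(200:2000, 1)
    x <- rgamma(n, 2, 0.01)
    p <- pad_length(n)
    s <- spectral_features(x)
    w <- rep(2, length(s))
    if (p %% 2 == 0) w[length(s)] <- 1   # Nyquist bin is its own conjugate
    expect_equal(sum(w * s), (p / n) * sum((x - mean(x))^2),
                 tolerance = 1e-6)
  }
})

test_that("the assembled vector has the documented size, order and naming", {
  x <- cosine_template(synth_config(n_patients = 0, n_controls = 1,
                                    n_minutes = 1440, seed = 1))
  f <- extract_features(x)
  expect_length(f, 929)  # 106 + 3 + 100 + 720
  expect_false(anyDuplicated(names(f)) > 0)
  expect_false(anyNA(f))
  expect_identical(names(f)[1], "dist.min")
  expect_identical(names(f)[107], "var.rmssd_lag1")
  expect_identical(names(f)[110], "ar.lag1")
  expect_identical(names(f)[210], "spec.f000001")
  expect_identical(attr(f, "source_length"), 1440L)

  # count formula 209 + floor(pad_length(N)/2) at assorted lengths
  for (n in c(201, 250, 720, 1000)) {
    set.seed(n)
    expect_length(extract_features(rpois(n, 20)),
                  209 + pad_length(n) %/% 2)
  }
  expect_error(extract_features(rpois(200, 20)), "201")

  # zero-variance input still yields a fully defined vector
  z <- extract_features(rep(5, 300))
  expect_false(anyNA(z))
  expect_true(all(is.finite(z)))
})

test_that("features use relative time only and scale as documented", {
  cfg <- synth_config(n_patients = 1, n_controls = 1, n_minutes = 400, seed = 2)
  rec <- generate_subject(cfg, "control", 1)
  shifted <- rec$series
  shifted$start_time <- shifted$start_time + 86400 * 30 + 3600
  expect_identical(extract_features(rec$series), extract_features(shifted))

  # scale equivariance audit with an integer factor (the mode is defined on
  # integer-rounded counts, so only integer scalings preserve it exactly)
  x <- rec$series$values
  k <- 3
  f1 <- extract_features(x)
  fk <- extract_features(k * x)
  lin <- c("dist.min", "dist.max", "dist.mean", "dist.median", "dist.mode",
           paste0("dist.q", 1:99), "var.rmssd_lag1", "var.rmssd_lag2", "var.sd")
  expect_equal(unname(fk[lin]), unname(k * f1[lin]), tolerance = 1e-10)
  # GCV re-selects the spline penalty on the rescaled ACF, so the lag
  # continuum is invariant only up to numerical optimisation noise
  inv <- c("dist.skewness", "dist.kurtosis", paste0("ar.lag", 1:100))
  expect_equal(unname(fk[inv]), unname(f1[inv]), tolerance = 1e-4)
  spec_names <- grep("^spec\\.", names(f1), value = TRUE)
  expect_equal(unname(fk[spec_names]), unname(k^2 * f1[spec_names]),
               tolerance = 1e-8)
})

test_that("build_matrix stacks per-subject vectors and enforces truncation", {
  cohort <- small_cohort(n_patients = 2, n_controls = 3, n_minutes = 250)
  expect_error(build_matrix(cohort), "truncated")

  cut <- truncate_to_common_length(cohort)
  f <- build_matrix(cut)
  expect_identical(dim(f$x), c(5L, 209L + pad_length(250L) %/% 2L))
  expect_identical(rownames(f$x),
                   vapply(cut$records, `[[`, character(1), "subject_id"))
  i <- 2
  expect_equal(unname(f$x[i, ]),
               as.numeric(extract_features(cut$records[[i]]$series)))
  # change scores attach to patients only
  expect_identical(is.na(f$change), f$group == "control")
})
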