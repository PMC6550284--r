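# build label vectors realizing a given confusion matrix (positive = control)
labels_from_confusion <- function(tp, fn, fp, tn) {
  observed <- c(rep("control", tp + fn), rep("patient", fp + tn))
  predicted <- c(rep("control", tp), rep("patient", fn),
                 rep("control", fp), rep("patient", tn))
  list(predicted = predicted, observed = observed)
}

test_that("agreement metrics reproduce the direct confusion-matrix formulas", {
  # the matrix implied by 32 controls / 23 patients with sensitivity 0.9375
  # and specificity 19/23
  l <- labels_from_confusion(tp = 30, fn = 2, fp = 4, tn = 19)
  m <- classification_metrics(l$predicted, l$observed, "control")
  expect_equal(m$accuracy, 49 / 55)
  expect_equal(m$sensitivity, 30 / 32)
  expect_equal(m$specificity, 19 / 23)
  expect_equal(round(m$kappa, 3), 0.773)
  expect_equal(m$nir, 32 / 55)

  perfect <- classification_metrics(l$observed, l$observed)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)

  # always predicting the majority class scores the no-information rate with
  # zero chance-corrected agreement
  maj <- classification_metrics(rep("control", 55), l$observed)
  expect_equal(maj$accuracy, maj$nir)
  expect_equal(maj$kappa, 0)

  expect_error(classification_metrics(c("a", "control"),
                                      c("control", "control")),
               "unknown label")
  expect_error(classification_metrics("control", c("control", "patient")),
               "equal length")
})

test_that("kappa and the binomial NIR test agree with independent oracles", {
  set.seed(99)
  for (i in 1:30) {
    cts <- rmultinom(1, sample(20:120, 1), prob = runif(4, 0.05, 1))[, 1]
    if (sum(cts[1:2]) == 0 || sum(cts[3:4]) == 0) next
    l <- labels_from_confusion(cts[1], cts[2], cts[3], cts[4])
    m <- classification_metrics(l$predicted, l$observed)

    tab <- table(factor(l$predicted, c("control", "patient")),
                 factor(l$observed, c("control", "patient")))
    expect_equal(m$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)

    n <- sum(cts)
    correct <- cts[1] + cts[4]
    expect_equal(m$nir_pvalue,
                 sum(dbinom(correct:n, n, max(colSums(tab)) / n)),
                 tolerance = 1e-12)
  }
})

test_that("correlation metrics match the t-transform and standardize cleanly", {
  expect_equal(regression_metrics(1:10, 1:10)$r, 1)
  expect_equal(regression_metrics(1:10, 1:10)$p, 0)
  expect_equal(regression_metrics(1:10, -(1:10))$r, -1)
  expect_error(regression_metrics(rep(1, 5), 1:5), "zero variance")
  expect_error(regression_metrics(1:2, 2:1), "at least 3")
  expect_error(regression_metrics(c(1, 2, Inf), 1:3), "non-finite")

  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1))
    b <- 0.5 * a + rnorm(length(a))
    m <- regression_metrics(a, b)
    ct <- cor.test(a, b)
    expect_equal(m$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(m$p, ct$p.value, tolerance = 1e-12)
    expect_equal(mean(m$predicted_z), 0, tolerance = 1e-12)
    expect_equal(sd(m$observed_z), 1, tolerance = 1e-12)
  }

  z <- standardize_change(c(30, 25, 22, 28), c(10, 20, 15, 26))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize_change(c(10, 12), c(5, 7)), "zero variance")
  expect_error(standardize_change(1, 2), "at least 2")
})

test_that("leave-one-out prediction recovers separable groups without leakage", {
  f <- make_fake_features(n_patients = 8, n_controls = 8, separation = 10)
  cfg <- model_config("classify", rounds = 40, seed = 5)
  fit <- loocv_boost(f, cfg)
  expect_s3_class(fit, "acti_loocv")
  expect_gte(fit$metrics$kappa, 0.75)
  expect_identical(unname(fitted(fit)), fit$predicted)

  # fold i is reproducible from the other n-1 rows alone: refit by hand
  i <- 4
  y <- as.numeric(f$group == "control")
  set.seed(cfg$seed + i)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = cfg$max_depth,
                  eta = cfg$learning_rate, lambda = cfg$l2_penalty,
                  subsample = cfg$subsample, nthread = 1),
    data = xgboost::xgb.DMatrix(f$x[-i, ], label = y[-i]),
    nrounds = cfg$rounds, verbose = 0)
  manual <- predict(booster, xgboost::xgb.DMatrix(f$x[i, , drop = FALSE]))
  expect_equal(unname(fit$probability[i]), manual, tolerance = 1e-12)

  # a duplicated subject used as test row is predicted as its twin's label
  g <- f
  g$x <- rbind(g$x, twin = g$x[1, ])
  rownames(g$x)[nrow(g$x)] <- "twin"
  g$subjects <- c(g$subjects, "twin")
  g$group <- c(g$group, g$group[1])
  g$change <- c(g$change, NA_real_)
  twin_fit <- loocv_boost(g, cfg)
  expect_identical(twin_fit$predicted[nrow(g$x)], g$group[1])
})

test_that("leave-one-out preconditions are enforced", {
  f <- make_fake_features(6, 6)
  freg <- make_fake_features(10, 4)
  expect_error(loocv_boost(make_fake_features(1, 6),
                           model_config("classify", rounds = 5)),
               "at least 2 subjects")
  expect_error(loocv_boost(make_fake_features(0, 6),
                           model_config("classify", rounds = 5)),
               "both classes")
  expect_error(loocv_boost(f, model_config("regress", rounds = 5)),
               "every subject")
  expect_error(model_config("classify", rounds = 0), "rounds")
  expect_error(model_config("classify", subsample = 0), "subsample")

  reg <- loocv_boost(subset_patients(freg), model_config("regress", rounds = 40))
  expect_gt(reg$metrics$r, 0.5)   # change is linear in a feature column
  expect_length(residuals(reg), 10)
})

test_that("permutation p-values obey the empirical formula and bounds", {
  f <- make_fake_features(7, 7, separation = 12)
  cfg <- model_config("classify", rounds = 20, seed = 3)
  res <- permutation_test(f, cfg, "kappa", b = 9, seed = 1)
  expect_length(res$null_draws, 9)
  expect_equal(res$p_empirical,
               (1 + sum(res$null_draws >= res$observed)) / 10)
  expect_gt(res$p_empirical, 0)
  expect_lte(res$p_empirical, 1)
  expect_gte(res$observed, 0.7)  # groups separable
  expect_lte(res$p_empirical, 0.2)

  expect_error(permutation_test(f, cfg, "kappa", b = 0), "at least 1")
  expect_error(permutation_test(f, cfg, "pearson_r", b = 5), "regress")
  expect_error(permutation_test(f, model_config("regress"), "kappa", b = 5),
               "classify")
})
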