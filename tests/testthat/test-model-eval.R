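test_that("roc_auc matches pair counting, handles ties and transforms", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(scores, labels), 8 / 9)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), labels), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "Both classes")

  # invariance under strictly increasing transforms
  set.seed(3)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
  expect_equal(roc_auc(rank(s), l), roc_auc(s, l))

  # oracle equivalence on random instances with ties
  for (i in 1:40) {
    withr::with_seed(200 + i, {
      n <- sample(4:20, 1)
      l <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), sample(c(1, 2, 8), 1))  # coarse rounding makes ties
    })
    expect_equal(roc_auc(s, l), pair_count_auc(s, l))
  }
})

test_that("confusion counts and derived metrics follow their definitions", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 1, 0, 0, 0)
  cc <- confusion(scores, labels, 0.5)
  expect_equal(unlist(cc), c(TP = 2, TN = 2, FP = 1, FN = 1))
  expect_equal(sum(unlist(cc)), length(scores))

  cc0 <- confusion(scores, labels, 0)
  expect_equal(cc0$FN + cc0$TN, 0L)
  cc1 <- confusion(scores, labels, 2)
  expect_equal(cc1$TP + cc1$FP, 0L)

  m <- metrics(tibble::tibble(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(m), c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(metrics(tibble::tibble(TP = 33, TN = 47, FP = 13, FN = 9))$accuracy,
               80 / 102)
  expect_equal(metrics(tibble::tibble(TP = 0, TN = 0, FP = 5, FN = 5))$accuracy, 0)
  expect_true(is.na(metrics(tibble::tibble(TP = 0, TN = 5, FP = 0, FN = 0))$sensitivity))

  # accuracy = (sens * P + spec * N) / (P + N), exactly, for any table
  for (i in 1:20) {
    cc <- withr::with_seed(i, tibble::tibble(
      TP = sample(0:20, 1), TN = sample(0:20, 1),
      FP = sample(1:20, 1), FN = sample(1:20, 1)))
    m <- metrics(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})

test_that("predicted probabilities follow the logistic form", {
  tbl <- tibble::tibble(status = rep(c(0L, 1L), each = 20),
                        x = c(rnorm(20), rnorm(20, 1)))
  fit <- fit_logistic(tbl, "x")
  x0 <- -fit$beta0 / fit$coefficients[["x"]]
  expect_equal(predict_prob(fit, c(x = x0)), 0.5)
  p <- predict_prob(fit, tbl)
  expect_true(all(p > 0 & p < 1))
  # plogis o qlogis identity survives the scorer
  expect_equal(stats::qlogis(predict_prob(fit, c(x = 1.3))),
               fit$beta0 + fit$coefficients[["x"]] * 1.3)
  expect_error(predict_prob(fit, c(y = 1)), "Missing feature")
})

test_that("the published scorer reproduces its fixed-coefficient sigmoid", {
  # hand oracle: 1 / (1 + exp(-2.722))
  expect_equal(published_score(0, 0, 0), 1 / (1 + exp(-2.722)), tolerance = 1e-10)
  expect_equal(published_score(0, 0, 0), 0.9384, tolerance = 1e-4)
  expect_equal(published_score(100, 0, 0), 1 / (1 + exp(-(2.722 - 2.2))),
               tolerance = 1e-10)
  expect_equal(published_score(100, 0, 0), 0.6276, tolerance = 1e-4)
  # roots of the linear predictor score exactly 0.5
  ph1 <- (2.722 + 0.243 * 2 + 0.055 * 3) / 0.022
  expect_equal(published_score(ph1, 2, 3), 0.5, tolerance = 1e-10)
  # monotone: decreasing in ph1, increasing in ph2 and ph3
  expect_lt(published_score(10, 0, 0), published_score(0, 0, 0))
  expect_gt(published_score(0, 1, 0), published_score(0, 0, 0))
  expect_gt(published_score(0, 0, 1), published_score(0, 0, 0))
  m <- published_frailty_model()
  expect_equal(m$beta0, 2.722)
  expect_equal(unname(m$coefficients),c(-0.022, 0.243, 0.055))
})

test_that("bootstrap performance summarizes validation metrics with CIs", {
  tbl <- simulate_feature_table(42, 60, seed = 31,
                                effects = c(sts_duration = 1.2),
                                features = c("sts_duration", "cv_hip_angle_range"))
  sp <- make_bootstrap_pairs(tbl$status, B = 100, seed = 9)
  perf <- bootstrap_performance(tbl, "sts_duration", sp)
  expect_setequal(perf$metric, c("auc", "sensitivity", "specificity", "accuracy"))
  expect_true(all(perf$mean >= 0 & perf$mean <= 100))
  expect_true(all(perf$lower <= perf$mean & perf$mean <= perf$upper))

  # deterministic given splits
  expect_identical(tibble::as_tibble(perf),
                   tibble::as_tibble(bootstrap_performance(tbl, "sts_duration", sp)))

  # SEM intervals are narrower than percentile intervals here
  perf_sem <- bootstrap_performance(tbl, "sts_duration", sp, ci = "sem")
  expect_lt(mean(perf_sem$upper - perf_sem$lower),
            mean(perf$upper - perf$lower))

  # null features: AUC near chance with a covering CI
  tbl0 <- null_table(seed = 53, features = "cv_hip_angle_range")
  perf0 <- bootstrap_performance(tbl0, "cv_hip_angle_range",
                                 make_bootstrap_pairs(tbl0$status, B = 150, seed = 1))
  auc0 <- perf0[perf0$metric == "auc", ]
  expect_lt(abs(auc0$mean - 50), 8)
  expect_true(auc0$lower < 50 && auc0$upper > 50)

  # single pair: degenerate zero-width CI, flagged
  expect_warning(p1 <- bootstrap_performance(tbl, "sts_duration",
                                             make_bootstrap_pairs(tbl$status, B = 1, seed = 2)),
                 "degenerate")
  expect_equal(p1$lower, p1$upper, tolerance = 1e-12)
})

test_that("tidiers return well-formed tibbles", {
  tbl <- planted_table(seed = 61)
  fit <- fit_logistic(tbl, attr(tbl, "planted"))
  td <- generics::tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 4)
  expect_equal(generics::glance(fit)$n_features, 3)

  rfe <- rfe_rank(tbl, sig8_features(), selection_config(B = 15, seed = 3))
  expect_equal(nrow(generics::tidy(rfe)), 8)
  g <- generics::glance(rfe)
  expect_equal(g$n_loops, 7)
  expect_equal(g$loo_fits, count_model_fits(8, 15))
  sel <- select_optimal(rfe)
  expect_s3_class(generics::tidy(sel), "tbl_df")
  expect_true(is.logical(generics::glance(sel)$admissible))
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  for (i in 1:5) {
    withr::with_seed(400 + i, {
      s <- rnorm(40)
      l <- c(0, 1, rbinom(38, 1, 0.5))
    })
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(s, l), ref)
  }
})
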