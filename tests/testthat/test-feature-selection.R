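test_that("bootstrap pairs have the documented structure and determinism", {
  labels <- rep(c(0L, 1L), c(42, 60))
  sp <- make_bootstrap_pairs(labels, B = 50, seed = 7)
  expect_length(sp, 50)
  for (s in sp[1:5]) {
    expect_length(s$train, 102)
    expect_length(intersect(unique(s$train), s$oob), 0)
    expect_setequal(unique(labels[s$oob]), c(0, 1))
  }
  # stratification preserves class counts in every training draw
  expect_true(all(purrr::map_int(sp, ~sum(labels[.x$train] == 0)) == 42))

  expect_identical(sp, make_bootstrap_pairs(labels, B = 50, seed = 7))
  # growing B extends the sequence without reshuffling earlier pairs
  sp2 <- make_bootstrap_pairs(labels, B = 80, seed = 7)
  expect_identical(sp[1:50], sp2[1:50])

  expect_error(make_bootstrap_pairs(rep(1L, 10), B = 5), "Both classes")
})

test_that("unstratified out-of-bag fraction matches the analytic expectation", {
  labels <- rep(c(0L, 1L), c(42, 60))
  sp <- make_bootstrap_pairs(labels, B = 2000, seed = 3, stratified = FALSE)
  fracs <- purrr::map_dbl(sp, ~length(.x$oob) / 102)
  expected <- (1 - 1 / 102)^102
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se)
})

test_that("logistic fitting handles degenerate designs and recovers parameters", {
  # uninformative constant feature: intercept = logit(prevalence) = 0
  tbl <- tibble::tibble(status = rep(c(0L, 1L), each = 25), flat = 0)
  fit <- fit_logistic(tbl, "flat")
  expect_equal(fit$beta0, 0, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), 0)

  # parameter recovery: logit(p) = 0.5 + 1.2 x
  set.seed(13)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, stats::plogis(0.5 + 1.2 * x))
  fit2 <- fit_logistic(tibble::tibble(status = y, x = x), "x")
  expect_equal(unname(fit2$coefficients), 1.2, tolerance = 0.15)
  expect_true(fit2$converged)

  # perfect separation: flagged, scores still rank perfectly
  sep <- tibble::tibble(status = rep(c(0L, 1L), each = 10),
                        x = c(rnorm(10, -5), rnorm(10, 5)))
  fit3 <- fit_logistic(sep, "x")
  expect_false(fit3$converged)
  expect_equal(roc_auc(predict_prob(fit3, sep), sep$status), 1)

  expect_error(fit_logistic(tibble::tibble(status = rep(1L, 10), x = rnorm(10)), "x"),
               "Both classes")
})

test_that("leave-one-out AUC identifies the informative feature", {
  tbl <- simulate_feature_table(
    42, 60, seed = 19,
    effects = c(mean_vertical_power_range = -1.5),
    features = c("mean_vertical_power_range", "cv_hip_angle_range"))
  sp <- make_bootstrap_pairs(tbl$status, B = 100, seed = 2)
  loo <- leave_one_out_auc(tbl, c("mean_vertical_power_range", "cv_hip_angle_range"), sp)
  auc_excl_noise <- loo$mean_auc[loo$feature == "cv_hip_angle_range"]
  auc_excl_info <- loo$mean_auc[loo$feature == "mean_vertical_power_range"]
  expect_gt(auc_excl_noise, auc_excl_info + 0.15)

  # B = 1, two candidates: exactly two model fits
  sp1 <- make_bootstrap_pairs(tbl$status, B = 1, seed = 5)
  reset_fit_count()
  leave_one_out_auc(tbl, c("mean_vertical_power_range", "cv_hip_angle_range"), sp1)
  expect_equal(fit_count(), 2L)

  # all-noise candidates hover near chance
  tbl0 <- null_table(seed = 77, features = sts_feature_names()[2:4])
  loo0 <- leave_one_out_auc(tbl0, sts_feature_names()[2:4],
                            make_bootstrap_pairs(tbl0$status, B = 150, seed = 3))
  expect_true(all(abs(loo0$mean_auc - 0.5) < 0.08))
})

test_that("the analytic fit count matches executed elimination runs", {
  expect_equal(count_model_fits(8, 2000), 70000L)
  expect_equal(count_model_fits(2, 1), 2L)
  expect_equal(count_model_fits(5, 10), 140L)
  expect_error(count_model_fits(1, 10), "at least 2")

  tbl <- planted_table(seed = 23)
  for (cfg in list(c(2, 5), c(4, 3), c(8, 2))) {
    feats <- sig8_features()[seq_len(cfg[1])]
    reset_fit_count()
    rfe <- rfe_rank(tbl, feats, selection_config(B = cfg[2], seed = 1),
                    subset_auc = FALSE)
    expect_equal(fit_count(), count_model_fits(cfg[1], cfg[2]))
    expect_equal(rfe$loo_fits, count_model_fits(cfg[1], cfg[2]))
  }
})

test_that("RFE is deterministic, complete and permutation-invariant", {
  tbl <- planted_table(seed = 29)
  cfg <- selection_config(B = 40, seed = 11)
  r1 <- rfe_rank(tbl, sig8_features(), cfg)
  r2 <- rfe_rank(tbl, sig8_features(), cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$ranking, r2$ranking)

  expect_setequal(r1$ranking$feature, sig8_features())
  expect_equal(r1$ranking$rank, 1:8)
  expect_equal(max(r1$trace$loop), 7)
  expect_equal(sum(r1$trace$eliminated), 7)

  # shuffling candidate order leaves an untied ranking unchanged
  shuffled <- withr::with_seed(4, sample(sig8_features()))
  r3 <- rfe_rank(tbl, shuffled, cfg)
  expect_equal(r3$ranking$feature, r1$ranking$feature)

  # smallest case: 2 features, B = 1
  r4 <- rfe_rank(tbl, sig8_features()[1:2],
                 selection_config(B = 1, seed = 2), subset_auc = FALSE)
  expect_equal(nrow(r4$ranking), 2)
  expect_equal(r4$loo_fits, 2L)
})

test_that("first elimination is exchangeable across all-noise features", {
  feats <- sts_feature_names()[2:9]
  first_out <- purrr::map_chr(1:200, function(r) {
    tbl <- null_table(seed = 5000 + r, features = feats, n_robust = 20, n_frail = 20)
    rfe <- rfe_rank(tbl, feats, selection_config(B = 3, seed = r),
                    subset_auc = FALSE)
    rfe$trace$feature[rfe$trace$eliminated & rfe$trace$loop == 1]
  })
  counts <- table(factor(first_out, levels = feats))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("optimal-subset selection applies the coverage + AUC rule", {
  fake_rfe <- function(phenos, aucs) {
    structure(list(
      ranking = tibble::tibble(rank = seq_along(phenos),
                               feature = paste0("f", seq_along(phenos)),
                               phenotype = phenos, subset_auc = aucs),
      config = selection_config(B = 1, seed = 1),
      trace = NULL, loo_fits = 0L, splits = NULL
    ), class = "frailty_rfe")
  }
  # coverage and AUC both reached at k = 3
  sel <- select_optimal(fake_rfe(c("slowness", "weakness", "exhaustion", "slowness"),
                                 c(0.70, 0.78, 0.852, 0.86)))
  expect_true(sel$admissible)
  expect_equal(sel$k, 3)
  expect_equal(sel$auc, 0.852)
  expect_equal(sel$features, c("f1", "f2", "f3"))

  # coverage only at k = 5 with AUC above threshold there
  sel5 <- select_optimal(fake_rfe(
    c("slowness", "slowness", "weakness", "weakness", "exhaustion"),
    c(0.9, 0.9, 0.9, 0.9, 0.81)))
  expect_equal(sel5$k, 5)

  # single-phenotype ranking can never cover: explicit non-admissible result
  sel_no <- select_optimal(fake_rfe(rep("slowness", 4), rep(0.95, 4)))
  expect_false(sel_no$admissible)
  expect_length(sel_no$features, 0)

  # AUC threshold gate: coverage at k = 3 but AUC too low everywhere
  sel_low <- select_optimal(fake_rfe(c("slowness", "weakness", "exhaustion"),
                                     c(0.6, 0.65, 0.7)))
  expect_false(sel_low$admissible)
})
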