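# Model scoring and bootstrap-validated performance: ROC AUC, confusion
# metrics, and mean/95% CI over the validation sets. Plus the published
# fixed-coefficient frailty scorer.

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' AUC equals the probability that a randomly chosen positive scores above
#' a randomly chosen negative, with positive-negative ties counted 1/2
#' (midranks).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0, 0)) # 8/9
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) rlang::abort("Both classes must be present.")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a probability threshold
#'
#' Predicted frail iff score >= threshold.
#'
#' @param scores Numeric scores (probabilities).
#' @param labels Binary labels (0/1).
#' @param threshold Operating threshold (default 0.5).
#' @return One-row tibble: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  tibble::tibble(
    TP = sum(pred & labels == 1), TN = sum(!pred & labels == 0),
    FP = sum(pred & labels == 0), FN = sum(!pred & labels == 1)
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/(TP+TN+FP+FN). Zero-denominator metrics are `NA`.
#'
#' @param counts One-row tibble/list with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`
#'   (proportions).
#' @export
metrics <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    tibble::tibble(
      sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
      specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
      accuracy = if (total > 0) (TP + TN) / total else NA_real_
    )
  })
}

#' Bootstrap-validated performance of a feature subset
#'
#' For each bootstrap pair, fits the logistic model on the training
#' resample, scores the out-of-bag validation set and computes AUC,
#' sensitivity, specificity and accuracy at the operating threshold;
#' reports the mean and 95% CI of each metric over the B validation sets,
#' in percent. The default CI is the percentile interval of the per-pair
#' values; `ci = "sem"` gives mean +/- 1.96 SE across pairs.
#'
#' @param table Feature table with binary `status`.
#' @param features Feature subset (non-empty).
#' @param splits A [make_bootstrap_pairs()] result.
#' @param threshold Operating probability threshold (default 0.5).
#' @param ci CI method, `"percentile"` or `"sem"`.
#' @return A `frailty_performance` tibble: `metric`, `mean`, `lower`,
#'   `upper` (percent); attributes `ci`, `threshold`, `B`.
#' @export
bootstrap_performance <- function(table, features, splits, threshold = 0.5,
                                  ci = c("percentile", "sem")) {
  ci <- match.arg(ci)
  if (length(features) < 1) rlang::abort("`features` must be non-empty.")
  X <- as.matrix(table[features]); y <- table$status
  vals <- t(vapply(splits, function(sp) {
    f <- .logit_fit(X[sp$train, , drop = FALSE], y[sp$train])
    p <- pmin(pmax(.logit_score(f$coef, X[sp$oob, , drop = FALSE]), 1e-12), 1 - 1e-12)
    yv <- y[sp$oob]
    m <- metrics(confusion(p, yv, threshold))
    c(auc = roc_auc(p, yv), sensitivity = m$sensitivity,
      specificity = m$specificity, accuracy = m$accuracy)
  }, numeric(4)))
  B <- nrow(vals)
  if (B == 1) rlang::warn("Single bootstrap pair: confidence intervals are degenerate (zero width).")
  summarize1 <- function(v) {
    v <- v[!is.na(v)]
    if (ci == "percentile") {
      lims <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    } else {
      se <- stats::sd(v) / sqrt(length(v))
      if (!is.finite(se)) se <- 0
      lims <- mean(v) + c(-1.96, 1.96) * se
    }
    c(mean(v), lims)
  }
  out <- purrr::map_dfr(colnames(vals), function(metric) {
    s <- summarize1(vals[, metric]) * 100
    tibble::tibble(metric = metric, mean = s[1], lower = s[2], upper = s[3])
  })
  attr(out, "ci") <- ci
  attr(out, "threshold") <- threshold
  attr(out, "B") <- B
  class(out) <- c("frailty_performance", class(out))
  out
}

#' The published fixed-coefficient frailty model
#'
#' Logistic model with intercept 2.722 and coefficients -0.022 on the mean
#' of hip angular velocity range (slowness), 0.243 on the mean of vertical
#' power range (weakness) and 0.055 on the CV of vertical power range
#' (exhaustion). Input units are taken as deg/s for the angular velocity,
#' W for the vertical power and percent for the CV; the coefficients are
#' fixed constants, so any rescaling of inputs must be done by the caller.
#'
#' @return A `frailty_logit` with the fixed coefficients.
#' @export
published_frailty_model <- function() {
  structure(
    list(beta0 = 2.722,
         coefficients = c(mean_hip_angular_velocity_range = -0.022,
                          mean_vertical_power_range = 0.243,
                          cv_vertical_power_range = 0.055),
         converged = TRUE, n = NA_integer_),
    class = "frailty_logit"
  )
}

#' Score frailty probability with the published model
#'
#' @param ph1 Mean of hip angular velocity range (deg/s).
#' @param ph2 Mean of vertical power range (W).
#' @param ph3 CV of vertical power range (percent).
#' @return Frailty probability in (0, 1); vectorized over inputs.
#' @export
#' @examples
#' published_score(0, 0, 0) # 0.938...
published_score <- function(ph1, ph2, ph3) {
  m <- published_frailty_model()
  b <- m$coefficients
  p <- stats::plogis(m$beta0 + b[[1]] * ph1 + b[[2]] * ph2 + b[[3]] * ph3)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
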