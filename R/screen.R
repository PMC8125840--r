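# Two-group per-feature screening: Shapiro-Wilk normality routing to
# one-way ANOVA or the Mann-Whitney U test.

#' Shapiro-Wilk normality p-value
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
normality_p <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) rlang::abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  if (stats::sd(values) == 0) rlang::abort("Constant sample: normality undefined.")
  stats::shapiro.test(values)$p.value
}

#' Normality-routed two-group test for one feature
#'
#' If both groups pass the Shapiro-Wilk test at `alpha`, a classical
#' (equal-variance) one-way ANOVA compares the groups; otherwise a
#' two-sided Mann-Whitney U test is used (exact when the smaller group has
#' at most 8 subjects and there are no ties, normal approximation with tie
#' correction otherwise). Routing is a pure function of the two normality
#' p-values and `alpha`.
#'
#' @param rg_values,fg_values Numeric samples for the robust and
#'   pre-frail/frail groups (each n >= 3).
#' @param alpha Significance level.
#' @param test `"auto"` for normality routing, or force `"anova"` /
#'   `"mann_whitney"`.
#' @return One-row tibble: `test`, `statistic` (F or U), `p_value`,
#'   `significant`.
#' @export
#' @examples
#' route_and_test(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
route_and_test <- function(rg_values, fg_values, alpha = 0.05,
                           test = c("auto", "anova", "mann_whitney")) {
  test <- match.arg(test)
  if (length(rg_values) == 0 || length(fg_values) == 0) {
    rlang::abort("Both groups must be non-empty.")
  }
  if (test == "auto") {
    if (length(rg_values) < 3 || length(fg_values) < 3) {
      rlang::abort("Need at least 3 subjects per group for normality routing.")
    }
    normal <- tryCatch(
      normality_p(rg_values) > alpha && normality_p(fg_values) > alpha,
      error = function(e) FALSE  # constant sample: clearly non-normal route
    )
    test <- if (normal) "anova" else "mann_whitney"
  }
  if (test == "anova") {
    values <- c(rg_values, fg_values)
    grp <- factor(rep(c("rg", "fg"), c(length(rg_values), length(fg_values))))
    fit <- stats::oneway.test(values ~ grp, var.equal = TRUE)
    stat <- unname(fit$statistic); p <- fit$p.value
  } else {
    nmin <- min(length(rg_values), length(fg_values))
    ties <- anyDuplicated(c(rg_values, fg_values)) > 0
    wt <- suppressWarnings(stats::wilcox.test(
      rg_values, fg_values, exact = (nmin <= 8 && !ties)))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  tibble::tibble(test = test, statistic = stat, p_value = p,
                 significant = p < alpha)
}

#' Screen all features of a table for group differences
#'
#' Runs [route_and_test()] on every feature column, in canonical column
#' order, with no multiplicity correction by default (a Benjamini-Hochberg
#' option is available). Significance is judged on the (optionally
#' adjusted) p-value.
#'
#' @param table Feature table: tibble with a binary `status` column and
#'   numeric feature columns.
#' @param alpha Significance level.
#' @param features Feature columns to screen (default: every numeric
#'   column except `subject_id` and `status`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `frailty_screen` tibble: `feature`, `phenotype`, `test`,
#'   `statistic`, `p_value`, `significant`; attribute `alpha`.
#' @export
#' @examples
#' tbl <- simulate_feature_table(seed = 3)
#' scr <- screen_features(tbl)
#' significant_features(scr)
screen_features <- function(table, alpha = 0.05, features = NULL,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!"status" %in% names(table)) rlang::abort("`table` must have a `status` column.")
  if (is.null(features)) features <- .feature_columns(table)
  rg <- table$status == 0
  res <- purrr::map_dfr(features, function(f) {
    dplyr::bind_cols(tibble::tibble(feature = f),
                     route_and_test(table[[f]][rg], table[[f]][!rg], alpha))
  })
  if (adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_value < alpha
  }
  ph <- sts_phenotype_map()
  res <- dplyr::mutate(res,
    phenotype = dplyr::if_else(.data$feature %in% names(ph),
                               unname(ph[.data$feature]), NA_character_),
    .after = "feature")
  attr(res, "alpha") <- alpha
  class(res) <- c("frailty_screen", class(res))
  res
}

#' Features passing the significance filter
#'
#' @param screen A `frailty_screen` result from [screen_features()].
#' @return Character vector of significant feature names, in canonical
#'   (input) order.
#' @export
significant_features <- function(screen) {
  stopifnot(inherits(screen, "frailty_screen"))
  screen$feature[screen$significant]
}
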