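# Bootstrapped recursive feature elimination over logistic models ranked
# by mean out-of-bag validation AUC, and phenotype-covering optimal-subset
# selection.

#' Configure the feature-selection procedure
#'
#' @param B Bootstrap pair count (default 2000).
#' @param seed Integer seed for the bootstrap draws.
#' @param auc_threshold AUC the optimal subset must exceed (default 0.80).
#' @param phenotype_map Named map feature -> phenotype
#'   (slowness/weakness/exhaustion); defaults to [sts_phenotype_map()].
#' @param stratified Stratify bootstrap resampling by class?
#' @param direction Elimination rule. `"least_informative"` (default)
#'   removes the feature whose leave-one-out (exclusion) model attains the
#'   HIGHEST mean AUC — i.e. the feature the model misses least.
#'   `"literal"` removes the feature whose exclusion model has the lowest
#'   mean AUC.
#' @return A `selection_config` list.
#' @export
selection_config <- function(B = 2000, seed = 1L, auc_threshold = 0.80,
                             phenotype_map = sts_phenotype_map(),
                             stratified = TRUE,
                             direction = c("least_informative", "literal")) {
  if (B < 1) rlang::abort("`B` must be at least 1.")
  if (auc_threshold <= 0 || auc_threshold >= 1) rlang::abort("`auc_threshold` must be in (0, 1).")
  structure(
    list(B = as.integer(B), seed = as.integer(seed),
         auc_threshold = auc_threshold, phenotype_map = phenotype_map,
         stratified = stratified, direction = match.arg(direction)),
    class = "selection_config"
  )
}

# mean OOB AUC of the model using `features`, over the given splits
.subset_mean_auc <- function(X, y, features, splits) {
  Xs <- X[, features, drop = FALSE]
  mean(vapply(splits, function(sp) {
    f <- .logit_fit(Xs[sp$train, , drop = FALSE], y[sp$train])
    roc_auc(.logit_score(f$coef, Xs[sp$oob, , drop = FALSE]), y[sp$oob])
  }, numeric(1)))
}

#' Leave-one-out mean validation AUCs for a candidate feature set
#'
#' For each candidate feature, fits the logistic model on all OTHER
#' features of the set on every bootstrap training set, scores its
#' out-of-bag validation set, and averages the AUC over the B pairs.
#'
#' @param table Feature table with binary `status`.
#' @param features Candidate feature set (>= 2 features).
#' @param splits A `bootstrap_splits` object.
#' @return Tibble: `feature`, `mean_auc` (AUC of the model excluding that
#'   feature).
#' @export
leave_one_out_auc <- function(table, features, splits) {
  if (length(features) < 2) rlang::abort("Need at least 2 candidate features.")
  X <- as.matrix(table[features])
  y <- table$status
  tibble::tibble(
    feature = features,
    mean_auc = vapply(features, function(f) {
      .subset_mean_auc(X, y, setdiff(features, f), splits)
    }, numeric(1))
  )
}

#' Analytic count of leave-one-out model fits in a full elimination run
#'
#' One leave-one-out model is fitted per remaining feature per bootstrap
#' pair, and elimination loops run while at least two features remain:
#' B * sum(k, k = 2..n_features). With 8 features and B = 2000 this is
#' 70,000 fits.
#'
#' @param n_features Number of starting features (>= 2).
#' @param B Bootstrap pair count (>= 1).
#' @return Integer fit count.
#' @export
#' @examples
#' count_model_fits(8, 2000) # 70000
count_model_fits <- function(n_features, B) {
  if (n_features < 2) rlang::abort("`n_features` must be at least 2.")
  if (B < 1) rlang::abort("`B` must be at least 1.")
  as.integer(B * sum(2:n_features))
}

#' Bootstrapped recursive feature elimination
#'
#' Starting from the candidate set, each elimination loop computes the
#' leave-one-out mean validation AUC for every remaining feature
#' ([leave_one_out_auc()]) and removes one feature per the configured
#' direction, until a single feature remains. The ranking is the reverse
#' elimination order (rank 1 = last survivor). Per-size subset AUCs (the
#' model on the top-k ranked features, same bootstrap splits) are computed
#' for the selection rule and the performance-vs-size curve. Ties on mean
#' AUC are broken toward the candidate earliest in canonical feature
#' order.
#'
#' @param table Feature table with binary `status`.
#' @param features Candidate features (>= 2); defaults to all feature
#'   columns of `table`.
#' @param config A [selection_config()].
#' @param splits Optional pre-built [make_bootstrap_pairs()] result
#'   (otherwise drawn from the config seed).
#' @param subset_auc Compute the per-k subset AUC curve? (Set `FALSE` to
#'   run only the elimination loops, e.g. when auditing fit counts.)
#' @return A `frailty_rfe`: list with `trace` (per-loop candidate AUCs and
#'   elimination flags), `ranking` (rank, feature, phenotype, subset_auc),
#'   `loo_fits` (executed leave-one-out fit count), `config`, `splits`.
#' @export
#' @examples
#' tbl <- simulate_feature_table(seed = 9)
#' rfe <- rfe_rank(tbl, config = selection_config(B = 10, seed = 2))
#' rfe$ranking
rfe_rank <- function(table, features = NULL, config = selection_config(),
                     splits = NULL, subset_auc = TRUE) {
  stopifnot(inherits(config, "selection_config"))
  if (is.null(features)) features <- .feature_columns(table)
  if (length(features) < 2) rlang::abort("Need at least 2 candidate features.")
  if (is.null(splits)) {
    splits <- make_bootstrap_pairs(table$status, B = config$B,
                                   seed = config$seed,
                                   stratified = config$stratified)
  }
  canonical <- features  # input order is the canonical tie-breaking order
  remaining <- features
  eliminated <- character(0)
  trace <- list()
  fits_before <- fit_count()
  loop <- 0L
  while (length(remaining) >= 2) {
    loop <- loop + 1L
    loo <- leave_one_out_auc(table, remaining, splits)
    pick <- switch(config$direction,
      least_informative = which.max(loo$mean_auc),
      literal = which.min(loo$mean_auc)
    ) # `remaining` kept in canonical order, so first max/min = earliest tie
    drop <- loo$feature[pick]
    trace[[loop]] <- dplyr::mutate(loo, loop = loop,
                                   eliminated = .data$feature == drop,
                                   .before = 1)
    eliminated <- c(eliminated, drop)
    remaining <- remaining[remaining != drop]
  }
  loo_fits <- fit_count() - fits_before
  ranked <- c(remaining, rev(eliminated))
  ph <- config$phenotype_map
  ranking <- tibble::tibble(
    rank = seq_along(ranked), feature = ranked,
    phenotype = dplyr::if_else(ranked %in% names(ph), unname(ph[ranked]),
                               NA_character_)
  )
  if (subset_auc) {
    X <- as.matrix(table[canonical]); y <- table$status
    ranking$subset_auc <- vapply(seq_along(ranked), function(k) {
      .subset_mean_auc(X, y, ranked[seq_len(k)], splits)
    }, numeric(1))
  } else {
    ranking$subset_auc <- NA_real_
  }
  structure(
    list(trace = dplyr::bind_rows(trace), ranking = ranking,
         loo_fits = loo_fits, config = config, splits = splits),
    class = "frailty_rfe"
  )
}

#' Select the optimal feature subset from a ranking
#'
#' Returns the smallest k such that the top-k ranked features cover all
#' three frailty phenotypes (slowness, weakness, exhaustion) AND the
#' top-k subset's mean validation AUC exceeds the threshold. If no k
#' satisfies both, an explicit non-admissible result is returned.
#'
#' @param rfe A `frailty_rfe` from [rfe_rank()] (with subset AUCs).
#' @param auc_threshold Override of the config's AUC threshold.
#' @return A `frailty_selection`: list with `features`, `k`, `auc`,
#'   `admissible`.
#' @export
select_optimal <- function(rfe, auc_threshold = NULL) {
  stopifnot(inherits(rfe, "frailty_rfe"))
  thr <- if (is.null(auc_threshold)) rfe$config$auc_threshold else auc_threshold
  rk <- rfe$ranking
  if (anyNA(rk$subset_auc)) rlang::abort("Ranking has no subset AUCs; rerun rfe_rank(subset_auc = TRUE).")
  needed <- c("slowness", "weakness", "exhaustion")
  for (k in seq_len(nrow(rk))) {
    top <- rk[seq_len(k), ]
    if (all(needed %in% top$phenotype) && top$subset_auc[k] > thr) {
      return(structure(list(features = top$feature, k = k,
                            auc = top$subset_auc[k], admissible = TRUE),
                       class = "frailty_selection"))
    }
  }
  structure(list(features = character(0), k = NA_integer_, auc = NA_real_,
                 admissible = FALSE),
            class = "frailty_selection")
}

#' @export
print.frailty_rfe <- function(x, ...) {
  cat(sprintf("<frailty_rfe> %d features ranked over B = %d bootstrap pairs (%d leave-one-out fits)\n",
              nrow(x$ranking), x$config$B, x$loo_fits))
  print(x$ranking)
  invisible(x)
}

#' @export
print.frailty_selection <- function(x, ...) {
  if (x$admissible) {
    cat(sprintf("<frailty_selection> top-%d subset, AUC = %.3f:\n  %s\n",
                x$k, x$auc, paste(x$features, collapse = ", ")))
  } else {
    cat("<frailty_selection> no admissible subset (phenotype coverage + AUC threshold unmet)\n")
  }
  invisible(x)
}
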