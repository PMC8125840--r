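# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted logistic frailty model
#'
#' @param x A `frailty_logit`.
#' @param ... Unused.
#' @return Tibble of `term`, `estimate` (intercept first).
#' @export
tidy.frailty_logit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$beta0, unname(x$coefficients))
  )
}

#' @rdname tidy.frailty_logit
#' @return `glance()`: one-row tibble with `n_features`, `converged`, `n`.
#' @export
glance.frailty_logit <- function(x, ...) {
  tibble::tibble(n_features = length(x$coefficients),
                 converged = x$converged, n = x$n)
}

#' Tidy a recursive-feature-elimination result
#'
#' @param x A `frailty_rfe`.
#' @param ... Unused.
#' @return The ranking tibble (`rank`, `feature`, `phenotype`,
#'   `subset_auc`).
#' @export
tidy.frailty_rfe <- function(x, ...) x$ranking

#' @rdname tidy.frailty_rfe
#' @return `glance()`: one-row tibble with feature/loop/fit counts and the
#'   best subset AUC.
#' @export
glance.frailty_rfe <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$ranking),
    n_loops = max(x$trace$loop),
    loo_fits = x$loo_fits,
    B = x$config$B,
    best_subset_auc = suppressWarnings(max(x$ranking$subset_auc))
  )
}

#' Tidy an optimal-subset selection
#'
#' @param x A `frailty_selection`.
#' @param ... Unused.
#' @return Tibble of the selected features with their rank.
#' @export
tidy.frailty_selection <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$features), feature = x$features)
}

#' @rdname tidy.frailty_selection
#' @export
glance.frailty_selection <- function(x, ...) {
  tibble::tibble(k = x$k, auc = x$auc, admissible = x$admissible)
}

#' Tidy a bootstrap performance summary
#'
#' @param x A `frailty_performance`.
#' @param ... Unused.
#' @return The metric tibble (`metric`, `mean`, `lower`, `upper`, percent).
#' @export
tidy.frailty_performance <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.frailty_performance
#' @return `glance()`: one-row tibble of metric means plus the CI method,
#'   threshold and B.
#' @export
glance.frailty_performance <- function(x, ...) {
  wide <- stats::setNames(as.list(x$mean), x$metric)
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::tibble(ci = attr(x, "ci"),
                                  threshold = attr(x, "threshold"),
                                  B = attr(x, "B")))
}

#' Tidy a full pipeline run
#'
#' @param x A `frailty_run`.
#' @param ... Unused.
#' @return The RFE ranking tibble with a `selected` flag.
#' @export
tidy.frailty_run <- function(x, ...) {
  dplyr::mutate(x$rfe$ranking,
                selected = .data$feature %in% x$selection$features)
}

#' @rdname tidy.frailty_run
#' @export
glance.frailty_run <- function(x, ...) {
  perf <- if (!is.null(x$performance)) glance(x$performance)[1, x$performance$metric] else
    tibble::tibble(auc = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, accuracy = NA_real_)
  dplyr::bind_cols(
    tibble::tibble(n_subjects = x$n_subjects,
                   n_significant = sum(x$screen$significant),
                   k_selected = x$selection$k,
                   admissible = x$selection$admissible),
    perf
  )
}
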