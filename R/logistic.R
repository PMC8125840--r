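# Unpenalized maximum-likelihood logistic regression with an instrumented
# fit counter, used by the recursive-feature-elimination and evaluation
# stages.

.fit_counter <- new.env(parent = emptyenv())
.fit_counter$n <- 0L

#' Reset / read the instrumented model-fit counter
#'
#' Every logistic fit performed by the package increments a global counter,
#' so the executed fit count of a selection run can be checked against the
#' analytic count from [count_model_fits()].
#'
#' @return `fit_count()` returns the number of fits since the last reset.
#' @export
reset_fit_count <- function() {
  .fit_counter$n <- 0L
  invisible(NULL)
}

#' @rdname reset_fit_count
#' @export
fit_count <- function() .fit_counter$n

# fast path: X is the design matrix WITHOUT intercept, y in {0,1}
.logit_fit <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, X), y, family = stats::binomial(), control = list(maxit = 30)))
  .fit_counter$n <- .fit_counter$n + 1L
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # aliased (e.g. constant) columns carry no signal
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  list(coef = coefs, converged = fit$converged && !separated)
}

.logit_score <- function(coef, X) {
  as.numeric(stats::plogis(coef[1] + X %*% coef[-1]))
}

#' Fit a logistic frailty model
#'
#' Maximum-likelihood logistic regression of binary frailty status on a
#' feature subset, intercept included, no penalty. On non-convergence or
#' perfect separation the iteration-capped estimate is returned with the
#' convergence flag unset; its scores remain usable for ranking (AUC).
#'
#' @param table Feature table with a binary `status` column.
#' @param features Character vector of feature columns to use.
#' @return A `frailty_logit`: list with `beta0`, named `coefficients`,
#'   `converged`, `n`.
#' @export
#' @examples
#' tbl <- simulate_feature_table(seed = 5)
#' fit_logistic(tbl, c("sts_duration", "mean_vertical_power_range"))
fit_logistic <- function(table, features) {
  if (length(features) < 1) rlang::abort("Need at least one feature.")
  y <- table$status
  if (length(unique(y)) < 2) rlang::abort("Both classes must be present in `status`.")
  X <- as.matrix(table[features])
  f <- .logit_fit(X, y)
  structure(
    list(beta0 = unname(f$coef[1]),
         coefficients = stats::setNames(unname(f$coef[-1]), features),
         converged = f$converged, n = length(y)),
    class = "frailty_logit"
  )
}

#' Predicted frailty probability from a logistic model
#'
#' p = 1 / (1 + exp(-(beta0 + sum(beta_j x_j)))), strictly inside (0, 1).
#'
#' @param model A `frailty_logit` (e.g. from [fit_logistic()] or
#'   [published_frailty_model()]).
#' @param newdata Tibble/data frame containing the model's feature columns,
#'   or a named numeric vector.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "frailty_logit"))
  feats <- names(model$coefficients)
  if (is.numeric(newdata) && !is.matrix(newdata)) newdata <- tibble::as_tibble(as.list(newdata))
  missing <- setdiff(feats, names(newdata))
  if (length(missing)) {
    rlang::abort(paste("Missing feature value(s):", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(newdata)[feats])
  p <- .logit_score(c(model$beta0, model$coefficients), X)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' @export
print.frailty_logit <- function(x, ...) {
  cat(sprintf("<frailty_logit> %d feature(s), n = %s%s\n",
              length(x$coefficients), ifelse(is.null(x$n), "?", x$n),
              if (isTRUE(x$converged)) "" else " (not converged)"))
  print(c(`(Intercept)` = x$beta0, x$coefficients))
  invisible(x)
}
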