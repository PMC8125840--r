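# Bootstrap training/validation pairs: resample-with-replacement training
# sets with out-of-bag validation sets.

#' Draw bootstrap training/validation pairs
#'
#' Each pair consists of a training multiset of size n drawn with
#' replacement (stratified within class by default, preserving the class
#' sizes) and its out-of-bag (OOB) validation set: the subjects absent
#' from the training draw. Draws with an empty or single-class OOB set
#' (or a single-class training set) are redrawn. Splits are drawn
#' sequentially from the seed, so increasing `B` extends the sequence
#' without reshuffling earlier pairs.
#'
#' @param labels Binary status vector (0/1), both classes present, n >= 4.
#' @param B Number of pairs.
#' @param seed Integer seed.
#' @param stratified Resample within class?
#' @return A `bootstrap_splits` list of `B` elements, each
#'   `list(train, oob)` of subject indices; attributes `n`, `seed`,
#'   `stratified`.
#' @export
#' @examples
#' sp <- make_bootstrap_pairs(rep(0:1, c(5, 7)), B = 3, seed = 1)
#' length(sp[[1]]$train)
make_bootstrap_pairs <- function(labels, B = 2000, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (n < 4) rlang::abort("Need at least 4 subjects.")
  if (length(unique(labels)) < 2) rlang::abort("Both classes must be present.")
  if (B < 1) rlang::abort("`B` must be at least 1.")
  idx0 <- which(labels == 0); idx1 <- which(labels == 1)
  splits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(B), function(b) {
      repeat {
        train <- if (stratified) {
          c(sample(idx0, length(idx0), replace = TRUE),
            sample(idx1, length(idx1), replace = TRUE))
        } else {
          sample.int(n, n, replace = TRUE)
        }
        oob <- setdiff(seq_len(n), train)
        if (length(oob) > 0 &&
            length(unique(labels[oob])) == 2 &&
            length(unique(labels[train])) == 2) {
          return(list(train = train, oob = oob))
        }
      }
    })
  })
  structure(splits, class = "bootstrap_splits", n = n, seed = as.integer(seed),
            stratified = stratified)
}

#' @export
print.bootstrap_splits <- function(x, ...) {
  cat(sprintf("<bootstrap_splits> B = %d pairs over n = %d subjects (%s)\n",
              length(x), attr(x, "n"),
              if (attr(x, "stratified")) "stratified" else "unstratified"))
  invisible(x)
}
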