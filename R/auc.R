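#' Area under the ROC curve (rank form)
#'
#' One-vs-rest AUROC computed as the normalized Mann-Whitney U statistic
#' with midrank tie handling: the probability that a random positive scores
#' above a random negative, counting ties as 1/2.
#'
#' @param scores numeric vector of scores (higher = more positive).
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop_ps("scores/labels contain NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop_ps("both classes must be present to compute AUROC")
  r <- rank(scores)                      # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multi-class AUROC (mean one-vs-rest)
#'
#' The unweighted mean of the one-vs-rest AUROCs of the three diagnostic
#' classes, each computed from the class's probability column.
#'
#' @param prob samples x classes probability matrix with class names as
#'   column names.
#' @param labels class labels (bacterial/viral/noninfected).
#' @param na_absent if `TRUE`, a class absent from `labels` contributes `NA`
#'   and is dropped from the mean (used on small held-out folds); if
#'   `FALSE` (default) an absent class is an error.
#' @return mean AUROC, and per-class values as attribute `per_class`.
#' @export
mauroc <- function(prob, labels, na_absent = FALSE) {
  y <- as_class_factor(labels)
  miss <- setdiff(TRIAGE_CLASSES, colnames(prob))
  if (length(miss) > 0)
    stop_ps("probability matrix lacks class column(s): %s",
            paste(miss, collapse = ", "))
  per <- vapply(TRIAGE_CLASSES, function(cl) {
    pos <- y == cl
    if (all(pos) || !any(pos)) {
      if (na_absent) return(NA_real_)
      stop_ps("class '%s' absent; cannot compute one-vs-rest AUROC", cl)
    }
    auroc(prob[, cl], pos)
  }, numeric(1))
  structure(mean(per, na.rm = TRUE), per_class = per)
}
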