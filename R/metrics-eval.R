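#' Per-class and averaged F1 scores
#'
#' F1 per class from the confusion matrix; macro is the unweighted mean over
#' classes (classes absent from both truth and prediction are excluded with a
#' warning); micro pools true/false positive and negative counts over
#' classes.
#'
#' @param truth,pred Character vectors of class labels.
#' @param classes Class vocabulary; defaults to the union of observed labels.
#' @return List with `per_class` (tibble `class`, `precision`, `recall`,
#'   `f1`), `macro`, `micro`.
#' @export
f1_scores <- function(truth, pred, classes = NULL) {
  assert_that(length(truth) == length(pred),
              "`truth` and `pred` must have equal length")
  classes <- classes %||% sort(union(truth, pred))
  tp <- fp <- fn <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp[i] <- sum(truth == k & pred == k)
    fp[i] <- sum(truth != k & pred == k)
    fn[i] <- sum(truth == k & pred != k)
  }
  f1 <- ifelse(2 * tp + fp + fn == 0, NA_real_, 2 * tp / (2 * tp + fp + fn))
  present <- (tp + fn) > 0 | (tp + fp) > 0
  if (any(!present)) {
    warn(paste0("class(es) absent from both truth and prediction excluded ",
                "from the macro mean: ",
                paste(classes[!present], collapse = ", ")))
  }
  per_class <- tibble(class = classes,
                      precision = ifelse(tp + fp == 0, NA_real_, tp / (tp + fp)),
                      recall = ifelse(tp + fn == 0, NA_real_, tp / (tp + fn)),
                      f1 = ifelse(present, ifelse(is.na(f1), 0, f1), NA_real_))
  micro <- 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  list(per_class = per_class,
       macro = mean(per_class$f1[present]),
       micro = micro)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise interpolation: with predictions sorted by decreasing score,
#' `AP = sum_k (R_k - R_{k-1}) P_k` over the distinct score thresholds.
#'
#' @param truth Binary vector (0/1).
#' @param scores Numeric prediction scores.
#' @return Average precision in [0, 1].
#' @export
average_precision <- function(truth, scores) {
  assert_that(length(truth) == length(scores),
              "`truth` and `scores` must have equal length")
  n_pos <- sum(truth == 1)
  assert_that(n_pos > 0, "no positive examples")
  ord <- order(scores, decreasing = TRUE)
  y <- truth[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}
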