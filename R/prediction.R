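#' Cautious classification with a reject option
#'
#' Retains a prediction only where the calibrated confidence
#' `max(p, 1 - p)` reaches the cutoff; below it the classifier abstains.
#' At cutoff 0.5 every point is retained, so coverage decreases
#' monotonically from 1 as the cutoff rises.
#'
#' @param probs probability vector (calibrated `p(link)` values).
#' @param cutoff confidence threshold in `[0.5, 1]`.
#' @return A tibble with columns `prob`, `predicted` (`+1` if `p >= 0.5`,
#'   else `-1`) and `retained`, plus attribute `coverage` (retained
#'   fraction).
#' @examples
#' cautious_predict(c(0.9, 0.6, 0.2), cutoff = 0.8)
#' @export
cautious_predict <- function(probs, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0.5 || cutoff > 1) {
    abort("`cutoff` must lie in [0.5, 1].", class = "kernlink_config_error")
  }
  conf <- pmax(probs, 1 - probs)
  out <- tibble::tibble(
    prob = probs,
    predicted = ifelse(probs >= 0.5, 1L, -1L),
    retained = conf >= cutoff)
  attr(out, "coverage") <- mean(out$retained)
  out
}

#' Accuracy/coverage trade-off across confidence cutoffs
#'
#' For each cutoff in the grid, computes the coverage (fraction of points
#' retained at that confidence) and the accuracy among retained points only.
#' Accuracy is `NA` when nothing is retained. This is the cautious
#' classification operating curve: raising the cutoff trades coverage for
#' accuracy.
#'
#' @param probs probability vector.
#' @param labels true labels in `{-1, +1}`.
#' @param cutoffs cutoff grid; default 0.50 to 0.99 in steps of 0.01 plus
#'   0.995 and 0.999.
#' @return A tibble of class `accuracy_coverage` with columns `cutoff`,
#'   `n_retained`, `coverage`, `accuracy`.
#' @export
accuracy_coverage_curve <- function(probs, labels,
                                    cutoffs = c(seq(0.5, 0.99, by = 0.01),
                                                0.995, 0.999)) {
  y <- as.integer(labels)
  stopifnot(length(probs) == length(y), all(y %in% c(-1L, 1L)))
  pred <- ifelse(probs >= 0.5, 1L, -1L)
  conf <- pmax(probs, 1 - probs)
  rows <- lapply(cutoffs, function(ct) {
    keep <- conf >= ct
    tibble::tibble(
      cutoff = ct,
      n_retained = sum(keep),
      coverage = mean(keep),
      accuracy = if (any(keep)) mean(pred[keep] == y[keep]) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accuracy_coverage", class(out))
  out
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) AUC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, ties counting one half.
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric scores (larger = more link-like).
#' @param labels true labels in `{-1, +1}`; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1L); n_neg <- sum(y == -1L)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to compute AUC.",
          class = "kernlink_data_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score candidate pairs with a model and calibration
#'
#' Combines the decision function, calibration and cautious cutoff into the
#' standard prediction table.
#'
#' @param model a `composite_model`.
#' @param cal an `svm_calibration`.
#' @param pairs a [pair_set()].
#' @param cutoff cautious confidence cutoff in `[0.5, 1]`.
#' @return A tibble with `pair_id`, `node_a`, `node_b`, `phi`, `prob`,
#'   `predicted`, `retained` (and `label` when `pairs` is labeled).
#' @export
score_pairs <- function(model, cal, pairs, cutoff = 0.5) {
  phi <- decision_function(model, pairs)
  prob <- predict_proba(cal, phi)
  cp <- cautious_predict(prob, cutoff)
  out <- tibble::tibble(
    pair_id = pair_ids(pairs),
    node_a = pairs$node_a, node_b = pairs$node_b,
    phi = phi, prob = prob,
    predicted = cp$predicted, retained = cp$retained)
  if (is_labeled(pairs)) out$label <- pairs$label
  out
}

#' Plot an accuracy/coverage curve
#'
#' @param object an `accuracy_coverage` tibble.
#' @param ... unused.
#' @return A ggplot: accuracy and coverage against the confidence cutoff.
#' @method autoplot accuracy_coverage
#' @export
autoplot.accuracy_coverage <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("accuracy", "coverage"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "confidence cutoff", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
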