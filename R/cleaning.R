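#' Centroid seed selection
#'
#' Picks the most central training pairs of each class as a reliable starting
#' set for sequential learning. Centrality is squared feature-space distance
#' to the class centroid, computed purely from the kernel:
#' \deqn{d^2(x) = K(x,x) - \frac{2}{n}\sum_j K(x, x_j)
#'       + \frac{1}{n^2}\sum_{j,k} K(x_j, x_k)}
#' with sums over same-class members.
#'
#' @param gram composite Gram matrix over the training pairs.
#' @param labels vector in `{-1, +1}`.
#' @param n_per_class how many seeds per class (default 10).
#' @return Integer vector of seed indices (ascending), `n_per_class` per
#'   class.
#' @export
centroid_seeds <- function(gram, labels, n_per_class = 10L) {
  y <- as.integer(labels)
  stopifnot(nrow(gram) == length(y))
  picks <- lapply(c(-1L, 1L), function(cl) {
    members <- which(y == cl)
    n <- length(members)
    if (n < n_per_class) {
      abort(sprintf("class %+d has %d members, fewer than n_per_class = %d",
                    cl, n, n_per_class),
            class = "kernlink_data_error")
    }
    sub <- gram[members, members, drop = FALSE]
    d2 <- diag(sub) - 2 * rowMeans(sub) + mean(sub)
    members[order(d2)[seq_len(n_per_class)]]
  })
  sort(unlist(picks))
}

# Shared plumbing: resolve the composite training Gram (and optional
# train-by-test cross Gram) for the cleaning routines. Weights come from a
# preliminary MKL fit on the full pool unless supplied.
cleaning_setup <- function(grams, labels, C, lambda, test_grams) {
  check_gram_list(grams)
  if (is.null(lambda)) {
    lambda <- if (length(grams) == 1) 1 else
      mkl_train(grams, labels, C = C)$weights
  }
  stopifnot(length(lambda) == length(grams))
  K <- weighted_composite(grams, lambda)
  psd <- validate_psd(K, tol = PSD_TOL)
  if (!psd$ok) {
    warn("composite Gram not PSD within tolerance; clipping eigenvalues at 0.")
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    K <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
    K <- (K + t(K)) / 2
  }
  cross <- if (!is.null(test_grams)) weighted_composite(test_grams, lambda)
  list(lambda = lambda, K = K, cross = cross)
}

test_error <- function(fit, cross, learned, test_labels) {
  phi <- drop(crossprod(cross[learned, , drop = FALSE],
                        fit$alphas * fit$labels)) + fit$bias
  mean(ifelse(phi >= 0, 1, -1) != test_labels)
}

new_cleaning_trace <- function(seed_indices, order, skipped, stop_index,
                               stop_fired, trace, final_model, stop_model,
                               lambda, error_at_stop = NA_real_,
                               error_at_full = NA_real_) {
  structure(list(seed_indices = seed_indices, order = order, skipped = skipped,
                 stop_index = stop_index, stop_fired = stop_fired,
                 trace = trace, final_model = final_model,
                 stop_model = stop_model, lambda = lambda,
                 error_at_stop = error_at_stop, error_at_full = error_at_full),
            class = "cleaning_trace")
}

#' Sequential learning by lowest confidence, with margin-band stopping
#'
#' Starting from the seed set, repeatedly trains an SVM on the points learned
#' so far, scores all unlearnt points, and learns the one with the smallest
#' decision magnitude `|phi|` (ties broken by lowest index). Points with
#' small `|phi|` are necessarily low-confidence, so potential outliers —
#' which the current model confidently contradicts — are deferred to the end
#' of the sequence. The stopping criterion fires the first time no unlearnt
#' point remains inside the margin band, i.e. `min |phi| > 1`: beyond that,
#' agreeing points would be non-support vectors (nothing to gain) and
#' disagreeing points sit deep on the wrong side (likely mislabeled).
#' Learning continues past the stop so the caller can compare the
#' stopped model with the fully trained one.
#'
#' @param grams list of base Gram matrices over the full training pool.
#' @param labels vector in `{-1, +1}` over the pool.
#' @param seeds integer indices of the seed set (must contain both classes);
#'   see [centroid_seeds()].
#' @param C positive box bound.
#' @param lambda optional simplex weights for the composite; defaults to a
#'   preliminary MKL fit on the full pool.
#' @param test_grams optional list of pool-by-test cross Grams (same base
#'   kernel order) for a per-step held-out error trace.
#' @param test_labels labels for the test pairs.
#' @param svm_tol KKT tolerance for the per-step solves.
#' @return A `cleaning_trace`: seed indices, learning `order`, `stop_index`
#'   (number of post-seed points learned when the margin band first emptied;
#'   equals `length(order)` if it never fired), per-step `trace` tibble,
#'   `stop_model` and `final_model` (each a list with `indices` and the
#'   `svm_fit`), and — when a test set is given — `error_at_stop` and
#'   `error_at_full`.
#' @export
clean_sequential <- function(grams, labels, seeds, C = 1, lambda = NULL,
                             test_grams = NULL, test_labels = NULL,
                             svm_tol = 1e-6) {
  y <- as.numeric(labels)
  setup <- cleaning_setup(grams, y, C, lambda, test_grams)
  K <- setup$K
  n <- length(y)
  stopifnot(all(seeds %in% seq_len(n)))
  if (length(unique(y[seeds])) < 2) {
    abort("seed set must contain both classes.", class = "kernlink_data_error")
  }
  learned <- sort(unique(seeds))
  unlearnt <- setdiff(seq_len(n), learned)
  stop_index <- NA_integer_
  stop_model <- NULL
  warm <- NULL
  rows <- list()
  step <- 0L
  fit <- NULL
  repeat {
    fit <- train_svm(K[learned, learned, drop = FALSE], y[learned], C = C,
                     tol = svm_tol, alpha0 = warm, check_psd = FALSE)
    err <- if (!is.null(setup$cross))
      test_error(fit, setup$cross, learned, test_labels) else NA_real_
    if (length(unlearnt) == 0) break
    phi <- drop(K[unlearnt, learned, drop = FALSE] %*%
                  (fit$alphas * y[learned])) + fit$bias
    if (is.na(stop_index) && min(abs(phi)) > 1) {
      stop_index <- step
      stop_model <- list(indices = learned, fit = fit, test_error = err)
    }
    pick <- which.min(abs(phi))            # first minimum = lowest index
    idx <- unlearnt[pick]
    step <- step + 1L
    rows[[step]] <- tibble::tibble(step = step, index = idx, action = "learn",
                                   abs_phi = abs(phi[pick]), prob = NA_real_,
                                   test_error = err)
    pos <- findInterval(idx, learned)
    warm <- append(fit$alphas, 0, after = pos)
    learned <- append(learned, idx, after = pos)
    unlearnt <- unlearnt[-pick]
  }
  if (is.na(stop_index)) {
    stop_fired <- FALSE
    stop_index <- step
    stop_model <- list(indices = learned, fit = fit,
                       test_error = if (!is.null(setup$cross))
                         test_error(fit, setup$cross, learned, test_labels)
                       else NA_real_)
  } else {
    stop_fired <- TRUE
  }
  final_err <- if (!is.null(setup$cross))
    test_error(fit, setup$cross, learned, test_labels) else NA_real_
  new_cleaning_trace(
    seed_indices = sort(unique(seeds)),
    order = vapply(rows, function(r) r$index, 0L),
    skipped = tibble::tibble(index = integer(0), prob = numeric(0)),
    stop_index = stop_index, stop_fired = stop_fired,
    trace = dplyr::bind_rows(rows),
    final_model = list(indices = learned, fit = fit, test_error = final_err),
    stop_model = stop_model, lambda = setup$lambda,
    error_at_stop = stop_model$test_error, error_at_full = final_err)
}

#' Random-order screening of suspect labels
#'
#' Cheaper alternative to lowest-confidence ordering: visit the non-seed
#' points in a seeded random order; before learning each point, predict its
#' label with the current model and calibration. If the prediction is
#' confident (`max(p, 1-p) >= threshold`) but disagrees with the recorded
#' label, the point is flagged as a potential outlier and skipped; otherwise
#' it is learned. The calibration is refitted every `recalibrate_every`
#' learned points.
#'
#' @inheritParams clean_sequential
#' @param threshold confidence required to skip a disagreeing point, in
#'   `(0.5, 1]`. At 1.0 nothing is ever skipped (probabilities are strictly
#'   inside `(0, 1)`).
#' @param seed RNG seed for the visiting order.
#' @param recalibrate_every refit the sigmoid after this many learned points.
#' @param platt_targets passed to [fit_sigmoid()]. Defaults to `TRUE` here
#'   (unlike [fit_sigmoid()] itself): the screen's calibration is fit on the
#'   learned set's own margins, which an SVM keeps near-separated, and raw
#'   0/1 targets then drive the sigmoid slope to its cap so every
#'   disagreement looks maximally confident; Platt's regularized targets
#'   keep the confidence finite and the skip rule selective.
#' @return A `cleaning_trace`; `skipped` is a tibble of flagged indices with
#'   the confident probability that triggered the skip.
#' @export
clean_random_screen <- function(grams, labels, seeds, C = 1, threshold = 0.95,
                                seed = 1L, lambda = NULL,
                                recalibrate_every = 25L,
                                platt_targets = TRUE,
                                test_grams = NULL, test_labels = NULL,
                                svm_tol = 1e-6) {
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must lie in (0.5, 1].", class = "kernlink_config_error")
  }
  y <- as.numeric(labels)
  setup <- cleaning_setup(grams, y, C, lambda, test_grams)
  K <- setup$K
  n <- length(y)
  if (length(unique(y[seeds])) < 2) {
    abort("seed set must contain both classes.", class = "kernlink_data_error")
  }
  learned <- sort(unique(seeds))
  visit <- with_local_seed(seed, sample(setdiff(seq_len(n), learned)))
  fit <- train_svm(K[learned, learned, drop = FALSE], y[learned], C = C,
                   tol = svm_tol, check_psd = FALSE)
  refit_cal <- function(fit, learned) {
    suppressWarnings(fit_sigmoid(fit$decision, y[learned],
                                 platt_targets = platt_targets))
  }
  cal <- refit_cal(fit, learned)
  since_recal <- 0L
  rows <- list()
  skipped <- list()
  order_learned <- integer(0)
  step <- 0L
  for (idx in visit) {
    step <- step + 1L
    phi <- sum(K[idx, learned] * (fit$alphas * y[learned])) + fit$bias
    p <- predict_proba(cal, phi)
    conf <- max(p, 1 - p)
    predicted <- if (p >= 0.5) 1 else -1
    err <- if (!is.null(setup$cross))
      test_error(fit, setup$cross, learned, test_labels) else NA_real_
    if (conf >= threshold && predicted != y[idx]) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(index = idx, prob = p)
      rows[[step]] <- tibble::tibble(step = step, index = idx, action = "skip",
                                     abs_phi = abs(phi), prob = p,
                                     test_error = err)
      next
    }
    rows[[step]] <- tibble::tibble(step = step, index = idx, action = "learn",
                                   abs_phi = abs(phi), prob = p,
                                   test_error = err)
    pos <- findInterval(idx, learned)
    warm <- append(fit$alphas, 0, after = pos)
    learned <- append(learned, idx, after = pos)
    order_learned <- c(order_learned, idx)
    fit <- train_svm(K[learned, learned, drop = FALSE], y[learned], C = C,
                     tol = svm_tol, alpha0 = warm, check_psd = FALSE)
    since_recal <- since_recal + 1L
    if (since_recal >= recalibrate_every) {
      cal <- refit_cal(fit, learned)
      since_recal <- 0L
    }
  }
  final_err <- if (!is.null(setup$cross))
    test_error(fit, setup$cross, learned, test_labels) else NA_real_
  skipped_tbl <- if (length(skipped)) dplyr::bind_rows(skipped)
    else tibble::tibble(index = integer(0), prob = numeric(0))
  new_cleaning_trace(
    seed_indices = sort(unique(seeds)),
    order = order_learned,
    skipped = skipped_tbl,
    stop_index = length(order_learned), stop_fired = FALSE,
    trace = dplyr::bind_rows(rows),
    final_model = list(indices = learned, fit = fit, test_error = final_err),
    stop_model = list(indices = learned, fit = fit, test_error = final_err),
    lambda = setup$lambda,
    error_at_stop = final_err, error_at_full = final_err)
}

#' @export
print.cleaning_trace <- function(x, ...) {
  cat(sprintf(
    "<cleaning_trace: %d seeds, %d learned, %d skipped, stop at %d%s>\n",
    length(x$seed_indices), length(x$order), nrow(x$skipped), x$stop_index,
    if (x$stop_fired) " (margin band emptied)" else ""))
  if (!is.na(x$error_at_stop)) {
    cat(sprintf("held-out error: %.4f at stop, %.4f at full\n",
                x$error_at_stop, x$error_at_full))
  }
  invisible(x)
}

#' Indices never learned before the margin-band stop
#'
#' @param trace a `cleaning_trace` from [clean_sequential()].
#' @return Integer vector: the training-pool indices still unlearnt when the
#'   stopping criterion fired (empty if it never fired).
#' @export
unlearnt_at_stop <- function(trace) {
  stopifnot(inherits(trace, "cleaning_trace"))
  if (trace$stop_index >= length(trace$order)) return(integer(0))
  trace$order[(trace$stop_index + 1L):length(trace$order)]
}

#' Write a cleaning trace as TSV
#'
#' Columns: step, index, action (learn/skip), `|phi|`, probability and the
#' cumulative held-out error when available.
#'
#' @param trace a `cleaning_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_trace <- function(trace, path) {
  write.table(as.data.frame(trace$trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Plot a cleaning error trace
#'
#' @param object a `cleaning_trace` with a held-out error trace.
#' @param ... unused.
#' @return A ggplot of held-out error against learning step, with the
#'   margin-band stop marked.
#' @method autoplot cleaning_trace
#' @export
autoplot.cleaning_trace <- function(object, ...) {
  df <- object$trace[!is.na(object$trace$test_error), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$test_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "learning step", y = "held-out error") +
    ggplot2::theme_minimal()
  if (object$stop_fired) {
    p <- p + ggplot2::geom_vline(xintercept = object$stop_index,
                                 linetype = "dashed")
  }
  p
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
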