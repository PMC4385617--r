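#' Uniformly weighted composite kernel
#'
#' The baseline against which learned kernel weights are compared: the plain
#' mean of the base Gram matrices, i.e. equal simplex weights `1/p`.
#'
#' @param grams list of numeric matrices with identical dimensions.
#' @return A numeric matrix.
#' @export
uniform_composite <- function(grams) {
  check_gram_list(grams)
  Reduce(`+`, grams) / length(grams)
}

check_gram_list <- function(grams) {
  if (!is.list(grams) || length(grams) == 0) {
    abort("`grams` must be a nonempty list of matrices.",
          class = "kernlink_config_error")
  }
  d <- dim(grams[[1]])
  ok <- vapply(grams, function(g) is.matrix(g) && identical(dim(g), d), TRUE)
  if (!all(ok)) {
    abort("all Gram matrices must share the same dimensions.",
          class = "kernlink_config_error")
  }
  invisible(d)
}

#' Weighted composite kernel
#'
#' Linear combination \eqn{\bar K = \sum_\ell \lambda_\ell \hat K_\ell} of
#' base Gram matrices.
#'
#' @param grams list of numeric matrices with identical dimensions.
#' @param weights numeric weights, one per Gram.
#' @return A numeric matrix.
#' @export
weighted_composite <- function(grams, weights) {
  out <- grams[[1]] * weights[1]
  for (l in seq_along(grams)[-1]) out <- out + grams[[l]] * weights[l]
  out
}

#' Multiple kernel learning over a simplex of base kernels
#'
#' Learns a composite kernel \eqn{\bar K = \sum_\ell \lambda_\ell \hat K_\ell}
#' with weights on the probability simplex
#' (\eqn{\sum_\ell \lambda_\ell = 1, \lambda_\ell \ge 0}) jointly with the SVM
#' dual coefficients, by minimizing over \eqn{\lambda} the maximized SVM dual
#' objective. The outer problem is solved by reduced-gradient descent in the
#' style of SimpleMKL: each iterate solves the SVM exactly on the current
#' composite (warm-started), takes a descent direction projected onto the
#' simplex and backtracks until the objective decreases. By Danskin's theorem
#' the objective gradient is
#' \eqn{\partial W/\partial \lambda_\ell = -\tfrac12 (\alpha y)^\top \hat K_\ell (\alpha y)}.
#'
#' Convergence is declared when the relative duality gap
#' \eqn{(\max_\ell S_\ell - \sum_\ell \lambda_\ell S_\ell)/|W|} with
#' \eqn{S_\ell = \tfrac12 (\alpha y)^\top \hat K_\ell (\alpha y)} drops below
#' `tol`, or when the weight step falls below `1e-6`. Weights below `1e-4`
#' are zeroed and the remainder renormalized, matching the sparse weight
#' patterns this method is known for.
#'
#' @param grams list of base Gram matrices over the same training pairs.
#' @param labels vector in `{-1, +1}`.
#' @param C positive box bound for the SVM dual.
#' @param tol relative duality-gap tolerance.
#' @param max_iter outer iteration cap; exceeding it is an error carrying the
#'   last gap.
#' @param svm_tol KKT tolerance passed to the inner [train_svm()] solves.
#' @param verbose emit one message per outer iteration (objective, gap,
#'   number of active weights).
#' @return A list of class `mkl_fit`: `weights`, `alphas`, `bias`,
#'   `objective`, `C`, `trace` (tibble with one row per outer iteration),
#'   `converged`.
#' @examples
#' g <- tcrossprod(matrix(rnorm(40), 10))
#' fit <- mkl_train(list(g), c(rep(1, 5), rep(-1, 5)))
#' fit$weights  # single kernel: weight 1
#' @export
mkl_train <- function(grams, labels, C = 1, tol = 1e-4, max_iter = 200L,
                      svm_tol = 1e-6, verbose = FALSE) {
  check_gram_list(grams)
  p <- length(grams)
  y <- as.numeric(labels)
  lambda <- rep(1 / p, p)
  alpha <- NULL
  trace <- vector("list", max_iter)
  evaluate <- function(lam, warm) {
    fit <- train_svm(weighted_composite(grams, lam), y, C = C, tol = svm_tol,
                     alpha0 = warm, check_psd = FALSE)
    ay <- fit$alphas * y
    S <- vapply(grams, function(g) 0.5 * sum(ay * drop(g %*% ay)), 0)
    list(fit = fit, S = S, objective = fit$objective)
  }
  ev <- evaluate(lambda, NULL)
  gap <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    S <- ev$S
    gap <- (max(S) - sum(lambda * S)) / max(abs(ev$objective), 1e-12)
    n_active <- sum(lambda > 0)
    trace[[iter]] <- tibble::tibble(iteration = iter, objective = ev$objective,
                                    gap = gap, n_active = n_active)
    if (verbose) {
      message(sprintf("mkl iter %d: objective %.8g gap %.3g active %d",
                      iter, ev$objective, gap, n_active))
    }
    if (p == 1 || gap <= tol) { converged <- TRUE; break }
    # reduced gradient on the simplex, anchored at the largest weight
    g <- -S                       # d objective / d lambda
    mu <- which.max(lambda)
    d <- -(g - g[mu])
    d[lambda <= 0 & d < 0] <- 0
    d[mu] <- -sum(d[-mu])
    if (max(abs(d)) < 1e-12) { converged <- TRUE; break }
    shrink <- d < 0
    step_max <- if (any(shrink)) min(lambda[shrink] / -d[shrink]) else 1
    step <- step_max
    accepted <- FALSE
    for (ls in 1:30) {
      lam_new <- pmax(lambda + step * d, 0)
      lam_new <- lam_new / sum(lam_new)
      ev_new <- evaluate(lam_new, ev$fit$alphas)
      if (ev_new$objective < ev$objective - 1e-12 * abs(ev$objective)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted || max(abs(lam_new - lambda)) <= 1e-6) {
      lambda <- if (accepted) lam_new else lambda
      ev <- if (accepted) ev_new else ev
      converged <- TRUE
      break
    }
    lambda <- lam_new
    ev <- ev_new
  }
  if (!converged) {
    abort(sprintf("MKL did not converge in %d iterations (last relative gap %.3g)",
                  max_iter, gap),
          class = "kernlink_convergence_error")
  }
  # sparsify tiny weights and refit on the cleaned simplex
  keep <- lambda >= 1e-4
  if (!all(keep)) {
    lambda[!keep] <- 0
    lambda <- lambda / sum(lambda)
    ev <- evaluate(lambda, ev$fit$alphas)
  }
  structure(list(weights = lambda, alphas = ev$fit$alphas, bias = ev$fit$bias,
                 objective = ev$objective, C = C, labels = y,
                 trace = dplyr::bind_rows(trace[seq_len(iter)]),
                 converged = converged),
            class = "mkl_fit")
}

#' @export
print.mkl_fit <- function(x, ...) {
  cat(sprintf("<mkl_fit: p = %d base kernels, %d active, objective = %.6g>\n",
              length(x$weights), sum(x$weights > 0), x$objective))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Fit a composite link-prediction model
#'
#' High-level wrapper tying the pieces together: builds the pairwise base
#' Gram matrices from the given base-kernel specifications and the labeled
#' training pairs, runs [mkl_train()], and returns a model that can score new
#' candidate pairs with [decision_function()].
#'
#' @param specs list of [base_kernel_spec()] objects (the base kernels:
#'   pairwise kind x data kernel).
#' @param train_pairs labeled [pair_set()].
#' @param C positive box bound.
#' @param tol MKL relative duality-gap tolerance.
#' @param normalize cosine-normalize each node kernel before building
#'   pairwise Grams (recommended; puts heterogeneous data on equal footing).
#' @param block_size row block size for Gram assembly.
#' @param ... further arguments passed to [mkl_train()].
#' @return A list of class `composite_model`: the `mkl_fit` elements plus
#'   `specs`, `train_pairs` and `normalize`.
#' @export
fit_link_model <- function(specs, train_pairs, C = 1, tol = 1e-4,
                           normalize = TRUE, block_size = 1024L, ...) {
  stopifnot(is.list(specs), length(specs) >= 1)
  if (!is_labeled(train_pairs)) {
    abort("`train_pairs` must carry labels.", class = "kernlink_data_error")
  }
  if (normalize) {
    specs <- lapply(specs, function(s)
      base_kernel_spec(s$kind, normalize_kernel(s$kernel)))
  }
  grams <- base_grams(specs, train_pairs, block_size = block_size)
  fit <- mkl_train(grams, train_pairs$label, C = C, tol = tol, ...)
  structure(c(unclass(fit),
              list(specs = specs, train_pairs = train_pairs,
                   normalize = normalize)),
            class = c("composite_model", "mkl_fit"))
}

#' Decision values for candidate pairs
#'
#' Evaluates the composite decision function
#' \eqn{\phi(z) = \sum_j \alpha_j y_j \bar K(x_j, z) + b} for new node pairs,
#' assembling the weighted cross-Gram between training and test pairs on the
#' fly from the model's base-kernel specifications. The predicted label is
#' `sign(phi)` with 0 mapped to `+1`.
#'
#' @param model a `composite_model` from [fit_link_model()].
#' @param test_pairs a [pair_set()] of candidate pairs.
#' @return A numeric vector of decision values, one per test pair.
#' @export
decision_function <- function(model, test_pairs) {
  stopifnot(inherits(model, "composite_model"))
  ay <- model$alphas * model$labels
  phi <- rep(model$bias, nrow(test_pairs))
  active <- which(model$weights > 0)
  for (l in active) {
    s <- model$specs[[l]]
    cross <- pairwise_gram(s$kind, s$kernel, model$train_pairs, test_pairs)
    phi <- phi + model$weights[l] * drop(crossprod(cross, ay))
  }
  phi
}

#' Predicted link labels
#'
#' @param object a `composite_model`.
#' @param pairs a [pair_set()] of candidate pairs.
#' @param ... unused.
#' @return Integer vector in `{-1, +1}`: `sign(phi)` with 0 mapped to `+1`.
#' @export
predict.composite_model <- function(object, pairs, ...) {
  phi <- decision_function(object, pairs)
  ifelse(phi >= 0, 1L, -1L)
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model: %d base kernels (%d active), %d training pairs, C = %g>\n",
              length(x$weights), sum(x$weights > 0), nrow(x$train_pairs), x$C))
  w <- tidy.mkl_fit(x)
  print(w[w$weight > 0, ])
  invisible(x)
}

#' Tidy the learned kernel weights
#'
#' @param x an `mkl_fit` or `composite_model`.
#' @param ... unused.
#' @return A tibble with one row per base kernel: `base_kernel` label (when
#'   specs are attached), `kind`, `data_kernel` and `weight`.
#' @method tidy mkl_fit
#' @export
tidy.mkl_fit <- function(x, ...) {
  p <- length(x$weights)
  if (!is.null(x$specs)) {
    tibble::tibble(
      base_kernel = vapply(x$specs, spec_label, ""),
      kind = vapply(x$specs, function(s) s$kind, ""),
      data_kernel = vapply(x$specs, function(s)
        if (is.null(s$kernel$name)) NA_character_ else s$kernel$name, ""),
      weight = x$weights)
  } else {
    tibble::tibble(base_kernel = paste0("gram_", seq_len(p)), weight = x$weights)
  }
}

#' One-row model summary
#'
#' @param x an `mkl_fit` or `composite_model`.
#' @param ... unused.
#' @return A one-row tibble: number of base kernels, active kernels, support
#'   vectors, objective, bias, C and convergence flag.
#' @method glance mkl_fit
#' @export
glance.mkl_fit <- function(x, ...) {
  tibble::tibble(
    n_base = length(x$weights),
    n_active = sum(x$weights > 0),
    n_train = length(x$alphas),
    n_support = sum(x$alphas > 1e-8 * x$C),
    objective = x$objective,
    bias = x$bias,
    C = x$C,
    iterations = nrow(x$trace),
    converged = x$converged)
}
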