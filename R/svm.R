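#' Train a support vector machine on a precomputed kernel
#'
#' Solves the standard soft-margin SVM dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'       y_i y_j K_{ij}
#'   \quad \text{s.t.}\; \sum_i \alpha_i y_i = 0,\; 0 \le \alpha_i \le C}
#' by sequential minimal optimization with maximal-violating-pair working-set
#' selection. The solver is deterministic and accepts a warm start, which the
#' sequential data-cleaning routines rely on.
#'
#' The bias is set by the midpoint rule: with bias-free decision values
#' \eqn{f_i = \sum_j \alpha_j y_j K_{ij}},
#' \deqn{b = -\tfrac12\left[\max_{i: y_i = -1} f_i + \min_{i: y_i = +1} f_i\right].}
#' Ties take the first occurrence in training order.
#'
#' @param gram symmetric PSD kernel matrix over the training points.
#' @param labels vector in `{-1, +1}`, length `nrow(gram)`; both classes must
#'   be present.
#' @param C positive box bound on the dual coefficients.
#' @param tol KKT violation tolerance (stopping rule on the maximal
#'   violating pair).
#' @param alpha0 optional feasible warm-start vector.
#' @param max_iter iteration cap.
#' @param check_psd validate the Gram eigenvalues first; if it fails the
#'   tolerance, warn and solve the convexified problem with eigenvalues
#'   clipped at zero.
#' @return A list of class `svm_fit`: `alphas`, `bias`, `objective`,
#'   `decision` (training decision values including bias), `labels`, `C`,
#'   `iterations`.
#' @examples
#' fit <- train_svm(diag(2), c(1, -1), C = 10)
#' fit$alphas  # both points are support vectors with alpha = 1
#' @export
train_svm <- function(gram, labels, C = 1, tol = 1e-6, alpha0 = NULL,
                      max_iter = 500000L, check_psd = TRUE) {
  n <- length(labels)
  stopifnot(is.matrix(gram), nrow(gram) == n, ncol(gram) == n, C > 0)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) {
    abort("labels must be -1 or +1.", class = "kernlink_data_error")
  }
  if (length(unique(y)) < 2) {
    abort("both classes must be present to train an SVM.",
          class = "kernlink_data_error")
  }
  if (check_psd) {
    psd <- validate_psd(gram, tol = PSD_TOL)
    if (!psd$ok) {
      warn(sprintf(
        "Gram is not PSD within tolerance (min eig %.3g); clipping eigenvalues at 0.",
        psd$min_eigenvalue))
      eg <- eigen((gram + t(gram)) / 2, symmetric = TRUE)
      gram <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
      gram <- (gram + t(gram)) / 2
    }
  }
  res <- smo_solve(gram, y, C, tol, alpha0, max_iter)
  alpha <- res$alpha
  f <- drop(gram %*% (alpha * y))
  bias <- midpoint_bias(f, y, alpha, C)
  objective <- sum(alpha) - 0.5 * sum((alpha * y) * f)
  structure(list(alphas = alpha, bias = bias, objective = objective,
                 decision = f + bias, labels = y, C = C,
                 iterations = res$iterations, converged = res$converged),
            class = "svm_fit")
}

# Midpoint of the KKT-feasible bias interval: candidates are the usual
# up/low sets (negatives that could still grow their alpha enter the max,
# symmetrically for the min). On separable data every negative is an up
# candidate and every positive a low candidate, and this reduces to
# -(max_neg f + min_pos f)/2 — the hard-margin midpoint rule. Restricting to
# the candidate sets is what keeps the bias KKT-consistent once bounded
# support vectors (label noise) appear. First occurrence wins ties.
midpoint_bias <- function(f, y, alpha, C) {
  eps <- 1e-12 * C
  up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
  lo <- (y < 0 & alpha < C - eps) | (y > 0 & alpha > eps)
  if (!any(up) || !any(lo)) return(-0.5 * (max(f[y == -1]) + min(f[y == 1])))
  vals <- y - f
  (max(vals[up]) + min(vals[lo])) / 2
}

#' Midpoint bias for a trained dual solution
#'
#' Recomputes the decision-function offset from dual coefficients and a
#' composite Gram: the midpoint of the KKT-feasible bias interval, which on
#' separable data equals minus half the sum of the largest bias-free decision
#' value among negative training points and the smallest among positive ones.
#'
#' @param gram kernel matrix over the training points.
#' @param labels vector in `{-1, +1}`.
#' @param alphas dual coefficients.
#' @param C box bound the model was trained with.
#' @return The scalar bias.
#' @export
compute_bias <- function(gram, labels, alphas, C = max(alphas)) {
  y <- as.numeric(labels)
  midpoint_bias(drop(gram %*% (alphas * y)), y, alphas, C)
}

# SMO core. Minimizes 1/2 a'Qa - e'a with Q = (y y') * K subject to y'a = 0,
# 0 <= a <= C, selecting the maximal violating pair at each step. The
# two-variable subproblem moves along u = y_i e_i - y_j e_j, which keeps the
# equality constraint satisfied; its curvature is K_ii + K_jj - 2 K_ij >= 0
# for a PSD K (a floor guards semi-definite directions).
smo_solve <- function(K, y, C, tol, alpha0, max_iter) {
  n <- length(y)
  if (is.null(alpha0)) {
    alpha <- numeric(n)
    grad <- rep(-1, n)               # Q a - e at a = 0
  } else {
    stopifnot(length(alpha0) == n)
    alpha <- pmin(pmax(alpha0, 0), C)
    if (abs(sum(alpha * y)) > 1e-10 * max(1, C)) {
      # project the warm start back onto the equality constraint
      alpha <- alpha - y * (sum(alpha * y) / n)
      alpha <- pmin(pmax(alpha, 0), C)
      if (abs(sum(alpha * y)) > 1e-8 * max(1, C)) alpha <- numeric(n)
    }
    grad <- drop(K %*% (alpha * y)) * y - 1
  }
  it <- 0L
  converged <- FALSE
  eps_active <- 1e-12 * C
  repeat {
    it <- it + 1L
    yg <- -y * grad
    up <- (y > 0 & alpha < C - eps_active) | (y < 0 & alpha > eps_active)
    lo <- (y < 0 & alpha < C - eps_active) | (y > 0 & alpha > eps_active)
    if (!any(up) || !any(lo)) { converged <- TRUE; break }
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    if (yg[i] - yg[j] <= tol) { converged <- TRUE; break }
    if (it > max_iter) break
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    delta <- (yg[i] - yg[j]) / quad
    # box limits along the feasible direction
    lim_i <- if (y[i] > 0) c(-alpha[i], C - alpha[i]) else c(alpha[i] - C, alpha[i])
    lim_j <- if (y[j] > 0) c(alpha[j] - C, alpha[j]) else c(-alpha[j], C - alpha[j])
    delta <- min(delta, lim_i[2], lim_j[2])
    delta <- max(delta, lim_i[1], lim_j[1])
    if (delta == 0) { converged <- TRUE; break }
    alpha[i] <- alpha[i] + y[i] * delta
    alpha[j] <- alpha[j] - y[j] * delta
    grad <- grad + delta * (y * (K[, i] - K[, j]))
  }
  if (!converged) {
    warn(sprintf("SMO hit the iteration cap (%d) before reaching tol %.1e", max_iter, tol))
  }
  list(alpha = pmin(pmax(alpha, 0), C), iterations = it, converged = converged)
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit: n = %d, C = %g, support vectors = %d, objective = %.6g>\n",
              length(x$alphas), x$C, sum(x$alphas > 1e-8 * x$C), x$objective))
  invisible(x)
}
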