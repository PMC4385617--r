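# Shared fixtures and independent oracles. Everything is generated in code
# under explicit seeds; oracles deliberately avoid the code paths they check.

library(kernlab)

# random PSD kernel over n named nodes (Gram of random feature vectors)
rand_psd_kernel <- function(n, dim = n + 2, seed = 1, jitter = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * dim), n)
  node_kernel(tcrossprod(X) + jitter * diag(n),
              sprintf("v%02d", seq_len(n)))
}

# random canonical pair set over the first m nodes of a kernel
rand_pairs <- function(k, n_pairs, seed = 1, labels = FALSE) {
  m <- length(k$node_ids)
  all_pairs <- t(combn(m, 2))
  set.seed(seed)
  take <- all_pairs[sample(nrow(all_pairs), n_pairs), , drop = FALSE]
  lab <- if (labels) sample(c(-1L, 1L), n_pairs, replace = TRUE) else NULL
  pair_set(k$node_ids[take[, 1]], k$node_ids[take[, 2]], label = lab)
}

# explicit feature-space oracles for the pairwise kernels, given the raw
# feature matrix X whose linear kernel is the base kernel
oracle_pairwise <- function(kind, X, pa, pb) {
  a <- X[pa[1], ]; b <- X[pa[2], ]; cc <- X[pb[1], ]; d <- X[pb[2], ]
  switch(kind,
    P1 = {
      f1 <- as.vector(outer(a, b) + outer(b, a)) / sqrt(2)
      f2 <- as.vector(outer(cc, d) + outer(d, cc)) / sqrt(2)
      sum(f1 * f2)
    },
    P2 = sum((a + b) * (cc + d)),
    P3 = {
      d1 <- a - b; d2 <- cc - d
      sum(as.vector(outer(d1, d1)) * as.vector(outer(d2, d2)))
    },
    P4 = {
      d1 <- a - b; d2 <- cc - d
      sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
    })
}

# reference SVM dual solution from a generic interior-point QP solver
qp_svm_oracle <- function(K, y, C) {
  n <- length(y)
  H <- outer(y, y) * K
  fit <- kernlab::ipop(c = -rep(1, n), H = H, A = t(y), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0, sigf = 10)
  alpha <- kernlab::primal(fit)
  list(alpha = alpha,
       decision = drop(K %*% (alpha * y)),
       objective = sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y))))
}

# brute-force Mann-Whitney AUC over all positive x negative comparisons
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# dense grid search over simplex weights: returns the minimum over lambda of
# the maximized SVM dual, by exact solves at each grid point
mkl_grid_oracle <- function(grams, labels, C, step = 0.1) {
  p <- length(grams)
  grid1 <- seq(0, 1, by = step)
  best <- NULL
  lams <- if (p == 2) {
    lapply(grid1, function(a) c(a, 1 - a))
  } else if (p == 3) {
    out <- list()
    for (a in grid1) for (b in grid1) {
      if (a + b <= 1 + 1e-12) out <- c(out, list(c(a, b, 1 - a - b)))
    }
    out
  } else stop("oracle supports p in {2, 3}")
  warm <- NULL
  for (lam in lams) {
    K <- Reduce(`+`, Map(`*`, grams, lam))
    fit <- train_svm(K, labels, C = C, check_psd = FALSE, alpha0 = warm)
    warm <- fit$alphas
    if (is.null(best) || fit$objective < best$objective) {
      best <- list(lambda = lam, objective = fit$objective)
    }
  }
  best
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected), 1e-300), tol)
}
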