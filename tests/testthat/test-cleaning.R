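# small planted-noise benchmark reused across the cleaning tests
cleaning_fixture <- function(seed = 11, n_pairs = 260, flip = 0.1) {
  ds <- simulate_linkdata(n_nodes = 80, n_pairs = n_pairs,
                          flip_fraction = flip, seed = seed)
  n_tr <- floor(0.8 * n_pairs)
  tr <- ds$pairs[seq_len(n_tr), ]
  te <- ds$pairs[(n_tr + 1):n_pairs, ]
  k <- ds$kernels[[1]]
  list(ds = ds, tr = tr, te = te,
       g_tr = list(pairwise_gram("P1", k, tr)),
       g_te = list(pairwise_gram("P1", k, tr, te)),
       flipped = which(seq_len(n_tr) %in% ds$flipped))
}

test_that("centroid seeds minimize the kernel-space centroid distance", {
  # explicit feature-space oracle for a linear kernel
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 3), 20), matrix(rnorm(40, -3), 20))
  K <- tcrossprod(X)
  y <- c(rep(1, 20), rep(-1, 20))
  seeds <- centroid_seeds(K, y, n_per_class = 5)
  for (cl in c(-1, 1)) {
    members <- which(y == cl)
    centroid <- colMeans(X[members, ])
    d2 <- rowSums((X[members, ] - rep(centroid, each = 20))^2)
    want <- members[order(d2)[1:5]]
    expect_setequal(intersect(seeds, members), want)
  }
  # well-separated classes: every seed carries its own class label
  expect_true(all(abs(y[seeds]) == 1))
  expect_equal(sum(y[seeds] == 1), 5)

  # n_per_class equal to the class size returns everything
  expect_setequal(centroid_seeds(K, y, n_per_class = 20), 1:40)
  expect_error(centroid_seeds(K, y, n_per_class = 21), "fewer",
               class = "kernlink_data_error")
})

test_that("sequential learning traces are deterministic and partition the pool", {
  fx <- cleaning_fixture()
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label)
  t1 <- clean_sequential(fx$g_tr, fx$tr$label, seeds, C = 10, lambda = 1)
  t2 <- clean_sequential(fx$g_tr, fx$tr$label, seeds, C = 10, lambda = 1)
  expect_identical(t1$order, t2$order)
  expect_identical(t1$stop_index, t2$stop_index)
  expect_equal(t1$trace, t2$trace)
  expect_setequal(c(t1$seed_indices, t1$order, t1$skipped$index),
                  seq_len(nrow(fx$tr)))
  expect_lte(t1$stop_index, length(t1$order))
})

test_that("the margin band is empty at the stop point", {
  fx <- cleaning_fixture()
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label)
  tr <- clean_sequential(fx$g_tr, fx$tr$label, seeds, C = 10, lambda = 1)
  expect_true(tr$stop_fired)
  sm <- tr$stop_model
  un <- unlearnt_at_stop(tr)
  phi <- drop(fx$g_tr[[1]][un, sm$indices, drop = FALSE] %*%
                (sm$fit$alphas * fx$tr$label[sm$indices])) + sm$fit$bias
  expect_gt(min(abs(phi)), 1)
})

test_that("per-step models equal a cold re-solve on the same learned set", {
  fx <- cleaning_fixture(n_pairs = 120)
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label)
  tr <- clean_sequential(fx$g_tr, fx$tr$label, seeds, C = 1, lambda = 1)
  learned <- tr$final_model$indices
  cold <- train_svm(fx$g_tr[[1]][learned, learned], fx$tr$label[learned],
                    C = 1, check_psd = FALSE)
  warm_fit <- tr$final_model$fit
  K <- fx$g_tr[[1]][learned, learned]
  expect_lt(max(abs(drop(K %*% (warm_fit$alphas * fx$tr$label[learned])) -
                    drop(K %*% (cold$alphas * fx$tr$label[learned])))), 1e-5)
})

test_that("on clean data the stop costs at most a point of held-out error", {
  fx <- cleaning_fixture(seed = 21, flip = 0)
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label)
  tr <- clean_sequential(fx$g_tr, fx$tr$label, seeds, C = 10, lambda = 1,
                         test_grams = fx$g_te, test_labels = fx$te$label)
  expect_lte(tr$error_at_stop, tr$error_at_full + 0.01)
})

test_that("random screening with an unreachable threshold learns everything", {
  fx <- cleaning_fixture(n_pairs = 120)
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label)
  scr <- clean_random_screen(fx$g_tr, fx$tr$label, seeds, C = 1,
                             threshold = 1.0, seed = 99, lambda = 1)
  expect_equal(nrow(scr$skipped), 0)
  expect_setequal(c(scr$seed_indices, scr$order), seq_len(nrow(fx$tr)))
  # same data, same seed: identical trace
  scr2 <- clean_random_screen(fx$g_tr, fx$tr$label, seeds, C = 1,
                              threshold = 1.0, seed = 99, lambda = 1)
  expect_identical(scr$order, scr2$order)
})

test_that("random screening flags nothing on clean well-separated data", {
  ds <- simulate_linkdata(n_nodes = 80, n_pairs = 200, p_in = 1, p_out = 0,
                          informativeness = c(0.9), flip_fraction = 0,
                          seed = 31)
  g <- list(pairwise_gram("P1", ds$kernels[[1]], ds$pairs))
  seeds <- centroid_seeds(g[[1]], ds$pairs$label)
  scr <- clean_random_screen(g, ds$pairs$label, seeds, C = 1,
                             threshold = 0.95, seed = 7, lambda = 1)
  expect_equal(nrow(scr$skipped), 0L)
})

test_that("screening flags planted flips with useful precision", {
  fx <- cleaning_fixture(seed = 11)
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label)
  scr <- clean_random_screen(fx$g_tr, fx$tr$label, seeds, C = 1,
                             threshold = 0.95, seed = 13, lambda = 1)
  expect_gt(nrow(scr$skipped), 0)
  expect_gte(mean(scr$skipped$index %in% fx$flipped), 0.5)
})

test_that("threshold bounds are validated", {
  fx <- cleaning_fixture(n_pairs = 60)
  seeds <- centroid_seeds(fx$g_tr[[1]], fx$tr$label, n_per_class = 5)
  expect_error(clean_random_screen(fx$g_tr, fx$tr$label, seeds,
                                   threshold = 0.5),
               "threshold", class = "kernlink_config_error")
})
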