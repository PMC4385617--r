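make_instance <- function(n, p, seed, informative = TRUE) {
  set.seed(seed)
  y <- sample(rep(c(-1, 1), n / 2))
  grams <- lapply(seq_len(p), function(l) {
    X <- matrix(rnorm(n * 5), n)
    if (informative && l == 1) X[, 1] <- X[, 1] + 2 * y
    tcrossprod(X) / n
  })
  list(grams = grams, y = y)
}

test_that("single-kernel MKL reduces to the plain SVM", {
  inst <- make_instance(20, 1, seed = 1)
  mkl <- mkl_train(inst$grams, inst$y, C = 1)
  svm <- train_svm(inst$grams[[1]], inst$y, C = 1)
  expect_equal(mkl$weights, 1)
  expect_equal(mkl$alphas, svm$alphas, tolerance = 1e-8)
  expect_equal(mkl$objective, svm$objective, tolerance = 1e-10)
})

test_that("the objective is invariant under duplicated base kernels", {
  inst <- make_instance(24, 1, seed = 2)
  single <- mkl_train(inst$grams, inst$y, C = 1)
  dup <- mkl_train(c(inst$grams, inst$grams), inst$y, C = 1)
  expect_equal(dup$objective, single$objective, tolerance = 1e-6)
})

test_that("fitted models satisfy the simplex, box and equality invariants", {
  for (s in 1:3) {
    inst <- make_instance(30, 3, seed = 10 + s)
    fit <- mkl_train(inst$grams, inst$y, C = 2)
    expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
    expect_true(all(fit$weights >= 0))
    expect_true(all(fit$alphas >= 0 & fit$alphas <= 2))
    expect_lt(abs(sum(fit$alphas * inst$y)), 1e-6 * 2)
    expect_true(all(diff(fit$trace$objective) <= 1e-8 * abs(fit$trace$objective[-1])))
  }
})

test_that("learned weights never do worse than the uniform combination", {
  for (s in 1:4) {
    inst <- make_instance(26, 3, seed = 20 + s)
    fit <- mkl_train(inst$grams, inst$y, C = 1)
    unif <- train_svm(uniform_composite(inst$grams), inst$y, C = 1)
    expect_lte(fit$objective, unif$objective + 1e-6 * abs(unif$objective))
  }
})

test_that("an informative kernel dominates a label-permuted noise kernel", {
  # informative gram vs the same construction with permuted labels, checked
  # against the exact grid minimum over the 2-simplex
  ds <- simulate_linkdata(n_pairs = 200, seed = 30)
  good <- pairwise_gram("P1", ds$kernels[[1]], ds$pairs)
  y <- ds$pairs$label
  noise <- pairwise_gram("P1", ds$kernels[[3]], ds$pairs)
  fit <- mkl_train(list(good, noise), y, C = 1)
  expect_gte(fit$weights[1], 0.9)
  oracle <- mkl_grid_oracle(list(good, noise), y, C = 1, step = 0.05)
  expect_gte(oracle$lambda[1], 0.9)
  expect_lte(fit$objective, oracle$objective + 1e-4 * abs(oracle$objective))
})

test_that("uniform_composite averages and validates shapes", {
  g <- tcrossprod(matrix(rnorm(20), 5))
  expect_equal(uniform_composite(list(g)), g)
  expect_equal(uniform_composite(list(g, -g + 2 * g)), g)
  expect_error(uniform_composite(list(g, diag(3))), "dimensions",
               class = "kernlink_config_error")
})

test_that("decision_function matches dense composite-Gram evaluation", {
  ds <- simulate_linkdata(n_pairs = 80, seed = 5)
  specs <- lapply(ds$kernels, function(k) base_kernel_spec("P1", k))
  tr <- ds$pairs[1:60, ]
  te <- ds$pairs[61:80, ]
  model <- fit_link_model(specs, tr, C = 1, normalize = FALSE)
  phi <- decision_function(model, te)
  dense <- Reduce(`+`, Map(function(s, w)
    w * pairwise_gram(s$kind, s$kernel, tr, te),
    model$specs, model$weights))
  expect_equal(phi,
               drop(crossprod(dense, model$alphas * model$labels)) + model$bias,
               tolerance = 1e-10)
  # all-zero duals leave only the bias
  model0 <- model
  model0$alphas <- rep(0, length(model0$alphas))
  expect_equal(decision_function(model0, te),
               rep(model0$bias, nrow(te)))
  # predicted label is sign(phi) with 0 mapped to +1
  expect_equal(predict(model, te), ifelse(phi >= 0, 1L, -1L))
})

test_that("model files round trip exactly", {
  ds <- simulate_linkdata(n_pairs = 60, seed = 6)
  specs <- lapply(ds$kernels, function(k) base_kernel_spec("P1", k))
  model <- fit_link_model(specs, ds$pairs, C = 1)
  cal <- fit_sigmoid(decision_function(model, ds$pairs), ds$pairs$label)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path, cal)
  kernels <- setNames(ds$kernels, vapply(ds$kernels, `[[`, "", "name"))
  loaded <- read_model(path, kernels)
  expect_identical(loaded$model$weights, model$weights)
  expect_identical(loaded$model$alphas, model$alphas)
  expect_identical(loaded$model$bias, model$bias)
  expect_identical(loaded$calibration$a, cal$a)
  expect_equal(decision_function(loaded$model, ds$pairs),
               decision_function(model, ds$pairs))
})

test_that("tidy and glance summarize fits", {
  ds <- simulate_linkdata(n_pairs = 60, seed = 7)
  specs <- lapply(ds$kernels, function(k) base_kernel_spec("P3", k))
  model <- fit_link_model(specs, ds$pairs, C = 1)
  td <- tidy(model)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  expect_true(all(td$kind == "P3"))
  gl <- glance(model)
  expect_equal(gl$n_base, 3L)
  expect_true(gl$converged)
})
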