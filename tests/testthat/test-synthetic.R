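test_that("degenerate link probabilities give disjoint module cliques", {
  net <- generate_network(12, 3, p_in = 1, p_out = 0, seed = 1)
  same <- outer(net$module, net$module, "==")
  diag(same) <- FALSE
  expect_equal(unname(net$adjacency == 1), same)
})

test_that("link counts match the binomial expectation within 3 sigma", {
  n <- 60; k <- 4
  net <- generate_network(n, k, p_in = 0.8, p_out = 0.1, seed = 2)
  module <- net$module
  same <- outer(module, module, "==")[upper.tri(diag(n))]
  n_in <- sum(same); n_out <- sum(!same)
  mu <- n_in * 0.8 + n_out * 0.1
  sd <- sqrt(n_in * 0.8 * 0.2 + n_out * 0.1 * 0.9)
  links <- sum(net$adjacency) / 2
  expect_lt(abs(links - mu), 3 * sd)
})

test_that("network generation is reproducible and validated", {
  expect_identical(generate_network(20, 2, 0.9, 0.1, seed = 5)$adjacency,
                   generate_network(20, 2, 0.9, 0.1, seed = 5)$adjacency)
  expect_error(generate_network(10, 2, 0.5, 0.6, seed = 1), "p_out",
               class = "kernlink_config_error")
  expect_error(generate_network(5, 9, 0.9, 0.1, seed = 1), "n_modules",
               class = "kernlink_config_error")
})

test_that("generated kernels are valid node kernels", {
  net <- generate_network(30, 3, 0.9, 0.05, seed = 3)
  ks <- generate_node_kernels(net, c(0, 0.5, 1), dim = 10, seed = 3)
  for (k in ks) {
    expect_s3_class(k, "node_kernel")
    expect_equal(unname(diag(k$matrix)), rep(1, 30))
    ev <- eigen(k$matrix, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
  }
  expect_error(generate_node_kernels(net, c(0.5, 1.2)), "informativeness",
               class = "kernlink_config_error")
})

test_that("kernel informativeness orders single-kernel discrimination", {
  # pure-noise kernel: held-out AUC compatible with chance; fully
  # informative kernel on a deterministic partition: near-perfect AUC
  ds0 <- simulate_linkdata(n_nodes = 70, informativeness = c(0), p_in = 1,
                           p_out = 0, n_pairs = 300, seed = 17)
  ds1 <- simulate_linkdata(n_nodes = 70, informativeness = c(1), p_in = 1,
                           p_out = 0, n_pairs = 300, seed = 17)
  aucs <- vapply(list(ds0, ds1), function(ds) {
    tr <- ds$pairs[1:200, ]; te <- ds$pairs[201:300, ]
    fit <- train_svm(pairwise_gram("P1", ds$kernels[[1]], tr),
                     tr$label, C = 1, check_psd = FALSE)
    phi <- drop(crossprod(pairwise_gram("P1", ds$kernels[[1]], tr, te),
                          fit$alphas * fit$labels)) + fit$bias
    auc_score(phi, te$label)
  }, 0)
  expect_lt(abs(aucs[1] - 0.5), 0.08)
  expect_gte(aucs[2], 0.95)
})

test_that("pair datasets are balanced, duplicate-free and reproducible", {
  net <- generate_network(40, 4, 0.9, 0.05, seed = 4)
  p <- make_pair_dataset(net, 100, seed = 4)
  expect_lte(abs(sum(p$label == 1) - sum(p$label == -1)), 1)
  expect_equal(anyDuplicated(paste(p$node_a, p$node_b)), 0L)
  expect_identical(as.data.frame(make_pair_dataset(net, 100, seed = 4)),
                   as.data.frame(p))
  # labels agree with the adjacency
  idx <- cbind(match(p$node_a, net$node_ids), match(p$node_b, net$node_ids))
  expect_equal(p$label, ifelse(net$adjacency[idx] == 1, 1L, -1L))
  expect_error(make_pair_dataset(net, 1e6, seed = 1), "cannot draw",
               class = "kernlink_data_error")
})

test_that("label flipping is exact, recorded and involutive", {
  net <- generate_network(60, 4, 0.95, 0.02, seed = 5)
  p <- make_pair_dataset(net, 400, seed = 5)
  f0 <- flip_labels(p, 0, seed = 5)
  expect_identical(f0$pairs$label, p$label)
  expect_length(f0$flipped, 0)

  f1 <- flip_labels(p, 0.1, seed = 5)
  expect_length(f1$flipped, 40)
  expect_equal(f1$pairs$label[f1$flipped], -p$label[f1$flipped])
  expect_equal(f1$pairs$label[-f1$flipped], p$label[-f1$flipped])

  # flipping the same indices again restores the original labels
  twice <- f1$pairs
  twice$label[f1$flipped] <- -twice$label[f1$flipped]
  expect_identical(twice$label, p$label)

  expect_error(flip_labels(p, 0.5), "fraction",
               class = "kernlink_config_error")
})

test_that("full datasets are reproducible from their seed", {
  a <- simulate_linkdata(seed = 8)
  b <- simulate_linkdata(seed = 8)
  expect_identical(a$network$adjacency, b$network$adjacency)
  expect_identical(lapply(a$kernels, `[[`, "matrix"),
                   lapply(b$kernels, `[[`, "matrix"))
  expect_identical(as.data.frame(a$pairs), as.data.frame(b$pairs))
})

test_that("weights recover the informativeness ranking end to end", {
  ds <- simulate_linkdata(seed = 1)      # informativeness (0.9, 0.6, 0.0)
  specs <- lapply(ds$kernels, function(k) base_kernel_spec("P1", k))
  fit <- fit_link_model(specs, ds$pairs, C = 1, normalize = FALSE)
  expect_equal(which.max(fit$weights), 1L)
  expect_lte(fit$weights[3], 0.05)
})
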