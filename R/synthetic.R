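#' Planted-partition network generator
#'
#' Draws an undirected network in which nodes belong to modules (assigned
#' round-robin) and each unordered pair of distinct nodes is linked
#' independently with probability `p_in` inside a module and `p_out` between
#' modules. This planted-module structure stands in for a curated interaction
#' network: kernels generated from it carry varying amounts of information
#' about the true links.
#'
#' @param n_nodes number of nodes.
#' @param n_modules number of modules (`<= n_nodes`).
#' @param p_in within-module link probability; must exceed `p_out`.
#' @param p_out between-module link probability.
#' @param seed RNG seed; identical seeds give identical networks.
#' @return A list of class `planted_network`: `adjacency` (0/1 symmetric
#'   matrix with named rows), `module` (integer module per node), `node_ids`.
#' @export
generate_network <- function(n_nodes, n_modules, p_in, p_out, seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    abort("need 0 <= p_out < p_in <= 1.", class = "kernlink_config_error")
  }
  if (n_modules > n_nodes || n_modules < 1) {
    abort("`n_modules` must lie in [1, n_nodes].",
          class = "kernlink_config_error")
  }
  node_ids <- sprintf("n%03d", seq_len(n_nodes))
  module <- rep_len(seq_len(n_modules), n_nodes)
  adj <- matrix(0L, n_nodes, n_nodes, dimnames = list(node_ids, node_ids))
  with_local_seed(derive_seed(seed, 1L), {
    ut <- which(upper.tri(adj), arr.ind = TRUE)
    same <- module[ut[, 1]] == module[ut[, 2]]
    link <- rbinom(nrow(ut), 1L, ifelse(same, p_in, p_out))
    adj[ut] <- link
  })
  adj <- adj + t(adj)
  structure(list(adjacency = adj, module = module, node_ids = node_ids),
            class = "planted_network")
}

#' Heterogeneous node kernels over a planted network
#'
#' Emulates a panel of data sources of varying quality (in real studies:
#' sequence kernels, diffusion kernels from assay networks). Each kernel is
#' the cosine-normalized linear kernel of node feature vectors
#' `[w * module_indicator, (1 - w) * noise]` where `w` is the kernel's
#' informativeness: at `w = 0` the kernel is pure Gaussian noise and carries
#' nothing about the modules; at `w = 1` it encodes module membership
#' exactly. The indicator block and the noise block occupy disjoint
#' coordinates, so `w` cleanly interpolates between the two.
#'
#' @param network a `planted_network`.
#' @param informativeness numeric vector in `[0, 1]`, one entry per kernel.
#' @param dim number of noise dimensions per kernel.
#' @param seed RNG seed.
#' @return A list of [node_kernel()]s named `inf<w>_k<l>`.
#' @export
generate_node_kernels <- function(network, informativeness, dim = 20L,
                                  seed = 1L) {
  stopifnot(inherits(network, "planted_network"))
  if (any(informativeness < 0 | informativeness > 1)) {
    abort("informativeness values must lie in [0, 1].",
          class = "kernlink_config_error")
  }
  m <- length(network$node_ids)
  n_modules <- max(network$module)
  indicator <- matrix(0, m, n_modules)
  indicator[cbind(seq_len(m), network$module)] <- 1
  lapply(seq_along(informativeness), function(l) {
    w <- informativeness[l]
    noise <- with_local_seed(derive_seed(seed, 100L + l),
                             matrix(rnorm(m * dim), m, dim))
    feats <- cbind(w * indicator, (1 - w) * noise)
    k <- node_kernel(tcrossprod(feats), network$node_ids,
                     name = sprintf("inf%02.0f_k%d", 100 * w, l))
    normalize_kernel(k)
  })
}

#' Balanced labeled pair set from an adjacency matrix
#'
#' Samples, without replacement, `n_pairs / 2` linked pairs (label `+1`) and
#' `n_pairs / 2` unlinked pairs (label `-1`), mirroring the balanced
#' link/nonlink reference sets used for supervised network inference.
#'
#' @param network a `planted_network`.
#' @param n_pairs total pairs (split as evenly as possible between classes).
#' @param seed RNG seed.
#' @return A labeled [pair_set()].
#' @export
make_pair_dataset <- function(network, n_pairs, seed = 1L) {
  stopifnot(inherits(network, "planted_network"))
  adj <- network$adjacency
  ids <- network$node_ids
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  linked <- ut[adj[ut] == 1, , drop = FALSE]
  unlinked <- ut[adj[ut] == 0, , drop = FALSE]
  n_pos <- ceiling(n_pairs / 2)
  n_neg <- n_pairs - n_pos
  if (nrow(linked) < n_pos || nrow(unlinked) < n_neg) {
    abort(sprintf(
      "network has %d links and %d nonlinks; cannot draw %d + %d pairs",
      nrow(linked), nrow(unlinked), n_pos, n_neg),
      class = "kernlink_data_error")
  }
  with_local_seed(derive_seed(seed, 2L), {
    pos <- linked[sample(nrow(linked), n_pos), , drop = FALSE]
    neg <- unlinked[sample(nrow(unlinked), n_neg), , drop = FALSE]
    shuffle <- sample(n_pairs)        # interleave classes so any contiguous
  })                                  # split of the rows is near-balanced
  a <- c(ids[pos[, 1]], ids[neg[, 1]])[shuffle]
  b <- c(ids[pos[, 2]], ids[neg[, 2]])[shuffle]
  lab <- c(rep(1L, n_pos), rep(-1L, n_neg))[shuffle]
  pair_set(a, b, label = lab)
}

#' Plant label noise in a pair set
#'
#' Inverts the labels of exactly `round(fraction * n)` pairs chosen uniformly
#' at random, recording which — the ground truth against which the cleaning
#' strategies are scored.
#'
#' @param pairs a labeled [pair_set()].
#' @param fraction flip fraction in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return A list: `pairs` (with flipped labels) and `flipped` (integer row
#'   indices of the inverted labels).
#' @export
flip_labels <- function(pairs, fraction, seed = 1L) {
  if (!is_labeled(pairs)) {
    abort("`pairs` must carry labels.", class = "kernlink_data_error")
  }
  if (fraction < 0 || fraction >= 0.5) {
    abort("`fraction` must lie in [0, 0.5).", class = "kernlink_config_error")
  }
  n <- nrow(pairs)
  n_flip <- round(fraction * n)
  flipped <- if (n_flip > 0) {
    sort(with_local_seed(derive_seed(seed, 3L), sample(n, n_flip)))
  } else integer(0)
  pairs$label[flipped] <- -pairs$label[flipped]
  list(pairs = pairs, flipped = flipped)
}

#' Generate a complete synthetic link-prediction benchmark
#'
#' One call produces everything the pipeline consumes: a planted-partition
#' network, a panel of node kernels of varying informativeness, a balanced
#' labeled pair set, and (optionally) planted label noise. All randomness
#' derives from `seed` through independent per-component streams, so the
#' whole dataset is reproducible and adding components never perturbs the
#' others.
#'
#' The defaults — 60 nodes in 4 modules, near-deterministic within-module
#' linkage (`p_in = 0.95`) against a sparse background (`p_out = 0.02`),
#' three kernels of informativeness 0.9 / 0.6 / 0.0, and 200 balanced
#' pairs — make module membership the dominant determinant of linkage, so a
#' kernel's informativeness about the modules orders its usefulness for
#' link prediction: the regime the weight-learning machinery is meant to
#' resolve. The residual off-module linkage keeps the task from being a
#' deterministic lookup. A weaker partition would instead reward
#' uninformative kernels, whose near-orthogonal Grams let a soft-margin
#' classifier memorize pairs whose labels no module-level signal explains.
#'
#' @param n_nodes,n_modules,p_in,p_out see [generate_network()].
#' @param informativeness per-kernel informativeness in `[0, 1]`.
#' @param dim noise dimensions per kernel.
#' @param n_pairs balanced pair count.
#' @param flip_fraction label-noise fraction in `[0, 0.5)`.
#' @param seed master RNG seed.
#' @return A list of class `synthetic_dataset`: `network`, `kernels`,
#'   `pairs` (labels after flipping), `clean_labels`, `flipped`, `seed` and
#'   the generator parameters.
#' @export
simulate_linkdata <- function(n_nodes = 60L, n_modules = 4L, p_in = 0.95,
                              p_out = 0.02,
                              informativeness = c(0.9, 0.6, 0.0),
                              dim = 20L, n_pairs = 200L, flip_fraction = 0,
                              seed = 1L) {
  network <- generate_network(n_nodes, n_modules, p_in, p_out, seed = seed)
  kernels <- generate_node_kernels(network, informativeness, dim = dim,
                                   seed = seed)
  pairs <- make_pair_dataset(network, n_pairs, seed = seed)
  clean_labels <- pairs$label
  fl <- flip_labels(pairs, flip_fraction, seed = seed)
  structure(list(network = network, kernels = kernels, pairs = fl$pairs,
                 clean_labels = clean_labels, flipped = fl$flipped,
                 seed = seed,
                 params = list(n_nodes = n_nodes, n_modules = n_modules,
                               p_in = p_in, p_out = p_out,
                               informativeness = informativeness, dim = dim,
                               n_pairs = n_pairs,
                               flip_fraction = flip_fraction)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %d nodes / %d modules, %d kernels, %d pairs (%d flipped), seed %d>\n",
    length(x$network$node_ids), max(x$network$module), length(x$kernels),
    nrow(x$pairs), length(x$flipped), x$seed))
  invisible(x)
}
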