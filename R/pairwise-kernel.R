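#' Pairwise kernels over node pairs
#'
#' Link prediction classifies *pairs* of nodes, so the kernel must measure
#' similarity between two candidate edges `(a, b)` and `(c, d)` using a node
#' kernel `K`. Five constructions are supported, named `P1`-`P5`:
#'
#' * `P1` — tensor product pairwise kernel (TPPK):
#'   `K(a,c) K(b,d) + K(a,d) K(b,c)`; the weighted adjacency of a Kronecker
#'   product graph.
#' * `P2` — symmetric direct sum: `K(a,c) + K(a,d) + K(b,c) + K(b,d)`;
#'   the inner product of summed feature vectors.
#' * `P3` — metric learning pairwise kernel (MLPK):
#'   `(K(a,c) - K(a,d) - K(b,c) + K(b,d))^2`; the squared inner product of
#'   feature-space difference vectors.
#' * `P4` — cosine pairwise kernel: the same difference-vector inner product,
#'   normalized by the two difference norms, i.e. the cosine between
#'   `Phi(a) - Phi(b)` and `Phi(c) - Phi(d)`.
#' * `P5` — Cartesian product pairwise kernel (CSPK):
#'   `K(a,c) I(b=d) + K(b,d) I(a=c) + K(a,d) I(b=c) + K(b,c) I(a=d)` with `I`
#'   the indicator on node *indices* (graph vertices, not kernel rows).
#'
#' All five produce symmetric PSD Gram matrices over canonicalized pairs.
#' `P4` is antisymmetric under swapping the two nodes within one pair, which
#' is why pair sets are canonicalized to a fixed orientation at ingest.
#'
#' @name pairwise-kernels
NULL

#' @rdname pairwise-kernels
#' @format `PAIRWISE_KINDS` is the closed set of supported kinds.
#' @export
PAIRWISE_KINDS <- c("P1", "P2", "P3", "P4", "P5")

check_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 || !kind %in% PAIRWISE_KINDS) {
    abort(sprintf("`kind` must be one of %s",
                  paste(PAIRWISE_KINDS, collapse = ", ")),
          class = "kernlink_config_error")
  }
  kind
}

#' Evaluate a pairwise kernel on two node pairs
#'
#' Scalar form of the five pairwise kernels; see [pairwise-kernels] for the
#' formulas. Mostly useful for testing — [pairwise_gram()] is the vectorized
#' workhorse.
#'
#' @param kind one of `"P1"` ... `"P5"`.
#' @param k a [node_kernel()].
#' @param pair_a,pair_b integer vectors of length 2: node indices into
#'   `k$node_ids`, first index smaller.
#' @return A single numeric value.
#' @examples
#' k <- node_kernel(diag(3), c("x", "y", "z"))
#' pairwise_value("P1", k, c(1, 2), c(1, 2))
#' @export
pairwise_value <- function(kind, k, pair_a, pair_b) {
  check_kind(kind)
  stopifnot(inherits(k, "node_kernel"),
            length(pair_a) == 2, length(pair_b) == 2)
  rows <- pair_set(k$node_ids[pair_a[1]], k$node_ids[pair_a[2]])
  cols <- pair_set(k$node_ids[pair_b[1]], k$node_ids[pair_b[2]])
  drop(pairwise_gram(kind, k, rows, cols))
}

#' Build a pairwise Gram matrix
#'
#' Assembles the `|rows| x |cols|` matrix of pairwise-kernel values between
#' two pair sets over the same node kernel. When `rows` and `cols` are the
#' same set the result is symmetric and PSD (within the package tolerance)
#' for all five kinds. Assembly proceeds in row blocks so that memory stays
#' proportional to `block_size * |cols|`; the result is independent of the
#' block size.
#'
#' @param kind one of `"P1"` ... `"P5"`.
#' @param k a [node_kernel()].
#' @param rows,cols [pair_set()]s referencing nodes of `k`; `cols` defaults
#'   to `rows`.
#' @param block_size rows per assembly block.
#' @return A numeric matrix.
#' @export
pairwise_gram <- function(kind, k, rows, cols = rows, block_size = 1024L) {
  check_kind(kind)
  stopifnot(inherits(k, "node_kernel"))
  ri <- pair_indices(rows, k$node_ids)
  ci <- pair_indices(cols, k$node_ids)
  K <- k$matrix
  if (kind == "P4") {
    sr <- p4_self(K, ri)
    sc <- p4_self(K, ci)
    check_p4_degenerate(sr, rows)
    check_p4_degenerate(sc, cols)
  }
  out <- matrix(0, nrow(ri), nrow(ci))
  for (start in seq(1, nrow(ri), by = block_size)) {
    idx <- start:min(start + block_size - 1L, nrow(ri))
    out[idx, ] <- pairwise_block(kind, K, ri[idx, , drop = FALSE], ci,
                                 if (kind == "P4") sr[idx] else NULL,
                                 if (kind == "P4") sc else NULL)
  }
  out
}

# Squared norm of the feature-space difference vector for each pair.
p4_self <- function(K, idx) {
  K[cbind(idx[, 1], idx[, 1])] - 2 * K[cbind(idx[, 1], idx[, 2])] +
    K[cbind(idx[, 2], idx[, 2])]
}

check_p4_degenerate <- function(s, pairs) {
  bad <- which(s <= 0)
  if (length(bad)) {
    abort(sprintf(
      "P4 undefined: zero difference norm for kernel-identical pair(s) %s",
      paste(pair_ids(pairs)[head(bad, 3)], collapse = ", ")),
      class = "kernlink_data_error")
  }
}

pairwise_block <- function(kind, K, ri, ci, sr = NULL, sc = NULL) {
  a <- ri[, 1]; b <- ri[, 2]; cc <- ci[, 1]; d <- ci[, 2]
  Kac <- K[a, cc, drop = FALSE]; Kad <- K[a, d, drop = FALSE]
  Kbc <- K[b, cc, drop = FALSE]; Kbd <- K[b, d, drop = FALSE]
  switch(kind,
    P1 = Kac * Kbd + Kad * Kbc,
    P2 = Kac + Kad + Kbc + Kbd,
    P3 = (Kac - Kad - Kbc + Kbd)^2,
    P4 = (Kac - Kad - Kbc + Kbd) / sqrt(tcrossprod(sr, sc)),
    P5 = Kac * outer(b, d, "==") + Kbd * outer(a, cc, "==") +
         Kad * outer(b, cc, "==") + Kbc * outer(a, d, "==")
  )
}

#' Base kernel specification
#'
#' Pairs a pairwise-kernel kind with a node kernel; a list of these defines
#' the base kernels entering multiple kernel learning (e.g. all five kinds
#' crossed with several data kernels).
#'
#' @param kind one of `"P1"` ... `"P5"`.
#' @param kernel a [node_kernel()].
#' @return An object of class `base_kernel_spec`.
#' @export
base_kernel_spec <- function(kind, kernel) {
  check_kind(kind)
  stopifnot(inherits(kernel, "node_kernel"))
  structure(list(kind = kind, kernel = kernel), class = "base_kernel_spec")
}

#' @export
print.base_kernel_spec <- function(x, ...) {
  cat(sprintf("<base_kernel_spec: %s on %s (%d nodes)>\n", x$kind,
              if (is.null(x$kernel$name)) "kernel" else x$kernel$name,
              length(x$kernel$node_ids)))
  invisible(x)
}

spec_label <- function(spec) {
  paste0(spec$kind, "(", if (is.null(spec$kernel$name)) "kernel"
         else spec$kernel$name, ")")
}

#' Gram matrices for a list of base-kernel specifications
#'
#' Convenience wrapper building one pairwise Gram per [base_kernel_spec()]
#' over common row/column pair sets — the base kernels entering
#' [mkl_train()].
#'
#' @param specs list of [base_kernel_spec()]s.
#' @param rows,cols [pair_set()]s; `cols` defaults to `rows`.
#' @param block_size rows per assembly block.
#' @return A list of numeric matrices, one per spec.
#' @export
base_grams <- function(specs, rows, cols = rows, block_size = 1024L) {
  lapply(specs, function(s)
    pairwise_gram(s$kind, s$kernel, rows, cols, block_size = block_size))
}
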