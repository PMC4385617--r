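#' Labeled and unlabeled node-pair sets
#'
#' A pair set is the tabular unit of supervised link prediction: one row per
#' unordered pair of distinct nodes, optionally labeled `+1` (link) or `-1`
#' (nonlink). Pairs are canonicalized so the lexicographically smaller node ID
#' comes first; duplicates after canonicalization are an error, as are
#' self-pairs.
#'
#' @param node_a,node_b character vectors of node IDs.
#' @param label optional integer vector in `{-1, +1}`.
#' @return A tibble of class `pair_set` with columns `node_a`, `node_b` and,
#'   when labels are given, `label`.
#' @examples
#' pair_set(c("n2", "n1"), c("n1", "n3"), label = c(1, -1))
#' @export
pair_set <- function(node_a, node_b, label = NULL) {
  node_a <- as.character(node_a)
  node_b <- as.character(node_b)
  if (length(node_a) != length(node_b)) {
    abort("`node_a` and `node_b` must have the same length.",
          class = "kernlink_data_error")
  }
  if (any(node_a == node_b)) {
    abort(sprintf("self-pairs are not allowed: %s",
                  paste(unique(node_a[node_a == node_b]), collapse = ", ")),
          class = "kernlink_data_error")
  }
  swap <- node_a > node_b
  tmp <- node_a[swap]; node_a[swap] <- node_b[swap]; node_b[swap] <- tmp
  key <- paste(node_a, node_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(sprintf("duplicate pair after canonicalization: (%s)",
                  gsub("\r", ", ", dup)),
          class = "kernlink_data_error")
  }
  out <- tibble::tibble(node_a = node_a, node_b = node_b)
  if (!is.null(label)) {
    if (length(label) != length(node_a)) {
      abort("`label` must align with the pairs.", class = "kernlink_data_error")
    }
    label <- as.integer(label)
    if (!all(label %in% c(-1L, 1L))) {
      abort("labels must be -1 or +1.", class = "kernlink_data_error")
    }
    out$label <- label
  }
  class(out) <- c("pair_set", class(out))
  out
}

is_labeled <- function(pairs) "label" %in% names(pairs)

#' Read a pair file
#'
#' Tab-delimited, no header: `node_id_a<TAB>node_id_b[<TAB>label]` with label
#' in `{-1, 1}`. The labeled and unlabeled variants are distinguished by the
#' column count.
#'
#' @param path path to the TSV file.
#' @return A [pair_set()].
#' @export
read_pairs <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                    stringsAsFactors = FALSE)
  if (!ncol(raw) %in% 2:3) {
    abort(sprintf("%s: expected 2 or 3 tab-separated columns, got %d",
                  path, ncol(raw)),
          class = "kernlink_data_error")
  }
  label <- NULL
  if (ncol(raw) == 3) {
    suppressWarnings(label <- as.integer(raw[[3]]))
    if (anyNA(label)) {
      abort(sprintf("%s: non-integer label in column 3", path),
            class = "kernlink_data_error")
    }
  }
  pair_set(raw[[1]], raw[[2]], label = label)
}

#' Write a pair file
#'
#' @param pairs a [pair_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Map a pair set onto a kernel's node order, canonicalizing each pair so that
# index_a < index_b. This index-order canonicalization fixes the orientation
# of the implicit difference vector Phi(a) - Phi(b), which is what makes the
# sign-sensitive cosine pairwise kernel well defined across train and test.
pair_indices <- function(pairs, node_ids) {
  ia <- match(pairs$node_a, node_ids)
  ib <- match(pairs$node_b, node_ids)
  missing <- unique(c(pairs$node_a[is.na(ia)], pairs$node_b[is.na(ib)]))
  if (length(missing)) {
    abort(sprintf("node id(s) absent from kernel: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "kernlink_data_error")
  }
  swap <- ia > ib
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  cbind(a = ia, b = ib)
}

pair_ids <- function(pairs) paste(pairs$node_a, pairs$node_b, sep = "--")
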