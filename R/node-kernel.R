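#' Node kernel objects
#'
#' A node kernel is a symmetric positive semidefinite similarity matrix over a
#' set of named nodes (genes, proteins): the building block from which pairwise
#' kernels over candidate links are constructed. Typical examples are sequence
#' kernels (spectrum, motif, domain-content) or diffusion kernels derived from
#' an interaction network.
#'
#' @param matrix square numeric matrix of node-node similarities.
#' @param node_ids character vector of unique node identifiers, one per
#'   row/column of `matrix`. Defaults to the matrix dimnames.
#' @param strict logical; if `TRUE`, a positive semidefiniteness violation
#'   beyond tolerance is an error instead of a warning.
#' @param name optional short label carried along for reporting.
#'
#' @details Validation enforces: a square matrix, unique IDs matching the
#' matrix side, symmetry to within `1e-9 * max|K|`, and eigenvalues no smaller
#' than `-1e-8` times the largest eigenvalue. The last check warns by default
#' (tiny negative eigenvalues are a fact of life for diffusion kernels stored
#' at finite precision) and errors under `strict = TRUE`.
#'
#' @return An object of class `node_kernel`: a list with elements `node_ids`,
#'   `matrix` and `name`.
#' @examples
#' k <- node_kernel(diag(3), node_ids = c("a", "b", "c"))
#' k
#' @export
node_kernel <- function(matrix, node_ids = rownames(matrix), strict = FALSE,
                        name = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix.", class = "kernlink_data_error")
  }
  if (nrow(matrix) != ncol(matrix)) {
    abort(sprintf("kernel matrix must be square, got %d x %d",
                  nrow(matrix), ncol(matrix)),
          class = "kernlink_data_error")
  }
  if (is.null(node_ids)) {
    abort("`node_ids` missing and matrix has no rownames.",
          class = "kernlink_data_error")
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(matrix)) {
    abort("length of `node_ids` must equal the matrix side.",
          class = "kernlink_data_error")
  }
  if (anyDuplicated(node_ids)) {
    abort(sprintf("duplicate node ids: %s",
                  paste(unique(node_ids[duplicated(node_ids)]), collapse = ", ")),
          class = "kernlink_data_error")
  }
  if (anyNA(matrix)) {
    abort("kernel matrix contains missing values.", class = "kernlink_data_error")
  }
  scale <- max(abs(matrix))
  asym <- max(abs(matrix - t(matrix)))
  if (asym > 1e-9 * max(scale, 1e-300)) {
    abort(sprintf("kernel matrix is asymmetric: max |K - t(K)| = %.3g", asym),
          class = "kernlink_data_error")
  }
  matrix <- (matrix + t(matrix)) / 2
  psd <- validate_psd(matrix, tol = PSD_TOL)
  if (!psd$ok) {
    msg <- sprintf(
      "kernel is not PSD within tolerance: min eigenvalue %.3g (max %.3g)",
      psd$min_eigenvalue, psd$max_eigenvalue)
    if (strict) abort(msg, class = "kernlink_data_error") else warn(msg)
  }
  dimnames(matrix) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, matrix = matrix, name = name),
            class = "node_kernel")
}

#' @export
print.node_kernel <- function(x, ...) {
  cat(sprintf("<node_kernel%s: %d nodes>\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$node_ids)))
  cat("ids:", paste(head(x$node_ids, 6), collapse = ", "),
      if (length(x$node_ids) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.node_kernel <- function(x) dim(x$matrix)

#' Check positive semidefiniteness of a symmetric matrix
#'
#' A valid kernel matrix must have nonnegative eigenvalues. The check is
#' relative: the matrix passes when its smallest eigenvalue is at least
#' `-tol` times its largest (the largest taken as 1 for an all-zero matrix).
#'
#' @param matrix square numeric matrix, symmetric within `1e-9` relative.
#' @param tol nonnegative relative tolerance (default `1e-8`).
#' @return A list with `ok` (logical), `min_eigenvalue` and `max_eigenvalue`.
#' @examples
#' validate_psd(diag(2))                      # ok, min eigenvalue 1
#' validate_psd(matrix(c(1, 2, 2, 1), 2))     # not PSD, eigenvalues 3 and -1
#' @export
validate_psd <- function(matrix, tol = PSD_TOL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (max(abs(matrix - t(matrix))) > 1e-9 * max(max(abs(matrix)), 1e-300)) {
    abort("`matrix` must be symmetric.", class = "kernlink_data_error")
  }
  ev <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev)
  ref <- if (max(abs(matrix)) == 0) 1 else mx
  list(ok = min(ev) >= -tol * ref, min_eigenvalue = min(ev), max_eigenvalue = mx)
}

#' Cosine-normalize a node kernel
#'
#' Rescales a kernel so every node has unit self-similarity:
#' \eqn{\hat K_{ij} = K_{ij} / \sqrt{K_{ii} K_{jj}}}. Equivalent to projecting
#' the implicit feature vectors onto the unit sphere, which puts heterogeneous
#' data sources on an equal footing before they are combined.
#'
#' @param k a [node_kernel()].
#' @return A `node_kernel` with unit diagonal.
#' @examples
#' k <- node_kernel(matrix(c(4, 2, 2, 1), 2), c("a", "b"))
#' normalize_kernel(k)$matrix
#' @export
normalize_kernel <- function(k) {
  stopifnot(inherits(k, "node_kernel"))
  d <- diag(k$matrix)
  bad <- which(d <= 0)
  if (length(bad)) {
    abort(sprintf("cannot normalize: nonpositive diagonal for node(s) %s",
                  paste(k$node_ids[bad], collapse = ", ")),
          class = "kernlink_data_error")
  }
  s <- 1 / sqrt(d)
  m <- k$matrix * tcrossprod(s)
  diag(m) <- 1
  node_kernel(m, k$node_ids, name = k$name)
}

#' Read a node kernel from a TSV file
#'
#' The expected layout is a square matrix with node IDs in the header row and
#' the first column: first cell empty, then m node IDs; each body row starts
#' with its node ID followed by m numeric values. Tab-delimited, UTF-8,
#' `.` decimal.
#'
#' @param path path to the TSV file.
#' @param strict logical; escalate PSD violations to errors.
#' @return A [node_kernel()].
#' @seealso [write_node_kernel()]
#' @export
read_node_kernel <- function(path, strict = FALSE) {
  raw <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 2) {
    abort(sprintf("%s: not a kernel matrix file", path),
          class = "kernlink_data_error")
  }
  header_ids <- as.character(raw[1, -1])
  row_ids <- as.character(raw[-1, 1])
  if (nrow(raw) - 1 != ncol(raw) - 1) {
    abort(sprintf("%s: body is not square (%d rows, %d columns)",
                  path, nrow(raw) - 1, ncol(raw) - 1),
          class = "kernlink_data_error")
  }
  if (!identical(header_ids, row_ids)) {
    abort(sprintf("%s: header and row node ids disagree", path),
          class = "kernlink_data_error")
  }
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(storage)) {
    bad <- which(is.na(storage), arr.ind = TRUE)[1, ]
    abort(sprintf("%s: non-numeric cell at row '%s', column '%s'",
                  path, row_ids[bad[1]], header_ids[bad[2]]),
          class = "kernlink_data_error")
  }
  node_kernel(storage, header_ids, strict = strict,
              name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a node kernel to a TSV file
#'
#' Values are printed at 17 significant digits so that a read/write round trip
#' reproduces the double-precision matrix bit for bit.
#'
#' @param k a [node_kernel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_node_kernel()]
#' @export
write_node_kernel <- function(k, path) {
  stopifnot(inherits(k, "node_kernel"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", k$node_ids), collapse = "\t"), con)
  body <- apply(k$matrix, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(k$node_ids, body, sep = "\t"), con)
  invisible(path)
}
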