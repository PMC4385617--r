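#' Save a composite model as structured text
#'
#' Writes a JSON file holding the base-kernel specifications (pairwise kind +
#' data-kernel name), simplex weights, dual coefficients keyed by pair ID,
#' bias, box bound, normalization flag and (optionally) the calibration.
#' Numbers are written at full double precision, so a save/load round trip
#' reproduces the model exactly.
#'
#' @param model a `composite_model` from [fit_link_model()].
#' @param path output path.
#' @param calibration optional `svm_calibration` stored alongside.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, calibration = NULL) {
  stopifnot(inherits(model, "composite_model"))
  payload <- list(
    format = "kernlink_model",
    version = 1L,
    base_specs = lapply(model$specs, function(s)
      list(kind = s$kind,
           kernel = if (is.null(s$kernel$name)) NA else s$kernel$name)),
    weights = model$weights,
    pair_ids = pair_ids(model$train_pairs),
    train_pairs = list(node_a = model$train_pairs$node_a,
                       node_b = model$train_pairs$node_b,
                       label = model$train_pairs$label),
    alphas = model$alphas,
    bias = model$bias,
    C = model$C,
    objective = model$objective,
    normalize = model$normalize)
  if (!is.null(calibration)) {
    payload$calibration <- list(
      a = calibration$a, b_sig = calibration$b_sig, n = calibration$n,
      iterations = calibration$iterations, converged = calibration$converged,
      capped = calibration$capped)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a composite model
#'
#' Re-attaches the node kernels by name: supply either a named list of
#' [node_kernel()] objects or a directory containing `<name>.tsv` files
#' written by [write_node_kernel()]. Normalization recorded in the file is
#' re-applied to the kernels.
#'
#' @param path path to a model JSON written by [write_model()].
#' @param kernels named list of `node_kernel`s, or a directory path.
#' @return A list: `model` (`composite_model`) and `calibration`
#'   (`svm_calibration` or `NULL`).
#' @export
read_model <- function(path, kernels) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(payload$format, "kernlink_model")) {
    abort(sprintf("%s is not a kernlink model file", path),
          class = "kernlink_data_error")
  }
  lookup <- function(name) {
    if (is.character(kernels)) {
      read_node_kernel(file.path(kernels, paste0(name, ".tsv")))
    } else {
      if (!name %in% names(kernels)) {
        abort(sprintf("kernel '%s' not supplied", name),
              class = "kernlink_data_error")
      }
      kernels[[name]]
    }
  }
  specs <- lapply(payload$base_specs, function(s) {
    k <- lookup(s$kernel)
    if (isTRUE(payload$normalize)) k <- normalize_kernel(k)
    base_kernel_spec(s$kind, k)
  })
  tp <- pair_set(payload$train_pairs$node_a, payload$train_pairs$node_b,
                 label = payload$train_pairs$label)
  model <- structure(
    list(weights = as.numeric(payload$weights),
         alphas = as.numeric(payload$alphas),
         bias = payload$bias, objective = payload$objective,
         C = payload$C, labels = as.numeric(tp$label),
         trace = NULL, converged = TRUE, specs = specs, train_pairs = tp,
         normalize = isTRUE(payload$normalize)),
    class = c("composite_model", "mkl_fit"))
  cal <- NULL
  if (!is.null(payload$calibration)) {
    cal <- structure(
      list(a = payload$calibration$a, b_sig = payload$calibration$b_sig,
           n = payload$calibration$n,
           iterations = payload$calibration$iterations,
           converged = isTRUE(payload$calibration$converged),
           capped = isTRUE(payload$calibration$capped),
           cross_entropy = NA_real_, platt_targets = FALSE),
      class = "svm_calibration")
  }
  list(model = model, calibration = cal)
}
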