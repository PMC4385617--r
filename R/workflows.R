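#' Command-style workflows
#'
#' The `run_*` functions are the package's batch entry points, mirrored by
#' the `kernlink` command-line script (`exec/kernlink`): `run_simulate`
#' writes a synthetic benchmark to disk, `run_train` cross-validates and fits
#' a weighted composite model, `run_predict` scores candidate pairs with a
#' saved model, `run_curve` tabulates the cautious accuracy/coverage
#' trade-off, and `run_clean` applies a data-cleaning strategy. Every command
#' writes a `manifest.json` recording its configuration and seed, so each
#' output directory is reproducible from its manifest.
#'
#' @name workflows
NULL

write_manifest <- function(dir, command, config) {
  jsonlite::write_json(c(list(command = command), config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @describeIn workflows Generate a synthetic benchmark and write node-kernel
#'   TSVs, a labeled pair TSV and a manifest (including the planted flip
#'   indices) to `out_dir`.
#' @param out_dir output directory (created if needed).
#' @param ... passed to [simulate_linkdata()].
#' @param seed RNG seed.
#' @return `run_simulate`: the `synthetic_dataset`, invisibly.
#' @export
run_simulate <- function(out_dir, ..., seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_linkdata(..., seed = seed)
  for (k in ds$kernels) {
    write_node_kernel(k, file.path(out_dir, paste0(k$name, ".tsv")))
  }
  write_pairs(ds$pairs, file.path(out_dir, "pairs.tsv"))
  write_manifest(out_dir, "simulate",
                 c(ds$params, list(seed = seed, flipped = ds$flipped,
                                   kernel_files = paste0(
                                     vapply(ds$kernels, `[[`, "", "name"),
                                     ".tsv"))))
  invisible(ds)
}

read_kernel_files <- function(kernel_files, strict = FALSE) {
  ks <- lapply(kernel_files, read_node_kernel, strict = strict)
  names(ks) <- vapply(ks, `[[`, "", "name")
  if (anyDuplicated(names(ks))) {
    abort("kernel files must have distinct base names.",
          class = "kernlink_config_error")
  }
  ids <- ks[[1]]$node_ids
  same <- vapply(ks, function(k) identical(sort(k$node_ids), sort(ids)), TRUE)
  if (!all(same)) {
    abort("all kernels must cover the same node set.",
          class = "kernlink_data_error")
  }
  ks
}

make_specs <- function(kernels, kinds) {
  if (identical(kinds, "all")) kinds <- PAIRWISE_KINDS
  lapply(kinds, check_kind)
  specs <- list()
  for (kind in kinds) {
    for (k in kernels) specs <- c(specs, list(base_kernel_spec(kind, k)))
  }
  specs
}

stratified_folds <- function(labels, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' @describeIn workflows Cross-validate and fit the weighted composite model.
#'   Reports per-fold accuracy and AUC for the MKL-weighted model (and,
#'   optionally, the uniform-weight baseline), fits the final model and a
#'   sigmoid calibration on the pooled held-out margins, and writes
#'   `model.json`, `weights.tsv` (kind-by-data-kernel layout), and
#'   `cv_metrics.tsv`.
#' @param kernel_files character vector of node-kernel TSV paths.
#' @param pairs_file labeled pair TSV.
#' @param kinds pairwise kinds to use: subset of `P1`..`P5`, or `"all"`.
#' @param C box bound.
#' @param normalize cosine-normalize node kernels first.
#' @param folds number of cross-validation folds.
#' @param uniform_baseline also evaluate equal kernel weights per fold.
#' @return `run_train`: a list with `model`, `calibration`, `cv_metrics`
#'   (tibble) and `weights` (tibble), invisibly.
#' @export
run_train <- function(kernel_files, pairs_file, out_dir, kinds = "P1",
                      C = 1, normalize = TRUE, folds = 5L,
                      uniform_baseline = TRUE, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kernels <- read_kernel_files(kernel_files)
  pairs <- read_pairs(pairs_file)
  if (!is_labeled(pairs)) {
    abort("training pairs must be labeled.", class = "kernlink_data_error")
  }
  specs <- make_specs(kernels, kinds)
  fold <- stratified_folds(pairs$label, folds, derive_seed(seed, 11L))
  heldout_phi <- numeric(nrow(pairs))
  metrics <- list()
  for (f in seq_len(folds)) {
    tr <- pairs[fold != f, ]
    te <- pairs[fold == f, ]
    fit <- fit_link_model(specs, tr, C = C, normalize = normalize)
    phi <- decision_function(fit, te)
    heldout_phi[fold == f] <- phi
    row <- tibble::tibble(fold = f, scheme = "weighted",
                          accuracy = mean(ifelse(phi >= 0, 1, -1) == te$label),
                          auc = auc_score(phi, te$label))
    if (uniform_baseline) {
      nspecs <- fit$specs       # kernels already normalized inside the fit
      g_tr <- base_grams(nspecs, tr)
      g_te <- base_grams(nspecs, tr, te)
      ufit <- train_svm(uniform_composite(g_tr), tr$label, C = C,
                        check_psd = FALSE)
      uphi <- drop(crossprod(uniform_composite(g_te),
                             ufit$alphas * ufit$labels)) + ufit$bias
      row <- dplyr::bind_rows(row, tibble::tibble(
        fold = f, scheme = "uniform",
        accuracy = mean(ifelse(uphi >= 0, 1, -1) == te$label),
        auc = auc_score(uphi, te$label)))
    }
    metrics[[f]] <- row
  }
  metrics <- dplyr::bind_rows(metrics)
  model <- fit_link_model(specs, pairs, C = C, normalize = normalize)
  calibration <- fit_sigmoid(heldout_phi, pairs$label)
  weights <- tidy(model) |>
    dplyr::select("kind", "data_kernel", "weight") |>
    tidyr::pivot_wider(names_from = "data_kernel", values_from = "weight")
  write_model(model, file.path(out_dir, "model.json"), calibration)
  write.table(as.data.frame(weights), file.path(out_dir, "weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(metrics), file.path(out_dir, "cv_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "train", list(
    kernel_files = kernel_files, pairs_file = pairs_file, kinds = kinds,
    C = C, normalize = normalize, folds = folds,
    uniform_baseline = uniform_baseline, seed = seed))
  invisible(list(model = model, calibration = calibration,
                 cv_metrics = metrics, weights = weights))
}

#' @describeIn workflows Score candidate pairs with a saved model and write a
#'   predictions TSV (pair IDs, `phi`, probability, predicted label, retained
#'   flag under the cautious cutoff).
#' @param model_file path to a `model.json`.
#' @param cutoff cautious confidence cutoff.
#' @param out_file output TSV path.
#' @return `run_predict`: the predictions tibble, invisibly.
#' @export
run_predict <- function(model_file, kernel_files, pairs_file, out_file,
                        cutoff = 0.5) {
  loaded <- read_model(model_file, read_kernel_files(kernel_files))
  if (is.null(loaded$calibration)) {
    abort("model file carries no calibration; run_train stores one.",
          class = "kernlink_data_error")
  }
  pairs <- read_pairs(pairs_file)
  preds <- score_pairs(loaded$model, loaded$calibration, pairs, cutoff)
  write.table(as.data.frame(preds), out_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(preds)
}

#' @describeIn workflows Tabulate the accuracy/coverage curve of a saved
#'   model on labeled pairs across a cutoff grid and write it as TSV
#'   (cutoff, n_retained, coverage, accuracy).
#' @param cutoffs cutoff grid for the curve.
#' @return `run_curve`: the `accuracy_coverage` tibble, invisibly.
#' @export
run_curve <- function(model_file, kernel_files, pairs_file, out_file,
                      cutoffs = c(seq(0.5, 0.99, by = 0.01), 0.995, 0.999)) {
  loaded <- read_model(model_file, read_kernel_files(kernel_files))
  pairs <- read_pairs(pairs_file)
  if (!is_labeled(pairs)) {
    abort("curve evaluation needs labeled pairs.",
          class = "kernlink_data_error")
  }
  phi <- decision_function(loaded$model, pairs)
  prob <- predict_proba(loaded$calibration, phi)
  curve <- accuracy_coverage_curve(prob, pairs$label, cutoffs)
  write.table(as.data.frame(curve), out_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(curve)
}

#' @describeIn workflows Run a data-cleaning strategy on labeled pairs:
#'   splits off a held-out test fraction, seeds with the most central pairs
#'   of each class, runs the chosen strategy and writes the trace TSV plus a
#'   summary (error at stop vs error at full; skipped pairs for the
#'   screening strategy).
#' @param strategy `"lowest_confidence"` or `"random_screen"`.
#' @param threshold screening confidence threshold.
#' @param n_seeds seeds per class.
#' @param test_fraction held-out fraction for the error trace.
#' @return `run_clean`: the `cleaning_trace`, invisibly.
#' @export
run_clean <- function(kernel_files, pairs_file, out_dir,
                      strategy = c("lowest_confidence", "random_screen"),
                      kinds = "P1", C = 1, normalize = TRUE,
                      threshold = 0.95, n_seeds = 10L, test_fraction = 0.25,
                      seed = 1L) {
  strategy <- match.arg(strategy)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kernels <- read_kernel_files(kernel_files)
  pairs <- read_pairs(pairs_file)
  if (!is_labeled(pairs)) {
    abort("cleaning needs labeled pairs.", class = "kernlink_data_error")
  }
  specs <- make_specs(kernels, kinds)
  if (normalize) {
    specs <- lapply(specs, function(s)
      base_kernel_spec(s$kind, normalize_kernel(s$kernel)))
  }
  fold <- stratified_folds(pairs$label, round(1 / test_fraction),
                           derive_seed(seed, 12L))
  te <- pairs[fold == 1L, ]
  tr <- pairs[fold != 1L, ]
  g_tr <- base_grams(specs, tr)
  g_te <- base_grams(specs, tr, te)
  lambda <- if (length(g_tr) == 1) 1 else mkl_train(g_tr, tr$label, C = C)$weights
  seeds <- centroid_seeds(weighted_composite(g_tr, lambda), tr$label,
                          n_per_class = n_seeds)
  trace <- if (strategy == "lowest_confidence") {
    clean_sequential(g_tr, tr$label, seeds, C = C, lambda = lambda,
                     test_grams = g_te, test_labels = te$label)
  } else {
    clean_random_screen(g_tr, tr$label, seeds, C = C, threshold = threshold,
                        seed = derive_seed(seed, 13L), lambda = lambda,
                        test_grams = g_te, test_labels = te$label)
  }
  write_cleaning_trace(trace, file.path(out_dir, "trace.tsv"))
  summary <- tibble::tibble(
    strategy = strategy,
    n_train = nrow(tr), n_test = nrow(te),
    n_seeds = length(trace$seed_indices),
    n_learned = length(trace$order),
    n_skipped = nrow(trace$skipped),
    stop_index = trace$stop_index,
    stop_fired = trace$stop_fired,
    error_at_stop = trace$error_at_stop,
    error_at_full = trace$error_at_full)
  write.table(as.data.frame(summary), file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(trace$skipped)) {
    skipped <- dplyr::mutate(trace$skipped,
                             pair_id = pair_ids(tr)[.data$index])
    write.table(as.data.frame(skipped), file.path(out_dir, "skipped.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "clean", list(
    kernel_files = kernel_files, pairs_file = pairs_file, kinds = kinds,
    strategy = strategy, C = C, normalize = normalize, threshold = threshold,
    n_seeds = n_seeds, test_fraction = test_fraction, seed = seed))
  invisible(trace)
}
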