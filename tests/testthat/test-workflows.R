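# The run_* workflows are the CLI surface; exercised here directly.

test_that("simulate writes kernels, pairs and a reproducible manifest", {
  dir <- withr::local_tempdir()
  ds <- run_simulate(dir, n_pairs = 60, seed = 4)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$command, "simulate")
  expect_equal(manifest$seed, 4)
  files <- file.path(dir, manifest$kernel_files)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(dir, "pairs.tsv")))
  # kernels on disk reproduce the in-memory ones exactly
  k <- read_node_kernel(files[1])
  expect_equal(k$matrix, ds$kernels[[1]]$matrix)

  dir2 <- withr::local_tempdir()
  run_simulate(dir2, n_pairs = 60, seed = 4)
  expect_identical(readLines(file.path(dir, "pairs.tsv")),
                   readLines(file.path(dir2, "pairs.tsv")))
})

fixture_dirs <- function(n_pairs = 120, seed = 2, flip = 0) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  run_simulate(dir, n_pairs = n_pairs, flip_fraction = flip, seed = seed)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(dir = dir,
       kernels = file.path(dir, manifest$kernel_files),
       pairs = file.path(dir, "pairs.tsv"))
}

test_that("train cross-validates, reports weights and stores a model", {
  fx <- fixture_dirs()
  out <- withr::local_tempdir()
  res <- run_train(fx$kernels, fx$pairs, out, kinds = "P1", folds = 3,
                   seed = 5)
  expect_true(all(file.exists(file.path(out, c("model.json", "weights.tsv",
                                               "cv_metrics.tsv",
                                               "manifest.json")))))
  w <- as.matrix(res$weights[, -1])
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(sort(unique(res$cv_metrics$scheme)),
               c("uniform", "weighted"))
  expect_equal(nrow(res$cv_metrics), 3 * 2)
  # the weighted scheme should not trail the uniform baseline materially
  agg <- tapply(res$cv_metrics$accuracy, res$cv_metrics$scheme, mean)
  expect_gte(agg[["weighted"]], agg[["uniform"]] - 0.02)
})

test_that("predictions honor the cutoff and reproduce bit for bit", {
  fx <- fixture_dirs()
  out <- withr::local_tempdir()
  run_train(fx$kernels, fx$pairs, out, kinds = "P1", folds = 3, seed = 5)
  model_file <- file.path(out, "model.json")
  pred_file <- file.path(out, "preds.tsv")
  preds <- run_predict(model_file, fx$kernels, fx$pairs, pred_file,
                       cutoff = 0.5)
  expect_true(all(preds$retained))
  # phi values equal the library-level decision function
  ks <- lapply(fx$kernels, read_node_kernel)
  names(ks) <- vapply(ks, `[[`, "", "name")
  loaded <- read_model(model_file, ks)
  expect_equal(preds$phi, decision_function(loaded$model, read_pairs(fx$pairs)))

  pred_file2 <- file.path(out, "preds2.tsv")
  run_predict(model_file, fx$kernels, fx$pairs, pred_file2, cutoff = 0.5)
  expect_identical(readLines(pred_file), readLines(pred_file2))
})

test_that("curve output covers the requested cutoff grid", {
  fx <- fixture_dirs()
  out <- withr::local_tempdir()
  run_train(fx$kernels, fx$pairs, out, kinds = "P1", folds = 3, seed = 5)
  curve_file <- file.path(out, "curve.tsv")
  curve <- run_curve(file.path(out, "model.json"), fx$kernels, fx$pairs,
                     curve_file, cutoffs = c(0.5, 0.7, 0.9))
  expect_equal(nrow(curve), 3)
  expect_equal(curve$coverage[1], 1)
  tab <- read.delim(curve_file)
  expect_equal(nrow(tab), 3)
})

test_that("clean workflow writes a partitioning trace and summary", {
  fx <- fixture_dirs(n_pairs = 150, seed = 6, flip = 0.1)
  out <- withr::local_tempdir()
  trace <- run_clean(fx$kernels, fx$pairs, out, strategy = "random_screen",
                     kinds = "P1", threshold = 1.0, n_seeds = 8, seed = 7)
  expect_equal(nrow(trace$skipped), 0)
  summ <- read.delim(file.path(out, "summary.tsv"))
  expect_equal(summ$strategy, "random_screen")
  expect_equal(summ$n_seeds + summ$n_learned + summ$n_skipped, summ$n_train)
  expect_true(file.exists(file.path(out, "trace.tsv")))
})

test_that("the installed command-line script runs end to end", {
  script <- file.path(find.package("kernlink"), "exec", "kernlink")
  expect_true(file.exists(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  code <- system2(rscript, c(script, "simulate", "--out", shQuote(dir),
                             "--npairs", "40", "--seed", "3"),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_equal(attr(code, "status"), NULL)   # exit 0
  expect_true(file.exists(file.path(dir, "pairs.tsv")))

  bad <- suppressWarnings(system2(rscript, c(script, "frobnicate"), env = env,
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2L)
})
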