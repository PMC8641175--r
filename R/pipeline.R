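#' Run the complete synthetic study: simulate, train, call, evaluate
#'
#' Simulates disjoint train/validation/test genomes, trains the window
#' classifier, scores the test genome, refines calls, and evaluates them
#' against the test truth set. Every source of randomness derives from
#' `seed`.
#'
#' @param seed Root seed.
#' @param out_dir Optional directory; when given, writes the test call VCF,
#'   truth VCF/BED, a JSON evaluation report and a run manifest there.
#' @param sim_configs List of three [simulation_config()]s (`train`, `val`,
#'   `test`); defaults to [easy_fixture_config()] under `seed`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [training_config()]; its `shuffle_seed` is replaced
#'   by one derived from `seed`.
#' @param max_epochs Convenience override of `train_cfg$max_epochs`.
#' @param verbose Print progress.
#' @return List: `model`, `datasets`, `val_auc`, `test_auc`, `scored`
#'   (test window scores), `calls`, `report` (an `eval_report`),
#'   `breakpoint` (per-matched-call start/size errors).
#' @export
run_end2end <- function(seed = 1L, out_dir = NULL,
                        sim_configs = easy_fixture_config(seed),
                        model_cfg = model_config(),
                        train_cfg = training_config(max_epochs = 20L),
                        max_epochs = NULL, verbose = FALSE) {
  seed <- as.integer(seed)
  if (!is.null(max_epochs)) train_cfg$max_epochs <- as.integer(max_epochs)
  train_cfg$shuffle_seed <- (seed * 7L + 13L) %% 1000000L
  if (verbose) message("simulating train/val/test genomes ...")
  ds <- make_dataset(sim_configs$train, sim_configs$val, sim_configs$test,
                     n = model_cfg$n, T_steps = model_cfg$T_steps)
  model <- init_model(model_cfg, seed = (seed * 31L + 7L) %% 1000000L)
  if (verbose) message("training ...")
  model <- train(model,
                 list(featset = ds$train$featset, batches = ds$train$batches,
                      labels = ds$train$labels),
                 list(featset = ds$val$featset, batches = ds$val$batches,
                      labels = ds$val$labels),
                 train_cfg, verbose = verbose)
  val_auc <- max(model$history$val_auc)
  if (verbose) message("scoring test genome ...")
  scored <- predict_windows(model, ds$test$featset, ds$test$batches)
  test_auc <- window_auc(
    scored$prob,
    ds$test$labels[match_window_rows(scored, ds$test$featset$windows)])
  calls <- call_deletions(scored, ds$test$alignments)
  report <- match_calls(calls, ds$test$genome$truth)
  bp <- breakpoint_accuracy(calls, ds$test$genome$truth, report)
  out <- list(model = model, datasets = ds, val_auc = val_auc,
              test_auc = test_auc, scored = scored, calls = calls,
              report = report, breakpoint = bp, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lens <- stats::setNames(ds$test$genome$length, ds$test$genome$contig)
    write_vcf(calls, lens, file.path(out_dir, "calls.vcf"))
    write_vcf(ds$test$genome$truth, lens, file.path(out_dir, "truth.vcf"))
    write_truth_bed(ds$test$genome$truth, file.path(out_dir, "truth.bed"))
    jsonlite::write_json(
      list(val_auc = val_auc, test_auc = test_auc,
           precision = report$precision, recall = report$recall,
           f1 = report$f1, tp = report$tp, fp = report$fp, fn = report$fn,
           breakpoint = bp),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write_manifest("end2end", list(seed = seed), out_dir)
  }
  out
}

#' Breakpoint and size accuracy of matched calls
#'
#' @param calls,truths Call and truth data.frames.
#' @param report An `eval_report` from [match_calls()].
#' @return List: `n`, `mean_start_error`, `mean_size_error`,
#'   `frac_start_within_40bp`, `frac_size_within_10pct`.
#' @export
breakpoint_accuracy <- function(calls, truths, report) {
  m <- report$matches
  if (nrow(m) == 0L)
    return(list(n = 0L, mean_start_error = NA_real_,
                mean_size_error = NA_real_, frac_start_within_40bp = NA_real_,
                frac_size_within_10pct = NA_real_))
  d_start <- abs(calls$start[m$call] - truths$start[m$truth])
  d_size <- abs(calls$size[m$call] - truths$size[m$truth])
  rel_size <- d_size / truths$size[m$truth]
  list(n = nrow(m), mean_start_error = mean(d_start),
       mean_size_error = mean(d_size),
       frac_start_within_40bp = mean(d_start <= 40),
       frac_size_within_10pct = mean(rel_size <= 0.10))
}

write_manifest <- function(subcommand, config, out_dir) {
  jsonlite::write_json(
    list(tool = "delnet",
         version = as.character(utils::packageVersion("delnet")),
         subcommand = subcommand, config = config,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
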