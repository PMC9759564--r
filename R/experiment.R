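#' Run the repeated best/average classification experiment
#'
#' The evaluation protocol used for the breast-cancer tables: for each of
#' `cfg$attempts` attempts the (already normalized) dataset is re-split
#' 80/20 into training and test with 20% of the training rows held out
#' for validation, every record is encoded as an image, a fresh 4-block
#' CNN is built and trained, and accuracy is measured on the validation
#' and test partitions.  Best and mean accuracies over attempts are
#' aggregated, along with per-attempt confusion-matrix metrics on the
#' test partition.  Attempt `a` uses seed `cfg$seed + a`, so the whole
#' protocol is reproducible from one integer.
#'
#' @param ds a normalized [tabular_dataset()] (missing values resolved).
#' @param enc_cfg an [encoding_config()].
#' @param cfg a [train_config()]; `cfg$attempts` controls the number of
#'   re-split/re-train cycles.
#' @param split an optional [split_spec()] template (its seed is
#'   overridden per attempt).
#' @return an object of class `"experiment_report"`: per-attempt
#'   validation/test accuracies (percent), best/mean aggregates, and the
#'   per-attempt [eval_metrics()] reports.
#' @export
run_experiment <- function(ds, enc_cfg = encoding_config("combined"),
                           cfg = train_config(), split = split_spec()) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (!ds$normalized) stop("normalize the dataset before running")
  val_acc <- test_acc <- numeric(cfg$attempts)
  reports <- vector("list", cfg$attempts)
  arch <- NULL
  for (a in seq_len(cfg$attempts)) {
    seed_a <- cfg$seed + a
    sp <- split_spec(split$test_fraction,
                     split$validation_fraction_of_train,
                     seed = seed_a, stratified = split$stratified)
    parts <- split_dataset(ds, sp)
    img_train <- encode_array(parts$train, enc_cfg)
    if (is.null(arch))
      arch <- build_architecture(dim(img_train)[1L], dim(img_train)[2L],
                                 dim(img_train)[3L])
    cfg_a <- cfg; cfg_a$seed <- seed_a
    fit <- train_cnn(img_train, parts$train$labels, arch, cfg_a)
    pred_val <- predict(fit, encode_array(parts$validation, enc_cfg))
    pred_test <- predict(fit, encode_array(parts$test, enc_cfg))
    val_acc[a] <- 100 * mean(pred_val == parts$validation$labels)
    test_acc[a] <- 100 * mean(pred_test == parts$test$labels)
    reports[[a]] <- eval_metrics(confusion(parts$test$labels, pred_test))
  }
  structure(list(
    method = enc_cfg$method, px = enc_cfg$px, attempts = cfg$attempts,
    val_accuracy = val_acc, test_accuracy = test_acc,
    best = c(val = max(val_acc), test = max(test_acc)),
    mean = c(val = mean(val_acc), test = mean(test_acc)),
    reports = reports,
    metric_summary = summarize_reports(reports)),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: method %s, px%d, %d attempts\n",
              x$method, x$px, x$attempts))
  cat(sprintf("  best   : val %.2f%%  test %.2f%%\n",
              x$best["val"], x$best["test"]))
  cat(sprintf("  average: val %.2f%%  test %.2f%%\n",
              x$mean["val"], x$mean["test"]))
  s <- x$metric_summary$percent
  cat(sprintf("  test metrics (avg): sensitivity %.2f  specificity %.2f  F1 %.2f\n",
              s$average["sensitivity"], s$average["specificity"],
              s$average["f1"]))
  invisible(x)
}

#' Tabulate experiment reports like the published accuracy tables
#'
#' @param reports named list of `experiment_report` objects (names used
#'   as row labels, e.g. encoder/px combinations).
#' @return data frame with best/mean validation and test accuracy per row.
#' @export
experiment_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(setting = nm, method = r$method, px = r$px,
               best_val = round(r$best["val"], 2),
               best_test = round(r$best["test"], 2),
               mean_val = round(r$mean["val"], 2),
               mean_test = round(r$mean["test"], 2),
               row.names = NULL)
  }))
}
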