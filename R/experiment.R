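#' Default run configuration
#'
#' A complete, nested run configuration for the experiment runner.  The
#' training block carries the reference protocol (Adam, learning rate
#' 1e-4, minibatch 64, epoch budget 64); the data block defaults to the
#' built-in phantom generator so a run never requires a download.
#'
#' @param seed Integer master seed (data generation, split, weight
#'   initialization and shuffling all derive from it).
#' @return Nested list, serializable to YAML with [write_run_config()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    data = list(source = "phantom", root = NULL,
                n_per_class = 100L, image_size = c(224L, 224L),
                noise_sd = 0.05),
    split = list(fractions = c(0.7, 0.1, 0.2), stratified = TRUE),
    activation = list(name = "rectified_softsign", slope = 0.01,
                      ceiling = 10, alpha = 1.0,
                      gelu_constant = 1 / sqrt(2)),
    training = list(learning_rate = 1e-4, batch_size = 64L,
                    max_epochs = 64L, early_stop_patience = NULL))
}

#' Read / write a run configuration
#'
#' Run configurations are plain YAML files mirroring the structure of
#' [default_run_config()]; fields missing from the file keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return `read_run_config()`: the merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_digest_ <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

activation_from_config_ <- function(a) {
  activation_spec(a$name,
                  slope = a$slope %||% 0.01,
                  ceiling = a$ceiling %||% 10,
                  alpha = a$alpha %||% 1,
                  gelu_constant = a$gelu_constant %||% (1 / sqrt(2)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

load_or_generate_ <- function(cfg) {
  d <- cfg$data
  if (identical(d$source, "phantom")) {
    generate_phantoms(n_per_class = d$n_per_class %||% 100L,
                      image_size = d$image_size %||% c(224L, 224L),
                      noise_sd = d$noise_sd %||% 0.05,
                      seed = cfg$seed)
  } else if (identical(d$source, "folder")) {
    if (is.null(d$root)) stop("data$root is required for source 'folder'",
                              call. = FALSE)
    load_image_folder(d$root, target_size = d$image_size %||% c(224L, 224L))
  } else {
    stop("unknown data source '", d$source, "'", call. = FALSE)
  }
}

evaluate_run_ <- function(model, test_set, history, act_name, seed, digest) {
  pr <- predict(model, test_set)
  cm <- confusion(test_set$labels, pr$labels,
                  k = length(test_set$class_names),
                  class_names = test_set$class_names)
  tab <- metrics_table(cm)
  rocs <- multiclass_roc(pr$probs, test_set$labels)
  structure(list(
    activation = act_name,
    test_accuracy = accuracy(cm),
    macro_precision = mean(tab$precision, na.rm = TRUE),
    macro_recall = mean(tab$recall, na.rm = TRUE),
    macro_f1 = macro_f1(cm),
    mean_auc = mean(vapply(rocs, `[[`, numeric(1), "auc")),
    per_class = tab,
    confusion = cm,
    roc = rocs,
    history = history,
    probs = pr$probs,
    seed = seed,
    config_digest = digest), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result> %s: accuracy %.3f, macro F1 %.3f, mean AUC %.3f\n",
    x$activation, x$test_accuracy, x$macro_f1, x$mean_auc))
  invisible(x)
}

write_run_outputs_ <- function(res, model, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  write.csv(res$per_class, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(unclass(res$confusion)),
            file.path(out_dir, "confusion.csv"))
  roc_df <- do.call(rbind, lapply(seq_along(res$roc), function(k)
    data.frame(class = k, fpr = res$roc[[k]]$fpr, tpr = res$roc[[k]]$tpr)))
  write.csv(roc_df, file.path(out_dir, "roc.csv"), row.names = FALSE)
  write.csv(res$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  saveRDS(model, file.path(out_dir, "model.rds"))
  summary_df <- data.frame(activation = res$activation,
                           test_accuracy = res$test_accuracy,
                           macro_precision = res$macro_precision,
                           macro_recall = res$macro_recall,
                           macro_f1 = res$macro_f1,
                           mean_auc = res$mean_auc,
                           seed = res$seed,
                           config_digest = res$config_digest)
  write.csv(summary_df, file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Run one training/evaluation experiment
#'
#' Executes the full pipeline for a single activation: load or generate
#' the data, split it, build the network, train, and evaluate on the
#' held-out test split (confusion matrix, per-class precision/recall/F1,
#' one-vs-rest ROC/AUC).  With `out_dir` set, the run directory receives
#' `config.yaml`, `metrics.csv`, `confusion.csv`, `roc.csv`,
#' `history.csv`, `summary.csv` and the model checkpoint.
#'
#' @param config Configuration list (see [default_run_config()]) or path
#'   to a YAML file.
#' @param out_dir Optional output directory.
#' @return A `run_result` object; the trained model is attached as
#'   attribute `"model"`.
#' @export
run_experiment <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  act <- activation_from_config_(config$activation)  # fail fast
  digest <- config_digest_(config)
  dataset <- load_or_generate_(config)
  splits <- split_dataset(dataset,
                          fractions = config$split$fractions %||% c(0.7, 0.1, 0.2),
                          seed = config$seed,
                          stratified = config$split$stratified %||% TRUE)
  rm(dataset)
  k <- length(splits$train$class_names)
  net <- network_spec(input_shape = c(dim(splits$train$images)[1:3]),
                      num_classes = k)
  model <- build_network(net, act, seed = config$seed)
  tcfg <- train_config(
    learning_rate = config$training$learning_rate %||% 1e-4,
    batch_size = config$training$batch_size %||% 64L,
    max_epochs = config$training$max_epochs %||% 64L,
    seed = config$seed,
    early_stop_patience = config$training$early_stop_patience,
    verbose = isTRUE(config$training$verbose))
  fit <- train_network(model, splits$train, splits$val, tcfg)
  res <- evaluate_run_(fit$model, splits$test, fit$history, act$name,
                       config$seed, digest)
  if (!is.null(out_dir)) write_run_outputs_(res, fit$model, config, out_dir)
  attr(res, "model") <- fit$model
  res
}

#' Sweep all nine activation functions
#'
#' Runs [run_experiment()] once per activation while holding the data,
#' the split, the initialization seed and the training budget fixed, so
#' that differences in the comparison table are attributable to the
#' activation alone.  A failure in one activation is recorded and the
#' sweep continues.
#'
#' @param config Base configuration (list or YAML path); its
#'   `activation$name` is ignored.
#' @param out_dir Optional directory; each activation gets a
#'   subdirectory, and the comparison table is written as
#'   `sweep.csv`.
#' @param activations Activations to sweep (default all nine).
#' @return Data frame with one row per activation: `activation`,
#'   `test_accuracy`, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `mean_auc`, `error`.  Per-run results are attached as attribute
#'   `"results"`; the shared test indices as attribute
#'   `"test_indices"`.
#' @export
run_sweep <- function(config = default_run_config(), out_dir = NULL,
                      activations = list_activations()) {
  if (is.character(config)) config <- read_run_config(config)
  dataset <- load_or_generate_(config)
  splits <- split_dataset(dataset,
                          fractions = config$split$fractions %||% c(0.7, 0.1, 0.2),
                          seed = config$seed,
                          stratified = config$split$stratified %||% TRUE)
  test_idx <- attr(splits, "indices")$test
  rm(dataset)
  k <- length(splits$train$class_names)
  net <- network_spec(input_shape = c(dim(splits$train$images)[1:3]),
                      num_classes = k)
  tcfg <- train_config(
    learning_rate = config$training$learning_rate %||% 1e-4,
    batch_size = config$training$batch_size %||% 64L,
    max_epochs = config$training$max_epochs %||% 64L,
    seed = config$seed,
    early_stop_patience = config$training$early_stop_patience,
    verbose = isTRUE(config$training$verbose))

  results <- list(); rows <- list()
  for (a in activations) {
    cfg_a <- config; cfg_a$activation$name <- a
    row <- data.frame(activation = a, test_accuracy = NA_real_,
                      macro_precision = NA_real_, macro_recall = NA_real_,
                      macro_f1 = NA_real_, mean_auc = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      act <- activation_from_config_(cfg_a$activation)
      model <- build_network(net, act, seed = config$seed)
      fit <- train_network(model, splits$train, splits$val, tcfg)
      r <- evaluate_run_(fit$model, splits$test, fit$history, a,
                         config$seed, config_digest_(cfg_a))
      if (!is.null(out_dir))
        write_run_outputs_(r, fit$model, cfg_a, file.path(out_dir, a))
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$test_accuracy <- res$test_accuracy
      row$macro_precision <- res$macro_precision
      row$macro_recall <- res$macro_recall
      row$macro_f1 <- res$macro_f1
      row$mean_auc <- res$mean_auc
      results[[a]] <- res
    }
    rows[[a]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$test_accuracy, out$activation), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  }
  attr(out, "results") <- results
  attr(out, "test_indices") <- test_idx
  out
}
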