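# End-to-end pipeline: normalize -> fuzzy partition -> per-partition
# feature selection -> fusion -> subspace-rotation ensemble. The
# per-partition selection stage is an embarrassingly parallel map and runs
# through an execution-backend contract (serial or forked processes) with
# identical results either way.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and derives every stage seed from
#' one master seed so a run is reproducible end to end.
#'
#' @param idfc An [idfc_config].
#' @param mrfe An [mrfe_config].
#' @param ensemble An [ensemble_config].
#' @param normalize_before_split If TRUE the evaluation harness normalizes
#'   the full dataset before splitting (the order many small-benchmark
#'   studies use); the default FALSE fits normalization on the training
#'   side only, which is leakage-safe.
#' @param backend `"serial"` or `"process_parallel"` for the
#'   per-partition selection stage.
#' @param workers Worker count for the parallel backend.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(idfc = idfc_config(), mrfe = mrfe_config(),
                            ensemble = ensemble_config(),
                            normalize_before_split = FALSE,
                            backend = c("serial", "process_parallel"),
                            workers = 2L, seed = 1L) {
  backend <- match.arg(backend)
  structure(list(idfc = idfc, mrfe = mrfe, ensemble = ensemble,
                 normalize_before_split = normalize_before_split,
                 backend = backend, workers = as.integer(workers),
                 seed = as.integer(seed)), class = "pipeline_config")
}

# Re-seed every stage config from the master seed.
reseed_config <- function(config, seed) {
  config$seed <- as.integer(seed)
  config$idfc$seed <- derive_seed(seed, "idfc")
  config$mrfe$seed <- derive_seed(seed, "mrfe")
  config$ensemble$seed <- derive_seed(seed, "ensemble")
  config
}

#' Deterministic parallel map over independent tasks
#'
#' Runs a list of zero-argument task closures either serially or on forked
#' worker processes. Each task must carry its own seed (the pipeline
#' derives them from the master seed), so results are identical across
#' backends and worker counts. A failing task is retried once, then the
#' whole map aborts naming the task.
#'
#' @param tasks Named list of functions taking no arguments.
#' @param backend `"serial"` or `"process_parallel"`.
#' @param workers Number of forked workers.
#' @return List of task results in task order.
#' @export
parallel_map <- function(tasks, backend = c("serial", "process_parallel"),
                         workers = 2L) {
  backend <- match.arg(backend)
  if (length(tasks) == 0) return(list())
  run_one <- function(i) {
    out <- tryCatch(tasks[[i]](), error = function(e) e)
    if (inherits(out, "error")) {                       # one retry
      out <- tryCatch(tasks[[i]](), error = function(e) e)
    }
    out
  }
  res <- if (backend == "serial" || workers <= 1L) {
    lapply(seq_along(tasks), run_one)
  } else {
    parallel::mclapply(seq_along(tasks), run_one,
                       mc.cores = workers, mc.preschedule = TRUE)
  }
  for (i in seq_along(res)) {
    if (inherits(res[[i]], "error") || inherits(res[[i]], "try-error")) {
      nm <- names(tasks)[i]
      stop("task ", if (!is.null(nm) && nzchar(nm)) nm else i,
           " failed after retry: ", conditionMessage(res[[i]]))
    }
  }
  names(res) <- names(tasks)
  res
}

# Partition the (already normalized) training matrix and select features
# per partition; returns the fused feature set plus stage artifacts.
partition_and_select <- function(Xn, labels, config) {
  idfc_fit <- fit_idfc(Xn, config$idfc)
  parts <- assign_partitions(idfc_fit$state, labels)
  tasks <- lapply(seq_along(parts$partitions), function(p) {
    idx <- parts$partitions[[p]]
    force(idx); force(p)
    function() {
      Xp <- Xn[idx, , drop = FALSE]
      yp <- labels[idx]
      cfg <- config$mrfe
      cfg$seed <- derive_seed(config$mrfe$seed, paste0("part", p))
      if (ncol(Xp) <= cfg$n_select) {
        structure(list(partition_id = p, kept_indices = seq_len(ncol(Xp)),
                       elimination_trace = list(), feature_names = colnames(Xn)),
                  class = "selected_features")
      } else {
        mrfe_select(Xp, yp, cfg, partition_id = p,
                    feature_names = colnames(Xn))
      }
    }
  })
  names(tasks) <- paste0("select_P", seq_along(tasks))
  selections <- parallel_map(tasks, config$backend, config$workers)
  fused <- fuse_features(selections)
  list(idfc_fit = idfc_fit, partitions = parts, selections = selections,
       fused = fused)
}

#' Fit the full classification pipeline on training data
#'
#' Normalizes (min-max, fitted on the supplied data), partitions the
#' samples by deep fuzzy clustering, selects features per partition with
#' the hybrid recursive elimination, fuses the selections, and fits the
#' subspace-rotation ensemble on the fused features.
#'
#' @param train A [data_matrix] of training samples.
#' @param config A [pipeline_config]; its master seed reseeds all stages.
#' @param normalize If FALSE the data are assumed normalized already and
#'   the min-max stage is skipped (identity parameters recorded).
#' @return Object of class `pipeline_fit`.
#' @export
fit_pipeline <- function(train, config = pipeline_config(), normalize = TRUE) {
  config <- reseed_config(config, config$seed)
  if (normalize) {
    minmax <- fit_minmax(train)
    Xn <- apply_minmax(minmax, train)
  } else {
    minmax <- NULL
    Xn <- train
  }
  stage <- partition_and_select(Xn$values, Xn$labels, config)
  ens <- fit_ensemble(Xn$values, Xn$labels, stage$fused, config$ensemble)
  structure(list(minmax = minmax, idfc_fit = stage$idfc_fit,
                 partitions = stage$partitions,
                 selections = stage$selections, fused = stage$fused,
                 ensemble = ens, config = config,
                 classes = levels(Xn$labels)),
            class = "pipeline_fit")
}

#' Predict with a fitted pipeline
#'
#' @param object A `pipeline_fit`.
#' @param newdata A [data_matrix] or numeric matrix in the training
#'   feature order.
#' @param ... Unused.
#' @return List with `labels` and `vote_fractions`.
#' @export
predict.pipeline_fit <- function(object, newdata, ...) {
  V <- if (inherits(newdata, "data_matrix")) newdata$values else as.matrix(newdata)
  if (!is.null(object$minmax)) V <- apply_minmax(object$minmax, V)
  predict(object$ensemble, V)
}

#' Run the pipeline end to end and write artifacts
#'
#' Convenience driver for the command-line interface: loads or accepts a
#' dataset, makes a stratified split, fits the pipeline on the training
#' side, evaluates on the test side, and writes every intermediate
#' artifact (normalized matrix, partition table, per-partition and fused
#' feature tables, predictions, metrics, run manifest) under `out_dir`.
#'
#' @param data A [data_matrix], or a file path readable by [read_matrix()].
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config].
#' @param ratio Train fraction of the stratified split.
#' @param label_column,delimiter Passed to [read_matrix()] when `data` is
#'   a path.
#' @return The evaluation result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(data, out_dir, config = pipeline_config(),
                         ratio = 0.8, label_column = "class",
                         delimiter = ",") {
  if (is.character(data)) data <- read_matrix(data, label_column, delimiter)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  split <- stratified_split(data, ratio, derive_seed(config$seed, "split"))
  train <- data[split$train, ]
  test <- data[split$test, ]
  fit <- fit_pipeline(train, config)

  write_matrix(apply_minmax(fit$minmax, train),
               file.path(out_dir, "train_normalized.csv"))
  utils::write.csv(
    data.frame(sample_id = train$sample_ids,
               partition_id = fit$partitions$assignment),
    file.path(out_dir, "partitions.csv"), row.names = FALSE)
  sel_tab <- do.call(rbind, lapply(fit$selections, function(s) {
    data.frame(partition_id = s$partition_id, original_index = s$kept_indices,
               feature_name = train$feature_names[s$kept_indices])
  }))
  utils::write.csv(sel_tab, file.path(out_dir, "selected_features.csv"),
                   row.names = FALSE)
  trace_tab <- do.call(rbind, lapply(fit$selections, function(s) {
    if (length(s$elimination_trace) == 0) return(NULL)
    data.frame(partition_id = s$partition_id,
               iteration = rep(seq_along(s$elimination_trace),
                               lengths(s$elimination_trace)),
               dropped_index = unlist(s$elimination_trace))
  }))
  if (!is.null(trace_tab)) {
    utils::write.csv(trace_tab, file.path(out_dir, "elimination_trace.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(original_index = fit$fused$indices,
               feature_name = train$feature_names[fit$fused$indices],
               n_partitions = lengths(fit$fused$provenance)),
    file.path(out_dir, "fused_features.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(epoch = seq_along(fit$idfc_fit$loss_trajectory),
               loss = fit$idfc_fit$loss_trajectory),
    file.path(out_dir, "idfc_loss.csv"), row.names = FALSE)

  pred <- predict(fit, test)
  utils::write.csv(
    cbind(data.frame(sample_id = test$sample_ids, true = test$labels,
                     predicted = pred$labels), pred$vote_fractions),
    file.path(out_dir, "predictions.csv"), row.names = FALSE)
  rep <- evaluate_predictions(test$labels, pred$labels, pred$vote_fractions)
  jsonlite::write_json(report_as_list(rep), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = config$seed, ratio = ratio,
                   n_train = length(split$train), n_test = length(split$test),
                   n_features = ncol(train$values),
                   n_fused = length(fit$fused$indices),
                   backend = config$backend,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  saveRDS(fit, file.path(out_dir, "model.rds"))
  invisible(rep)
}

# Flatten a metrics report (plus optional auc) for JSON output.
report_as_list <- function(rep) {
  keys <- c("accuracy", "sensitivity", "specificity", "precision",
            "f_measure", "mcc", "npv", "fpr", "fnr")
  out <- lapply(keys, function(k) rep[[k]])
  names(out) <- keys
  if (!is.null(rep$auc)) out$auc <- rep$auc
  out
}

# Shared scoring: binary tasks get the full nine-metric report + AUC,
# multiclass gets macro metrics + plain accuracy.
evaluate_predictions <- function(y_true, y_pred, vote_fractions = NULL) {
  classes <- levels(factor(y_true))
  if (length(classes) == 2) {
    rep <- compute_metrics(confusion(y_true, y_pred, classes[2]))
    if (!is.null(vote_fractions)) {
      rep$auc <- roc_auc(y_true, vote_fractions[, classes[2]], classes[2])$auc
    }
    rep
  } else {
    mm <- multiclass_metrics(y_true, y_pred)
    out <- as.list(mm$macro)
    out$accuracy <- mm$accuracy
    out$per_class <- mm$per_class
    class(out) <- "metrics_report"
    out
  }
}
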