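# Experiment harness: repeated stratified 80:20 evaluation, optional
# cross-validated hyperparameter selection, the gamma x alpha sensitivity
# sweep, and the ablation variants (single-kernel clustering /
# margin-only elimination).

#' Default hyperparameter grid for cross-validated selection
#'
#' @param gamma Candidate subspace ratios.
#' @param alpha_mse Candidate mixing coefficients.
#' @return data.frame with one row per combination.
#' @export
default_grid <- function(gamma = seq(0.2, 0.8, by = 0.2),
                         alpha_mse = c(0.25, 0.5, 0.75)) {
  expand.grid(gamma = gamma, alpha_mse = alpha_mse)
}

apply_grid_row <- function(config, row) {
  if (!is.null(row$gamma)) config$ensemble$subspace_ratio <- row$gamma
  if (!is.null(row$alpha_mse)) config$ensemble$alpha_mse <- row$alpha_mse
  if (!is.null(row$alpha_kernel)) config$idfc$kernel$alpha_kernel <- row$alpha_kernel
  if (!is.null(row$alpha_rank)) config$mrfe$alpha_rank <- row$alpha_rank
  config
}

# One split -> fit on train -> metrics on test.
evaluate_split <- function(data, config, split, normalize_before_split = FALSE) {
  if (normalize_before_split) {
    data <- apply_minmax(fit_minmax(data), data)
    normalize <- FALSE
  } else {
    normalize <- TRUE
  }
  train <- data[split$train, ]
  test <- data[split$test, ]
  fit <- fit_pipeline(train, config, normalize = normalize)
  pred <- predict(fit, test)
  rep <- evaluate_predictions(test$labels, pred$labels, pred$vote_fractions)
  list(report = rep, fit = fit, prediction = pred, test_labels = test$labels)
}

#' Repeated stratified-split evaluation of the full pipeline
#'
#' For each seed: a stratified 80:20 split, optional k-fold
#' cross-validated selection over a hyperparameter grid on the training
#' side, a final fit on the full training side, and metrics on the
#' untouched test side.
#'
#' @param data A [data_matrix].
#' @param config A [pipeline_config].
#' @param seeds Integer vector; one full evaluation per seed.
#' @param ratio Train fraction.
#' @param grid Optional data.frame of hyperparameter candidates (columns
#'   among `gamma`, `alpha_mse`, `alpha_kernel`, `alpha_rank`); `NULL`
#'   (default) skips tuning and uses `config` as-is. See [default_grid()].
#' @param cv_folds Folds for the inner cross-validation when a grid is
#'   supplied.
#' @return Object of class `experiment_result`: `per_seed` (list of
#'   metrics reports), `mean`/`sd` per metric, `chosen` (per-seed grid
#'   rows), config snapshot.
#' @export
run_experiment <- function(data, config = pipeline_config(),
                           seeds = 1:5, ratio = 0.8, grid = NULL,
                           cv_folds = 5L) {
  if (!is.null(grid) && nrow(grid) == 0) stop("empty hyperparameter grid")
  per_seed <- vector("list", length(seeds))
  chosen <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    split <- stratified_split(data, ratio, derive_seed(seed, "outer_split"))
    cfg <- config
    cfg$seed <- derive_seed(seed, "pipeline")
    if (!is.null(grid) && nrow(grid) > 1) {
      train <- data[split$train, ]
      cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
        gcfg <- apply_grid_row(cfg, grid[g, , drop = FALSE])
        cv_accuracy(train, gcfg, cv_folds, derive_seed(seed, "inner_cv"))
      }, numeric(1))
      best <- which.max(cv_acc)
      chosen[[si]] <- grid[best, , drop = FALSE]
      cfg <- apply_grid_row(cfg, grid[best, , drop = FALSE])
    } else if (!is.null(grid)) {
      chosen[[si]] <- grid[1, , drop = FALSE]
      cfg <- apply_grid_row(cfg, grid[1, , drop = FALSE])
    }
    res <- evaluate_split(data, cfg, split, config$normalize_before_split)
    per_seed[[si]] <- res$report
  }
  keys <- c("accuracy", "sensitivity", "specificity", "precision",
            "f_measure", "mcc", "npv", "fpr", "fnr")
  vals <- sapply(keys, function(k)
    vapply(per_seed, function(r) r[[k]] %||% NA_real_, numeric(1)))
  vals <- matrix(vals, nrow = length(per_seed),
                 dimnames = list(NULL, keys))
  structure(list(per_seed = per_seed, seeds = seeds,
                 mean = colMeans(vals), sd = apply(vals, 2, stats::sd),
                 values = vals, chosen = chosen, config = config),
            class = "experiment_result")
}

# Stratified k-fold CV accuracy of the pipeline on training data only.
cv_accuracy <- function(train, config, folds, seed) {
  fold_id <- stratified_folds(train$labels, folds, seed)
  acc <- numeric(0)
  for (f in sort(unique(fold_id))) {
    tr <- train[which(fold_id != f), ]
    te <- train[which(fold_id == f), ]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("cvfold", f))
    fit <- fit_pipeline(tr, cfg)
    pred <- predict(fit, te)
    acc <- c(acc, mean(as.character(pred$labels) == as.character(te$labels)))
  }
  mean(acc)
}

#' Sensitivity sweep over the subspace ratio and a kernel/mixing alpha
#'
#' Evaluates mean test accuracy per (gamma, alpha) cell over seeds.
#' `which_alpha = "kernel"` (default) varies the hybrid-kernel mixing
#' weight of the clustering stage, refitting partitioning + selection per
#' (seed, alpha) and sharing them across gamma cells (gamma only affects
#' the ensemble stage); `"mse"` varies the mixed-space coefficient, so
#' partitioning + selection are fitted once per seed.
#'
#' @param data A [data_matrix].
#' @param config A [pipeline_config].
#' @param gamma_grid Subspace ratios to sweep.
#' @param alpha_grid Alpha values to sweep.
#' @param seeds Seeds (one outer split per seed).
#' @param which_alpha `"kernel"` or `"mse"`.
#' @param ratio Train fraction.
#' @return Object of class `sensitivity_grid`: `accuracy_surface`
#'   (|gamma| x |alpha|), `gamma_values`, `alpha_values`, `spread`
#'   (max - min of the surface).
#' @export
sensitivity_sweep <- function(data, config = pipeline_config(),
                              gamma_grid = c(0.2, 0.4, 0.6, 0.8),
                              alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                              seeds = 1:3,
                              which_alpha = c("kernel", "mse"),
                              ratio = 0.8) {
  which_alpha <- match.arg(which_alpha)
  if (length(gamma_grid) == 0 || length(alpha_grid) == 0) stop("empty grid")
  surf <- array(0, c(length(gamma_grid), length(alpha_grid), length(seeds)))
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    split <- stratified_split(data, ratio, derive_seed(seed, "outer_split"))
    dat <- if (config$normalize_before_split)
      apply_minmax(fit_minmax(data), data) else data
    train <- dat[split$train, ]
    test <- dat[split$test, ]
    base_cfg <- reseed_config(config, derive_seed(seed, "pipeline"))
    if (config$normalize_before_split) {
      minmax <- NULL; Xn_tr <- train
    } else {
      minmax <- fit_minmax(train)
      Xn_tr <- apply_minmax(minmax, train)
    }
    Xn_te <- if (is.null(minmax)) test else apply_minmax(minmax, test)

    eval_cells <- function(stage, cfg, ai) {
      for (gi in seq_along(gamma_grid)) {
        ecfg <- cfg$ensemble
        ecfg$subspace_ratio <- gamma_grid[gi]
        ens <- fit_ensemble(Xn_tr$values, Xn_tr$labels, stage$fused, ecfg)
        pred <- predict(ens, Xn_te$values)
        surf[gi, ai, si] <<-
          mean(as.character(pred$labels) == as.character(Xn_te$labels))
      }
    }
    if (which_alpha == "kernel") {
      for (ai in seq_along(alpha_grid)) {
        cfg <- base_cfg
        cfg$idfc$kernel$alpha_kernel <- alpha_grid[ai]
        stage <- partition_and_select(Xn_tr$values, Xn_tr$labels, cfg)
        eval_cells(stage, cfg, ai)
      }
    } else {
      stage <- partition_and_select(Xn_tr$values, Xn_tr$labels, base_cfg)
      for (ai in seq_along(alpha_grid)) {
        cfg <- base_cfg
        cfg$ensemble$alpha_mse <- alpha_grid[ai]
        eval_cells(stage, cfg, ai)
      }
    }
  }
  surface <- apply(surf, c(1, 2), mean)
  dimnames(surface) <- list(paste0("gamma=", gamma_grid),
                            paste0("alpha=", alpha_grid))
  structure(list(gamma_values = gamma_grid, alpha_values = alpha_grid,
                 accuracy_surface = surface,
                 spread = max(surface) - min(surface),
                 which_alpha = which_alpha, seeds = seeds),
            class = "sensitivity_grid")
}

#' Ablation: full pipeline vs single-kernel clustering vs margin-only RFE
#'
#' Runs three variants on identical seeds and splits: the full pipeline;
#' the clustering stage restricted to the pure Gaussian kernel
#' (`alpha_kernel = 1`, the conventional deep fuzzy clustering); and the
#' selection stage restricted to margin-only ranking (`alpha_rank = 1`,
#' conventional SVM-RFE).
#'
#' @param data A [data_matrix].
#' @param config A [pipeline_config].
#' @param seeds Seeds shared across variants (paired comparison).
#' @param ratio Train fraction.
#' @return Named list of `experiment_result`s:
#'   `full`, `conventional_dfc`, `conventional_rfe`.
#' @export
ablation <- function(data, config = pipeline_config(), seeds = 1:5,
                     ratio = 0.8) {
  cfg_dfc <- config
  cfg_dfc$idfc$kernel$alpha_kernel <- 1
  cfg_rfe <- config
  cfg_rfe$mrfe$alpha_rank <- 1
  list(full = run_experiment(data, config, seeds, ratio),
       conventional_dfc = run_experiment(data, cfg_dfc, seeds, ratio),
       conventional_rfe = run_experiment(data, cfg_rfe, seeds, ratio))
}

#' Tidy per-seed results table
#'
#' Flattens one or more experiment results into a long data.frame
#' (variant, seed, metric, value) ready for downstream significance
#' testing or plotting.
#'
#' @param ... Named `experiment_result` objects (or a single list of
#'   them, e.g. the output of [ablation()]).
#' @return data.frame with columns `variant`, `seed`, `metric`, `value`.
#' @export
tidy_results <- function(...) {
  args <- list(...)
  if (length(args) == 1 && !inherits(args[[1]], "experiment_result")) {
    args <- args[[1]]
  }
  if (is.null(names(args)) || any(names(args) == "")) {
    names(args) <- paste0("variant", seq_along(args))
  }
  do.call(rbind, lapply(names(args), function(nm) {
    res <- args[[nm]]
    v <- res$values
    data.frame(variant = nm,
               seed = rep(res$seeds, times = ncol(v)),
               metric = rep(colnames(v), each = nrow(v)),
               value = as.vector(v), row.names = NULL)
  }))
}
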