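# Thin uniform interface over the heterogeneous base learners used by the
# ensemble blocks: random forest, RBF support vector machine, and the
# weighted-Minkowski KNN implemented in this package.

#' Fit a base learner
#'
#' @param kind One of `"random_forest"`, `"svm"`, `"iknn"`.
#' @param X Training matrix.
#' @param y Training labels (factor).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param params Optional list of kind-specific parameters
#'   (`ntree` for the forest; `cost`, `gamma` for the SVM;
#'   `k`, `rho`, `scope` for the KNN).
#' @return Object of class `base_learner` wrapping the fitted model.
#' @export
fit_learner <- function(kind, X, y, seed = 1L, params = list()) {
  kind <- match.arg(kind, c("random_forest", "svm", "iknn"))
  X <- as.matrix(X); y <- factor(y)
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  rng <- local_rng(seed)
  fit <- switch(kind,
    random_forest = rng$with(randomForest::randomForest(
      x = X, y = y, ntree = params$ntree %||% 300L)),
    svm = rng$with(e1071::svm(
      X, y, kernel = "radial", probability = TRUE,
      cost = params$cost %||% 1, gamma = params$gamma %||% (1 / ncol(X)))),
    iknn = fit_iknn(X, y,
                    k = params$k %||% 5L, rho = params$rho %||% 2,
                    scope = params$scope %||% "neighbors",
                    seed = derive_seed(seed, "iknn")))
  structure(list(kind = kind, fit = fit, classes = levels(y)),
            class = "base_learner")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict labels with a fitted base learner
#'
#' @param object A `base_learner`.
#' @param newdata Query matrix.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.base_learner <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  p <- switch(object$kind,
    random_forest = predict(object$fit, X),
    svm = predict(object$fit, X),
    iknn = predict(object$fit, X))
  factor(as.character(p), levels = object$classes)
}

# Optional per-class score matrix (n x classes); NULL when the learner
# exposes none (the ensemble then falls back to index-order tie-breaks).
learner_scores <- function(object, newdata) {
  X <- as.matrix(newdata)
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  out <- switch(object$kind,
    random_forest = {
      pr <- predict(object$fit, X, type = "prob")
      pr[, object$classes, drop = FALSE]
    },
    svm = {
      pr <- attr(predict(object$fit, X, probability = TRUE), "probabilities")
      pr[, object$classes, drop = FALSE]
    },
    iknn = NULL)
  out
}
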