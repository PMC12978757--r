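# Weighted-Minkowski k-nearest-neighbour classifier. Feature weights are
# derived from "value parameters": the accuracy change of a conventional
# KNN when each feature is left out, so features whose removal helps get
# down-weighted and features whose removal hurts get up-weighted.

#' Cross-validated accuracy of a conventional Euclidean KNN
#'
#' Stratified k-fold cross-validation of plain majority-vote KNN with
#' Euclidean distances, averaged over the supplied neighbourhood sizes
#' (default k = 3, 5, 7). Deterministic given `seed`.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels.
#' @param k_values Neighbourhood sizes to average over.
#' @param folds Number of CV folds (reduced with a warning if a class is
#'   smaller than `folds`).
#' @param seed Integer seed for the fold assignment.
#' @return Mean accuracy in [0, 1].
#' @export
knn_cv_accuracy <- function(X, y, k_values = c(3L, 5L, 7L), folds = 3L,
                            seed = 1L) {
  X <- as.matrix(X); y <- factor(y)
  if (nlevels(y) < 2) stop("single-class input")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class (", min_class, ") < folds (", folds,
            "); reducing folds")
    folds <- max(2L, min_class)
  }
  fold_id <- stratified_folds(y, folds, seed)
  D2 <- full_dist2(X)
  mean(vapply(k_values, function(k) {
    knn_cv_accuracy_dist(D2, y, fold_id, k)
  }, numeric(1)))
}

# Squared Euclidean distance matrix of the rows of X.
full_dist2 <- function(X) {
  as.matrix(stats::dist(X))^2
}

stratified_folds <- function(y, folds, seed) {
  rng <- local_rng(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- rng$sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

# CV accuracy for one k given a precomputed squared-distance matrix.
knn_cv_accuracy_dist <- function(D2, y, fold_id, k) {
  correct <- 0L
  for (f in unique(fold_id)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    kk <- min(k, length(tr))
    for (i in te) {
      nb <- tr[order(D2[i, tr], tr)[seq_len(kk)]]
      votes <- table(y[nb])
      winners <- names(votes)[votes == max(votes)]
      pred <- winners[1]  # ties toward the lowest class index
      if (pred == as.character(y[i])) correct <- correct + 1L
    }
  }
  correct / length(y)
}

#' Per-feature value parameters from leave-one-feature-out KNN accuracy
#'
#' `acc_e` is the cross-validated accuracy of the conventional KNN on all
#' features; `acc_0(i)` the same with feature i removed. The value
#' parameter is \eqn{\nu_{p,i} = 1 - (acc_0(i) - acc_e)}, clamped at 1e-6:
#' a feature whose removal raises accuracy is down-weighted, one whose
#' removal lowers accuracy is up-weighted.
#'
#' @inheritParams knn_cv_accuracy
#' @return List with `value_params`, `acc_e`, `acc_0`.
#' @export
compute_value_params <- function(X, y, k_values = c(3L, 5L, 7L), folds = 3L,
                                 seed = 1L) {
  X <- as.matrix(X); y <- factor(y)
  t_ <- ncol(X)
  if (t_ < 2) stop("need at least 2 features")
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class (", min_class, ") < folds (", folds,
            "); reducing folds")
    folds <- max(2L, min_class)
  }
  fold_id <- stratified_folds(y, folds, seed)
  D2 <- full_dist2(X)
  acc_for <- function(D2m) {
    mean(vapply(k_values, function(k) knn_cv_accuracy_dist(D2m, y, fold_id, k),
                numeric(1)))
  }
  acc_e <- acc_for(D2)
  acc_0 <- vapply(seq_len(t_), function(i) {
    di <- outer(X[, i], X[, i], "-")^2    # remove feature i by subtraction
    acc_for(pmax(D2 - di, 0))
  }, numeric(1))
  vp <- pmax(1 - (acc_0 - acc_e), 1e-6)
  list(value_params = vp, acc_e = acc_e, acc_0 = acc_0)
}

#' Normalize value parameters into feature weights
#'
#' \deqn{W_i = \nu_{p,i} / \sum_j \nu_{p,j}}; the weights are positive and
#' sum to 1.
#'
#' @param value_params Positive numeric vector.
#' @return Weight vector summing to 1.
#' @export
compute_weights <- function(value_params) {
  stopifnot(all(value_params > 0))
  value_params / sum(value_params)
}

#' Weighted Minkowski distance
#'
#' \deqn{d(a,b) = \left[\sum_i W_i |a_i - b_i|^\rho\right]^{1/\rho}},
#' \eqn{\rho \ge 1}. With uniform weights and \eqn{\rho = 2} this is the
#' Euclidean distance scaled by \eqn{1/\sqrt{t}}, so neighbour rankings
#' coincide with the conventional Euclidean rule.
#'
#' @param a,b Numeric vectors of equal length.
#' @param W Non-negative weight vector.
#' @param rho Order, >= 1.
#' @return Non-negative scalar.
#' @export
wminkowski_distance <- function(a, b, W, rho = 2) {
  if (length(a) != length(b) || length(a) != length(W)) stop("length mismatch")
  if (rho < 1) stop("rho must be >= 1")
  (sum(W * abs(a - b)^rho))^(1 / rho)
}

#' Fit the improved weighted-Minkowski KNN
#'
#' Stores the training instances, computes value parameters by
#' leave-one-feature-out conventional-KNN accuracy and normalizes them
#' into feature weights.
#'
#' @param X Training matrix.
#' @param y Training labels.
#' @param k Neighbourhood size for prediction (default 5).
#' @param rho Minkowski order (default 2).
#' @param scope `"neighbors"` averages class distances over the k nearest
#'   neighbours (default); `"all"` averages over every training point of
#'   each class.
#' @param k_values,folds,seed Passed to [compute_value_params()].
#' @return Object of class `iknn`.
#' @export
fit_iknn <- function(X, y, k = 5L, rho = 2, scope = c("neighbors", "all"),
                     k_values = c(3L, 5L, 7L), folds = 3L, seed = 1L) {
  scope <- match.arg(scope)
  X <- as.matrix(X); y <- factor(y)
  vp <- compute_value_params(X, y, k_values, folds, seed)
  structure(list(train_matrix = X, train_labels = y,
                 feature_weights = compute_weights(vp$value_params),
                 value_params = vp$value_params,
                 baseline_accuracy = vp$acc_e,
                 ablation_accuracies = vp$acc_0,
                 minkowski_order = rho, k = as.integer(k), scope = scope),
            class = "iknn")
}

#' Predict with a fitted improved KNN
#'
#' For each query: weighted-Minkowski distances to all training points;
#' among the k nearest, average the distances per represented class and
#' predict the class with the smallest average (ties broken by larger
#' neighbour count, then lowest class index). `scope = "all"` averages
#' over all training points per class instead.
#'
#' @param object A fitted `iknn`.
#' @param newdata Query matrix.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.iknn <- function(object, newdata, ...) {
  Q <- as.matrix(newdata)
  tr <- object$train_matrix
  k <- min(object$k, nrow(tr))
  if (k < object$k) warning("k clamped to the number of training points")
  W <- object$feature_weights; rho <- object$minkowski_order
  y <- object$train_labels
  lv <- levels(y)
  D <- wminkowski_cross(Q, tr, W, rho)
  preds <- character(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    if (object$scope == "all") {
      avg <- vapply(lv, function(cl) mean(D[i, y == cl]), numeric(1))
      cnt <- as.numeric(table(y))
    } else {
      nb <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
      cls <- y[nb]
      present <- lv[lv %in% as.character(cls)]
      avg <- vapply(present, function(cl) mean(D[i, nb[cls == cl]]), numeric(1))
      cnt <- vapply(present, function(cl) sum(cls == cl), numeric(1))
      lvp <- present
      ord <- order(avg, -cnt, match(lvp, lv))
      preds[i] <- lvp[ord[1]]
      next
    }
    ord <- order(avg, -cnt, seq_along(lv))
    preds[i] <- lv[ord[1]]
  }
  factor(preds, levels = lv)
}

# Cross weighted-Minkowski distances between rows of Q and rows of Tr.
wminkowski_cross <- function(Q, Tr, W, rho) {
  if (rho == 2) {
    # weighted squared Euclidean via the expansion trick
    Qw <- sweep(Q, 2, W, "*")
    d2 <- matrix(rowSums(sweep(Q^2, 2, W, "*")), nrow(Q), nrow(Tr)) +
      matrix(rowSums(sweep(Tr^2, 2, W, "*")), nrow(Q), nrow(Tr), byrow = TRUE) -
      2 * Qw %*% t(Tr)
    sqrt(pmax(d2, 0))
  } else {
    D <- matrix(0, nrow(Q), nrow(Tr))
    for (i in seq_len(nrow(Q))) {
      dif <- abs(sweep(Tr, 2, Q[i, ], "-"))^rho
      D[i, ] <- (dif %*% W)^(1 / rho)
    }
    D
  }
}
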