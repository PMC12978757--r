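# The ensemble classifier: each block draws a weighted random subspace of
# the fused feature set, builds a rotation-forest-style block-diagonal PCA
# rotation on a 75% subsample, blends the subspace with its rotated image
# (mixed-space enhancement), and trains one base learner; blocks are
# combined by majority vote.

#' Ensemble configuration
#'
#' @param n_blocks Number of blocks (default 3; a warning is issued for an
#'   even count on binary tasks since votes can tie).
#' @param learner_kinds Base learner kinds cycled across blocks.
#' @param subspace_ratio Fraction \eqn{\gamma} of the fused features drawn
#'   into each block's subspace.
#' @param overlap_coeff Overlap bonus \eqn{\lambda}: columns of the primary
#'   draw that also appear in the secondary draw get their weight scaled by
#'   \eqn{1+\lambda}.
#' @param alpha_mse Mixing coefficient of the mixed-space enhancement; 1
#'   disables the rotated component.
#' @param bootstrap_fraction Row fraction used for each per-group PCA
#'   (default 0.75).
#' @param bootstrap_replace Sample rows with replacement (default FALSE,
#'   the rotation-forest convention).
#' @param group_size_choices Candidate per-group feature counts for the
#'   multi-scale rotation (one size drawn per block).
#' @param weight_range Range of the uniform per-column weights.
#' @param mse_rotation `"pca"` uses the block's rotation-forest matrix in
#'   the enhancement; `"random"` uses a QR-orthogonalized Gaussian matrix.
#' @param learner_params Named list of per-kind parameter lists.
#' @param seed Master seed; all block-level randomness derives from it.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_blocks = 3L,
                            learner_kinds = c("random_forest", "svm", "iknn"),
                            subspace_ratio = 0.5, overlap_coeff = 0.3,
                            alpha_mse = 0.5, bootstrap_fraction = 0.75,
                            bootstrap_replace = FALSE,
                            group_size_choices = c(2L, 3L, 4L),
                            weight_range = c(0.5, 1.5),
                            mse_rotation = c("pca", "random"),
                            learner_params = list(), seed = 1L) {
  mse_rotation <- match.arg(mse_rotation)
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (subspace_ratio <= 0 || subspace_ratio > 1) {
    stop("subspace_ratio must be in (0, 1]")
  }
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    stop("bootstrap_fraction must be in (0, 1]")
  }
  if (alpha_mse < 0 || alpha_mse > 1) stop("alpha_mse must be in [0, 1]")
  structure(list(n_blocks = as.integer(n_blocks),
                 learner_kinds = learner_kinds,
                 subspace_ratio = subspace_ratio,
                 overlap_coeff = overlap_coeff, alpha_mse = alpha_mse,
                 bootstrap_fraction = bootstrap_fraction,
                 bootstrap_replace = bootstrap_replace,
                 group_size_choices = as.integer(group_size_choices),
                 weight_range = weight_range, mse_rotation = mse_rotation,
                 learner_params = learner_params, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Draw one block's weighted feature subspace
#'
#' Draws `M = max(2, round(subspace_ratio * |fused|))` primary feature
#' indices and an independent secondary draw of the same size from the
#' fused set, assigns each primary column a uniform weight from
#' `weight_range`, and scales the weight by `1 + overlap_coeff` where the
#' column also appears in the secondary draw. Indices are reported sorted.
#'
#' @param fused A `fused_features` object (or list with `indices`).
#' @param config An [ensemble_config].
#' @param block_id Integer block tag.
#' @param rng_seed Integer seed; the draw is deterministic given it.
#' @return Object of class `subspace_spec` with `primary_indices`,
#'   `secondary_indices`, `weight_vector`, `column_multipliers`,
#'   `overlap_coeff`, `block_id`.
#' @export
draw_subspace <- function(fused, config, block_id = 1L, rng_seed = 1L) {
  pool <- fused$indices
  if (length(pool) < 2) stop("fused feature set must have >= 2 features")
  M <- max(2L, round(config$subspace_ratio * length(pool)))
  if (M > length(pool)) stop("subspace size exceeds the fused feature count")
  rng <- local_rng(rng_seed)
  primary <- sort(rng$sample(pool, M))
  secondary <- sort(rng$sample(pool, M))
  w <- rng$runif(M, config$weight_range[1], config$weight_range[2])
  mult <- w * (1 + config$overlap_coeff * (primary %in% secondary))
  structure(list(block_id = as.integer(block_id), primary_indices = primary,
                 secondary_indices = secondary, weight_vector = w,
                 overlap_coeff = config$overlap_coeff,
                 column_multipliers = mult),
            class = "subspace_spec")
}

#' Materialize a subspace: column selection plus per-column weighting
#'
#' @param X Numeric matrix whose columns are indexed by the original
#'   feature indices used in the spec.
#' @param spec A `subspace_spec`.
#' @return Matrix `n x M`: the primary columns of `X` scaled by the
#'   column multipliers.
#' @export
apply_subspace <- function(X, spec) {
  X <- as.matrix(X)
  if (max(spec$primary_indices) > ncol(X)) stop("feature index out of range")
  sweep(X[, spec$primary_indices, drop = FALSE], 2,
        spec$column_multipliers, "*")
}

#' Build a rotation-forest-style block-diagonal rotation
#'
#' Draws a group size from `group_size_choices`, randomly partitions the M
#' subspace columns into disjoint groups of that size (last group may be
#' smaller), fits a full-component PCA per group on a
#' `bootstrap_fraction` row subsample (column-centered), and assembles the
#' per-group loading matrices into an M x M orthogonal matrix aligned with
#' the original column order. Groups with zero variance in the sampled
#' rows receive identity loadings.
#'
#' @param S Subspace matrix (>= 4 rows).
#' @param y Labels (unused by the PCA itself; kept for interface symmetry).
#' @param config An [ensemble_config].
#' @param rng_seed Integer seed.
#' @return Object of class `rotation_model` with `rotation` (M x M),
#'   `groups`, `group_size`, `degenerate_groups`.
#' @export
build_rotation <- function(S, y = NULL, config = ensemble_config(),
                           rng_seed = 1L) {
  S <- as.matrix(S)
  if (nrow(S) < 4) stop("need at least 4 rows to build a rotation")
  M <- ncol(S)
  rng <- local_rng(rng_seed)
  g <- if (length(config$group_size_choices) == 1) config$group_size_choices
       else rng$sample(config$group_size_choices, 1)
  g <- min(g, M)
  perm <- rng$sample(seq_len(M))
  groups <- split(perm, ceiling(seq_along(perm) / g))
  n_sub <- ceiling(config$bootstrap_fraction * nrow(S))
  R <- matrix(0, M, M)
  degenerate <- integer(0)
  for (j in seq_along(groups)) {
    idx <- groups[[j]]
    rows <- rng$sample(seq_len(nrow(S)), n_sub,
                       replace = config$bootstrap_replace)
    sub <- S[rows, idx, drop = FALSE]
    if (all(apply(sub, 2, stats::var) < .Machine$double.eps)) {
      R[idx, idx] <- diag(length(idx))
      degenerate <- c(degenerate, j)
      next
    }
    pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
    L <- pc$rotation
    if (ncol(L) < length(idx)) L <- complete_orthonormal(L, length(idx))
    R[idx, idx] <- L
  }
  structure(list(n_features = M, groups = groups, group_size = g,
                 n_subsample = n_sub, rotation = R,
                 degenerate_groups = degenerate),
            class = "rotation_model")
}

# Extend a column-orthonormal matrix to a full orthonormal basis.
complete_orthonormal <- function(L, p) {
  q <- qr.Q(qr(cbind(L, diag(p))))
  q[, seq_len(p), drop = FALSE]
}

#' Mixed-space enhancement
#'
#' Convex blend of a subspace with its rotated image:
#' \deqn{\varepsilon = \alpha S + (1-\alpha) S R.}
#'
#' @param S Subspace matrix.
#' @param model A `rotation_model` (or any list with an orthogonal
#'   `rotation` of matching size).
#' @param alpha_mse Mixing coefficient in [0, 1]; 1 returns `S` unchanged.
#' @return Matrix of the same shape as `S`.
#' @export
mixed_enhance <- function(S, model, alpha_mse = 0.5) {
  S <- as.matrix(S)
  if (ncol(S) != model$n_features) stop("shape mismatch")
  if (alpha_mse == 1) return(S)
  alpha_mse * S + (1 - alpha_mse) * S %*% model$rotation
}

#' Fit the subspace-rotation ensemble
#'
#' For each block: draw a weighted subspace of the fused features, build
#' the rotation, mix, and fit that block's base learner on the enhanced
#' matrix. Per-block seeds are derived from the master seed, so the whole
#' fit is reproducible.
#'
#' @param X Training matrix in ORIGINAL feature indexing (the fused object
#'   carries the indices into it).
#' @param y Training labels.
#' @param fused A `fused_features` object ([fuse_features()]), or an
#'   integer vector of feature indices.
#' @param config An [ensemble_config].
#' @return Object of class `subspace_ensemble` with one entry per block
#'   (`spec`, `rotation`, `learner`, `learner_seed`) plus `classes` and
#'   the config snapshot.
#' @export
fit_ensemble <- function(X, y, fused, config = ensemble_config()) {
  X <- as.matrix(X); y <- factor(y)
  if (nlevels(y) < 2) stop("need >= 2 classes")
  if (is.numeric(fused)) fused <- list(indices = sort(unique(as.integer(fused))))
  if (nlevels(y) == 2 && config$n_blocks %% 2 == 0) {
    warning("even n_blocks on a binary task: majority votes can tie")
  }
  blocks <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    bseed <- derive_seed(config$seed, paste0("block", i))
    spec <- draw_subspace(fused, config, block_id = i,
                          rng_seed = derive_seed(bseed, "subspace"))
    S <- apply_subspace(X, spec)
    rot <- if (config$alpha_mse == 1) NULL
           else if (config$mse_rotation == "random")
             random_rotation(ncol(S), derive_seed(bseed, "rot"))
           else build_rotation(S, y, config, derive_seed(bseed, "rot"))
    eps <- if (is.null(rot)) S else mixed_enhance(S, rot, config$alpha_mse)
    kind <- config$learner_kinds[(i - 1L) %% length(config$learner_kinds) + 1L]
    lseed <- derive_seed(bseed, "learner")
    learner <- tryCatch(
      fit_learner(kind, eps, y, seed = lseed,
                  params = config$learner_params[[kind]] %||% list()),
      error = function(e) stop("block ", i, " (", kind, ") failed to fit: ",
                               conditionMessage(e)))
    blocks[[i]] <- list(spec = spec, rotation = rot, learner = learner,
                        learner_seed = lseed, kind = kind)
  }
  structure(list(blocks = blocks, classes = levels(y), config = config),
            class = "subspace_ensemble")
}

# QR-orthogonalized Gaussian rotation, exposed through mse_rotation="random".
random_rotation <- function(M, seed) {
  rng <- local_rng(seed)
  Q <- qr.Q(qr(matrix(rng$rnorm(M * M), M, M)))
  structure(list(n_features = M, rotation = Q, groups = list(seq_len(M)),
                 group_size = M, degenerate_groups = integer(0)),
            class = "rotation_model")
}

#' Predict with the subspace-rotation ensemble
#'
#' Each block transforms the query matrix through its own subspace,
#' rotation and mix, and predicts; the final label is the plurality vote.
#' Ties are broken by the summed per-class scores of the blocks that
#' expose scores, then by the lowest class index.
#'
#' @param object A fitted `subspace_ensemble`.
#' @param newdata Query matrix in original feature indexing.
#' @param ... Unused.
#' @return List with `labels` (factor) and `vote_fractions`
#'   (n x classes matrix of block vote shares; for binary tasks the
#'   positive-class column is the natural ROC score).
#' @export
predict.subspace_ensemble <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  classes <- object$classes
  nb <- length(object$blocks)
  votes <- matrix(0L, nrow(X), length(classes),
                  dimnames = list(NULL, classes))
  scores <- matrix(0, nrow(X), length(classes),
                   dimnames = list(NULL, classes))
  have_scores <- FALSE
  for (blk in object$blocks) {
    S <- apply_subspace(X, blk$spec)
    eps <- if (is.null(blk$rotation)) S
           else mixed_enhance(S, blk$rotation, object$config$alpha_mse)
    p <- predict(blk$learner, eps)
    votes[cbind(seq_len(nrow(X)), as.integer(p))] <-
      votes[cbind(seq_len(nrow(X)), as.integer(p))] + 1L
    sc <- learner_scores(blk$learner, eps)
    if (!is.null(sc)) {
      scores <- scores + sc
      have_scores <- TRUE
    }
  }
  plurality_vote(votes, classes, if (have_scores) scores else NULL, nb)
}

# Plurality vote with score-sum then lowest-class-index tie-breaks.
plurality_vote <- function(votes, classes, scores = NULL, n_blocks) {
  lab <- integer(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1 && !is.null(scores)) {
      top <- top[order(-scores[i, top], top)]
    }
    lab[i] <- top[1]
  }
  list(labels = factor(classes[lab], levels = classes),
       vote_fractions = votes / n_blocks)
}
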