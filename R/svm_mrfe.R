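# Per-partition feature selection: a recursive-elimination wrapper whose
# ranking criterion blends the squared weights of a linear maximum-margin
# classifier with a modified Fisher separability score.

#' Configuration for the hybrid recursive feature elimination
#'
#' @param alpha_rank Blend weight in [0, 1] between the margin term
#'   (squared SVM weights) and the modified Fisher score; 0.5 by default,
#'   1 recovers conventional SVM-RFE ranking.
#' @param n_select Target number of features to keep per partition.
#' @param drop_fraction Fraction of remaining features dropped per
#'   iteration (ceiling, at least 1).
#' @param svm_regularization Cost parameter of the linear SVM.
#' @param seed Integer seed (the linear SVM fit is deterministic; the seed
#'   is recorded for provenance).
#' @return Object of class `mrfe_config`.
#' @export
mrfe_config <- function(alpha_rank = 0.5, n_select = 50L,
                        drop_fraction = 0.10, svm_regularization = 1.0,
                        seed = 1L) {
  if (alpha_rank < 0 || alpha_rank > 1) stop("alpha_rank must be in [0, 1]")
  if (n_select < 2) stop("n_select must be >= 2")
  if (drop_fraction <= 0 || drop_fraction >= 1) stop("drop_fraction must be in (0, 1)")
  structure(list(alpha_rank = alpha_rank, n_select = as.integer(n_select),
                 drop_fraction = drop_fraction,
                 svm_regularization = svm_regularization,
                 seed = as.integer(seed)), class = "mrfe_config")
}

# Class-indexed summaries shared by both Fisher variants.
class_summaries <- function(X, y) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("at least 2 classes required")
  counts <- as.integer(table(y))
  if (any(counts < 2)) stop("at least 2 samples per class required")
  means <- matrix(vapply(levels(y),
                         function(cl) colMeans(X[y == cl, , drop = FALSE]),
                         numeric(ncol(X))),
                  nrow = nlevels(y), ncol = ncol(X), byrow = TRUE)
  # population (1/n_d) within-class variances
  vars <- matrix(vapply(levels(y), function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    colMeans(Xi^2) - colMeans(Xi)^2
  }, numeric(ncol(X))), nrow = nlevels(y), ncol = ncol(X), byrow = TRUE)
  vars[vars < 0] <- 0
  list(levels = levels(y), counts = counts, class_means = means,
       class_vars = vars)
}

#' Fisher score per feature
#'
#' Classical between/within separability ratio with class sample counts as
#' weights:
#' \deqn{s(f_a) = \frac{\sum_d n_d (\mu_{da} - \mu_a)^2}
#'                     {\sum_d n_d \sigma_{da}^2}}
#' where \eqn{\mu_{da}, \sigma_{da}^2} are class-conditional mean and
#' (population) variance and \eqn{\mu_a} the global mean. A zero
#' denominator yields score 0 (such features are flagged as perfectly
#' separating when their numerator is positive).
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels (>= 2 classes, >= 2 samples per class).
#' @return List of class `fisher_scores` with `s` (scores), the class
#'   summaries, and `perfect` (logical: zero within-class variance but
#'   positive between-class spread).
#' @export
fisher_score <- function(X, y) {
  X <- as.matrix(X)
  cs <- class_summaries(X, y)
  mu_a <- colMeans(X)
  num <- colSums(cs$counts * sweep(cs$class_means, 2, mu_a, "-")^2)
  den <- colSums(cs$counts * cs$class_vars)
  s <- ifelse(den > 0, num / den, 0)
  structure(list(s = unname(s), class_means = cs$class_means,
                 class_sizes = cs$counts, class_vars = cs$class_vars,
                 global_means = mu_a, n_classes = length(cs$levels),
                 perfect = unname(den == 0 & num > 0)),
            class = "fisher_scores")
}

#' Modified Fisher score per feature
#'
#' A separability score that replaces the global mean by a studentized
#' version and rescales by the standard error of the feature mean:
#' \deqn{SE(\bar f_a) = sd(f_a)/\sqrt{n}, \quad
#'       \phi(\bar f_a) = (\bar f_a - \mu_0)/SE(\bar f_a),}
#' \deqn{Ms(f_a) = \frac{\sum_d n_d(\mu_{da} - \phi(\bar f_a))^2}
#'                      {\sum_d n_d \, SE(\bar f_a)}}
#' with \eqn{\mu_0} the grand mean over every cell of the matrix. Features
#' with SE = 0 (constant columns) score 0. The `classic_denominator`
#' variant substitutes the classical within-class-variance denominator for
#' sensitivity analyses.
#'
#' @param X Numeric matrix (samples x features), n >= 3.
#' @param y Class labels.
#' @param variant `"literal"` (default) or `"classic-denominator"`.
#' @return List of class `fisher_scores` with `ms` plus the intermediate
#'   quantities (`standard_errors`, `studentized_means`, `grand_mean`).
#' @export
modified_fisher_score <- function(X, y, variant = c("literal", "classic-denominator")) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("n must be >= 3 for the standard error to be defined")
  cs <- class_summaries(X, y)
  n <- nrow(X)
  fbar <- colMeans(X)
  se <- apply(X, 2, stats::sd) / sqrt(n)
  mu0 <- mean(X)
  phi <- ifelse(se > 0, (fbar - mu0) / se, 0)
  num <- colSums(cs$counts * sweep(cs$class_means, 2, phi, "-")^2)
  den <- if (variant == "literal") sum(cs$counts) * se
         else colSums(cs$counts * cs$class_vars)
  ms <- ifelse(den > 0 & se > 0, num / den, 0)
  structure(list(ms = unname(ms), class_means = cs$class_means,
                 class_sizes = cs$counts, global_means = fbar,
                 standard_errors = unname(se), studentized_means = unname(phi),
                 grand_mean = mu0, n_classes = length(cs$levels),
                 variant = variant),
            class = "fisher_scores")
}

#' Hybrid margin + separability feature rank
#'
#' \deqn{R(f_i) = \alpha \frac{|w_i|^2}{\max |w|^2}
#'              + (1-\alpha)\frac{Ms(f_i)}{\max Ms}.}
#' A term whose maximum is 0 contributes 0.
#'
#' @param svm_weights_sq Squared linear-SVM weights per feature.
#' @param ms Modified Fisher scores per feature.
#' @param alpha_rank Blend weight in [0, 1].
#' @return Rank vector in [0, 1].
#' @export
hybrid_rank <- function(svm_weights_sq, ms, alpha_rank = 0.5) {
  if (length(svm_weights_sq) != length(ms)) stop("length mismatch")
  wt <- if (max(svm_weights_sq) > 0) svm_weights_sq / max(svm_weights_sq) else 0 * svm_weights_sq
  mt <- if (max(ms) > 0) ms / max(ms) else 0 * ms
  alpha_rank * wt + (1 - alpha_rank) * mt
}

# Squared primal weights of a linear SVM; one-vs-rest with per-feature sums
# for more than two classes (the ranking needs one weight per feature).
linear_svm_weights_sq <- function(X, y, cost = 1) {
  y <- factor(y)
  fit_one <- function(yy) {
    fit <- e1071::svm(X, yy, kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$SV, fit$coefs)
    as.numeric(w)^2
  }
  if (nlevels(y) == 2) {
    fit_one(y)
  } else {
    Reduce(`+`, lapply(levels(y), function(cl) {
      fit_one(factor(ifelse(y == cl, cl, "rest"), levels = c(cl, "rest")))
    }))
  }
}

#' Recursive feature elimination with the hybrid rank
#'
#' Iteratively fits a linear maximum-margin classifier on the remaining
#' features, ranks features by [hybrid_rank()], and drops the
#' lowest-ranked `ceil(drop_fraction * remaining)` features (never below
#' `n_select`; the final iteration drops exactly enough). Rank ties are
#' broken by dropping the higher original index first. Deterministic.
#'
#' @param X Numeric matrix (samples x features).
#' @param y Class labels.
#' @param config An [mrfe_config].
#' @param partition_id Integer tag recorded in the result.
#' @param feature_names Optional names aligned with the columns of `X`.
#' @return Object of class `selected_features`: `kept_indices` (sorted,
#'   original indexing), `elimination_trace` (list of dropped index sets
#'   per iteration), `partition_id`, `feature_names`.
#' @export
mrfe_select <- function(X, y, config = mrfe_config(), partition_id = 1L,
                        feature_names = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  d <- ncol(X)
  if (is.null(feature_names)) feature_names <- colnames(X)
  if (any(table(y) < 2) || nlevels(y) < 2) {
    stop("partition ", partition_id,
         ": need >= 2 classes with >= 2 samples each to fit the ranking classifier")
  }
  remaining <- seq_len(d)
  trace <- list()
  it <- 0L
  while (length(remaining) > config$n_select) {
    it <- it + 1L
    Xr <- X[, remaining, drop = FALSE]
    w2 <- linear_svm_weights_sq(Xr, y, config$svm_regularization)
    ms <- modified_fisher_score(Xr, y)$ms
    r <- hybrid_rank(w2, ms, config$alpha_rank)
    n_drop <- min(ceiling(config$drop_fraction * length(remaining)),
                  length(remaining) - config$n_select)
    # ascending rank; ties (within float noise from the margin fit)
    # resolved toward the higher ORIGINAL index
    ord <- order(round(r, 12), -remaining)
    drop_local <- ord[seq_len(n_drop)]
    trace[[it]] <- remaining[drop_local]
    remaining <- remaining[-drop_local]
  }
  structure(list(partition_id = as.integer(partition_id),
                 kept_indices = sort(remaining),
                 elimination_trace = trace,
                 feature_names = feature_names),
            class = "selected_features")
}

#' Fuse per-partition feature selections
#'
#' Deduplicated, sorted union of the original feature indices selected in
#' each partition, with a provenance map recording which partitions chose
#' each feature.
#'
#' @param per_partition List of `selected_features` objects.
#' @return Object of class `fused_features` with `indices` and
#'   `provenance` (named list index -> partition ids).
#' @export
fuse_features <- function(per_partition) {
  if (length(per_partition) == 0) stop("no partition results to fuse")
  all_idx <- sort(unique(unlist(lapply(per_partition, `[[`, "kept_indices"))))
  if (length(all_idx) == 0) stop("empty fused feature set")
  prov <- lapply(all_idx, function(i) {
    vapply(per_partition,
           function(s) if (i %in% s$kept_indices) s$partition_id else NA_integer_,
           integer(1))
  })
  prov <- lapply(prov, function(v) v[!is.na(v)])
  names(prov) <- as.character(all_idx)
  fn <- per_partition[[1]]$feature_names
  structure(list(indices = all_idx, provenance = prov,
                 feature_names = if (!is.null(fn)) fn[all_idx] else NULL),
            class = "fused_features")
}
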