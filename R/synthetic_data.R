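#' Specification for synthetic expression-like data
#'
#' Describes a draw of a wide numeric matrix mimicking the shape of small
#' expression benchmarks (tens to hundreds of samples, hundreds to thousands
#' of features): a handful of informative features carry a class-mean shift,
#' the rest are pure noise, and an optional low-dimensional latent blob
#' structure gives the samples cluster geometry independent of the class
#' labels.
#'
#' @param n_samples Number of samples.
#' @param n_features Number of features.
#' @param n_informative Number of class-informative features.
#' @param effect_size Between-class mean shift on informative features, in
#'   units of `noise_sd`.
#' @param n_classes Number of classes (default 2).
#' @param class_balance Class prior vector summing to 1; default balanced.
#' @param n_latent_clusters Latent blob count (0 or 1 disables the blob
#'   structure).
#' @param cluster_separation Distance between latent blob centers, in noise
#'   units.
#' @param noise_sd Noise standard deviation.
#' @param feature_correlation Equicorrelation among informative features,
#'   in [0, 1).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 200L, n_features = 500L,
                           n_informative = 30L, effect_size = 1.5,
                           n_classes = 2L, class_balance = NULL,
                           n_latent_clusters = 3L, cluster_separation = 6,
                           noise_sd = 1, feature_correlation = 0,
                           seed = 1L) {
  if (is.null(class_balance)) class_balance <- rep(1 / n_classes, n_classes)
  if (length(class_balance) != n_classes) stop("class_balance length != n_classes")
  if (abs(sum(class_balance) - 1) > 1e-8) stop("class_balance must sum to 1")
  if (any(class_balance <= 0)) stop("class_balance entries must be positive")
  if (n_informative > n_features) stop("n_informative > n_features")
  if (feature_correlation < 0 || feature_correlation >= 1) {
    stop("feature_correlation must be in [0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, n_classes = as.integer(n_classes),
                 class_balance = class_balance,
                 n_latent_clusters = as.integer(n_latent_clusters),
                 cluster_separation = cluster_separation,
                 noise_sd = noise_sd,
                 feature_correlation = feature_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic class counts: largest-remainder apportionment of n over priors.
balance_counts <- function(n, balance) {
  raw <- n * balance
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a labelled classification matrix with known informative features
#'
#' Informative features get a per-class mean offset of
#' `effect_size * noise_sd` between consecutive classes; the remaining
#' features are zero-mean noise. When `n_latent_clusters >= 2`, a latent
#' Gaussian blob structure (independent of the class labels) is embedded
#' across all features so the sample geometry has cluster shape for
#' partitioning methods to find.
#'
#' @param spec A [synthetic_spec].
#' @return List with `data` (a [data_matrix]), `informative` (integer
#'   indices of the planted features), and `latent_clusters` (integer blob
#'   assignment per sample).
#' @export
generate_classification <- function(spec) {
  rng <- local_rng(spec$seed)
  n <- spec$n_samples; d <- spec$n_features
  counts <- balance_counts(n, spec$class_balance)
  y <- rep(paste0("C", seq_len(spec$n_classes)), counts)
  y <- y[rng$sample(seq_len(n))]           # shuffle class order over rows
  informative <- sort(rng$sample(seq_len(d), spec$n_informative))

  X <- matrix(rng$rnorm(n * d, sd = spec$noise_sd), n, d)
  if (spec$feature_correlation > 0 && spec$n_informative > 1) {
    rho <- spec$feature_correlation
    shared <- rng$rnorm(n, sd = spec$noise_sd)
    X[, informative] <- sqrt(rho) * shared +
      sqrt(1 - rho) * X[, informative]
  }
  shift <- spec$effect_size * spec$noise_sd
  cls <- as.integer(factor(y, levels = paste0("C", seq_len(spec$n_classes))))
  X[, informative] <- X[, informative] + (cls - 1) * shift

  latent <- rep(1L, n)
  if (spec$n_latent_clusters >= 2L) {
    emb <- latent_blobs(rng, n, d, spec$n_latent_clusters,
                        spec$cluster_separation, spec$noise_sd)
    X <- X + emb$embedded
    latent <- emb$assignment
  }
  list(data = data_matrix(X, y), informative = informative,
       latent_clusters = latent)
}

# Blobs in a q-dim latent space pushed through a random linear map whose
# columns have unit norm, so cluster_separation stays in noise-sd units.
latent_blobs <- function(rng, n, d, k, separation, noise_sd, q = 5L) {
  assignment <- sort(rep_len(seq_len(k), n))
  assignment <- assignment[rng$sample(seq_len(n))]
  centers <- matrix(rng$rnorm(k * q), k, q)
  centers <- centers / sqrt(rowSums(centers^2)) * separation * noise_sd / 2
  Z <- centers[assignment, , drop = FALSE] +
    matrix(rng$rnorm(n * q, sd = noise_sd / 2), n, q)
  A <- matrix(rng$rnorm(q * d), q, d)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  list(embedded = Z %*% A, assignment = assignment)
}

#' Generate pure cluster-structured data with known blob labels
#'
#' Gaussian blobs in a low-dimensional latent space, embedded into
#' `n_features` dimensions through a random linear map plus isotropic noise.
#' Class labels returned with the data are the blob labels themselves, so
#' clustering stages can be scored against exact ground truth.
#'
#' @param spec A [synthetic_spec]; `n_latent_clusters` must be >= 2.
#' @return List with `data` (a [data_matrix] labelled by blob) and
#'   `cluster_labels` (integer vector).
#' @export
generate_clustered <- function(spec) {
  if (spec$n_latent_clusters < 2L) stop("n_latent_clusters must be >= 2")
  rng <- local_rng(spec$seed)
  n <- spec$n_samples; d <- spec$n_features
  emb <- latent_blobs(rng, n, d, spec$n_latent_clusters,
                      spec$cluster_separation, spec$noise_sd)
  X <- emb$embedded + matrix(rng$rnorm(n * d, sd = spec$noise_sd), n, d)
  list(data = data_matrix(X, paste0("K", emb$assignment)),
       cluster_labels = emb$assignment)
}

#' Cluster purity against ground truth
#'
#' Fraction of samples whose predicted cluster's majority true label matches
#' their own true label.
#'
#' @param assignment Predicted cluster ids.
#' @param truth True cluster ids.
#' @return Purity in [0, 1].
#' @export
cluster_purity <- function(assignment, truth) {
  stopifnot(length(assignment) == length(truth))
  tab <- table(assignment, truth)
  sum(apply(tab, 1, max)) / length(truth)
}
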