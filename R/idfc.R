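# Deep fuzzy clustering with a hybrid Gaussian/exponential kernel, used to
# partition the training samples before per-partition feature selection.
# The model couples an autoencoder reconstruction loss with (i) a
# KL-divergence self-training loss between the fuzzy memberships and a
# sharpened target distribution and (ii) an affinity regularizer pulling
# together latent codes that share a pseudo-label, with the affinity taken
# from the hybrid kernel.

#' Hybrid kernel specification
#'
#' @param alpha_kernel Mixing weight in [0, 1]: 1 gives the pure Gaussian
#'   kernel, 0 the pure exponential kernel.
#' @param sigma Positive bandwidth, or the string `"median"` to resolve it
#'   to the median pairwise latent distance after pretraining.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(alpha_kernel = 0.5, sigma = "median") {
  if (alpha_kernel < 0 || alpha_kernel > 1) stop("alpha_kernel must be in [0, 1]")
  if (!identical(sigma, "median") && (!is.numeric(sigma) || sigma <= 0)) {
    stop("sigma must be positive or \"median\"")
  }
  structure(list(alpha_kernel = alpha_kernel, sigma = sigma),
            class = "kernel_spec")
}

#' Configuration for the deep fuzzy clustering partitioner
#'
#' Defaults follow the package's reference setup: 3 clusters, a
#' 64-unit hidden layer with a 10-dimensional latent code, fuzzifier 2,
#' and plain full-batch gradient descent.
#'
#' @param n_clusters Number of clusters C (>= 2).
#' @param batch_size Batch size; `NULL` means `min(256, n)`.
#' @param latent_dim Latent code dimension.
#' @param hidden_dim Hidden layer width.
#' @param fuzzifier Fuzzifier exponent (> 1).
#' @param balance Between-cluster balance weight \eqn{\mu} (>= 0).
#' @param eta1 Weight of the KL self-training loss.
#' @param eta2 Weight of the affinity regularizer.
#' @param delta Affinity sharpening exponent (> 0).
#' @param kernel A [kernel_spec].
#' @param weight_decay Autoencoder L2 penalty \eqn{\gamma}.
#' @param epochs Joint-training epochs.
#' @param pretrain_epochs Autoencoder-only pretraining epochs.
#' @param learning_rate Gradient-descent step size for the joint phase.
#' @param pretrain_learning_rate Step size for the reconstruction-only
#'   pretraining phase (larger: that phase optimizes a single smooth
#'   objective, and the latent geometry the clustering sees is only as
#'   good as the pretrained code).
#' @param seed Integer seed.
#' @return Object of class `idfc_config`.
#' @export
idfc_config <- function(n_clusters = 3L, batch_size = NULL, latent_dim = 10L,
                        hidden_dim = 64L, fuzzifier = 2, balance = 0.1,
                        eta1 = 0.1, eta2 = 0.01, delta = 1,
                        kernel = kernel_spec(), weight_decay = 1e-4,
                        epochs = 100L, pretrain_epochs = 200L,
                        learning_rate = 1e-3,
                        pretrain_learning_rate = 1e-2, seed = 1L) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  if (delta <= 0) stop("delta must be > 0")
  if (balance < 0 || eta1 < 0 || eta2 < 0 || weight_decay < 0) {
    stop("balance, eta1, eta2 and weight_decay must be >= 0")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 batch_size = batch_size, latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim), fuzzifier = fuzzifier,
                 balance = balance, eta1 = eta1, eta2 = eta2, delta = delta,
                 kernel = kernel, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 learning_rate = learning_rate,
                 pretrain_learning_rate = pretrain_learning_rate,
                 seed = as.integer(seed)),
            class = "idfc_config")
}

#' Hybrid Gaussian/exponential kernel
#'
#' \deqn{\omega(a,b) = \alpha e^{-\|a-b\|^2 / 2\sigma^2}
#'                   + (1-\alpha) e^{-\|a-b\| / \sigma}.}
#' Both components are positive semi-definite kernels, so the convex
#' combination is too; the value lies in (0, 1] and equals 1 iff a = b.
#'
#' @param a,b Numeric vectors of equal length.
#' @param spec A [kernel_spec] with a resolved numeric sigma.
#' @return Scalar kernel value.
#' @export
hybrid_kernel <- function(a, b, spec) {
  if (length(a) != length(b)) stop("length mismatch")
  if (!is.numeric(spec$sigma) || spec$sigma <= 0) stop("sigma must be resolved and > 0")
  r2 <- sum((a - b)^2)
  spec$alpha_kernel * exp(-r2 / (2 * spec$sigma^2)) +
    (1 - spec$alpha_kernel) * exp(-sqrt(r2) / spec$sigma)
}

# Kernel Gram matrix over the rows of Z.
hybrid_kernel_matrix <- function(Z, spec) {
  D2 <- as.matrix(stats::dist(Z))^2
  spec$alpha_kernel * exp(-D2 / (2 * spec$sigma^2)) +
    (1 - spec$alpha_kernel) * exp(-sqrt(D2) / spec$sigma)
}

# Resolve a "median" sigma sentinel to the median pairwise distance.
resolve_sigma <- function(spec, Z) {
  if (identical(spec$sigma, "median")) {
    d <- as.vector(stats::dist(Z))
    s <- stats::median(d[d > 0])
    if (!is.finite(s) || s <= 0) s <- 1
    spec$sigma <- s
  }
  spec
}

#' Fuzzy membership matrix
#'
#' Membership of each latent point to each cluster, using the fuzzified
#' inverse-distance rule with a between-cluster balance term:
#' \deqn{D_{x,y} = \|z_x-\beta_y\|^2
#'   - \mu \frac{\sum_v \|\beta_v-\bar\beta\|^2}{\|\beta_y-\bar\beta\|^2}},
#' \deqn{\Upsilon_{x,y} = D_{x,y}^{-1/(fuz-1)} / \sum_v D_{x,v}^{-1/(fuz-1)}.}
#' D is floored at a small positive constant so the negative power is
#' defined; a point lying exactly on a center receives membership 1 for
#' that cluster (limit convention, lowest cluster index on ties).
#'
#' @param latent Numeric matrix b x latent_dim.
#' @param centers Numeric matrix C x latent_dim.
#' @param fuzzifier Fuzzifier (> 1).
#' @param balance Balance weight \eqn{\mu} (>= 0).
#' @return b x C membership matrix; rows sum to 1, entries in [0, 1].
#' @export
compute_membership <- function(latent, centers, fuzzifier = 2, balance = 0) {
  latent <- as.matrix(latent); centers <- as.matrix(centers)
  if (fuzzifier <= 1) stop("fuzzifier must be > 1")
  C <- nrow(centers)
  d2 <- cluster_dist2(latent, centers)
  if (C > 1 && max(stats::dist(centers)) == 0) stop("all centers identical")
  D <- membership_D(d2, centers, balance)
  on_center <- d2 <= .Machine$double.eps * 100
  U <- D^(-1 / (fuzzifier - 1))
  U <- U / rowSums(U)
  hit <- which(rowSums(on_center) > 0)
  for (x in hit) {                       # limit convention: one-hot
    U[x, ] <- 0
    U[x, which(on_center[x, ])[1]] <- 1
  }
  U[U < 0] <- 0; U[U > 1] <- 1
  unname(U / rowSums(U))
}

# Penalized squared distances D_{x,y} = ||z_x - beta_y||^2 - pen_y with the
# numerical guard shared by the membership formula and its gradient: the
# between-cluster penalty can exceed the raw distances (especially early in
# training, when the latent space is compact), so each cell is floored at
# half its unpenalized distance. The floor bounds how much the penalty can
# boost any one cluster's inverse-distance weight (factor <= 2 at fuz = 2),
# which keeps memberships graded and the self-training stable; it is
# inactive wherever the penalty is small relative to the distances.
membership_D <- function(d2, centers, balance, pen = NULL) {
  D <- d2
  if (is.null(pen) && balance > 0) pen <- balance_penalty(centers, balance)
  if (!is.null(pen) && any(pen != 0)) {
    D <- pmax(sweep(D, 2, pen, "-"), 0.5 * d2)
  }
  pmax(D, 1e-12)
}

balance_penalty <- function(centers, balance) {
  if (balance <= 0) return(rep(0, nrow(centers)))
  bbar <- colMeans(centers)
  gy <- rowSums(sweep(centers, 2, bbar, "-")^2)
  balance * sum(gy) / pmax(gy, 1e-12)
}

# Squared Euclidean distances from each row of Z to each row of centers.
cluster_dist2 <- function(Z, centers) {
  zz <- rowSums(Z^2)
  cc <- rowSums(centers^2)
  d2 <- outer(zz, cc, "+") - 2 * Z %*% t(centers)
  pmax(d2, 0)
}

#' Self-training target distribution
#'
#' Squares the memberships, normalizes by per-cluster totals (so large
#' clusters are not favoured), then renormalizes each row to sum to 1:
#' \deqn{T_{x,y} \propto \Upsilon_{x,y}^2 / \sum_x \Upsilon_{x,y}.}
#'
#' @param membership b x C membership matrix with rows summing to 1.
#' @return b x C target matrix with rows summing to 1.
#' @export
compute_target <- function(membership) {
  U <- as.matrix(membership)
  col_tot <- colSums(U)
  W <- sweep(U^2, 2, ifelse(col_tot > 0, col_tot, Inf), "/")
  rs <- rowSums(W)
  if (any(rs == 0)) stop("degenerate membership: all cluster totals zero for some row")
  W / rs
}

#' KL divergence between target and membership
#'
#' \deqn{KL(T\|\Upsilon) = \sum_{x,y} T_{x,y}\log(T_{x,y}/\Upsilon_{x,y})}
#' with the 0 log 0 = 0 convention. Membership entries that are 0 where the
#' target is positive are clamped at 1e-12 with a warning.
#'
#' @param target,membership Matrices of identical shape, rows summing to 1.
#' @return Non-negative scalar; 0 iff the matrices are equal.
#' @export
kl_loss <- function(target, membership) {
  T_ <- as.matrix(target); U <- as.matrix(membership)
  if (!identical(dim(T_), dim(U))) stop("shape mismatch")
  bad <- U < 1e-12 & T_ > 0
  if (any(bad)) {
    if (any(bad & T_ > 1e-12)) {
      warning("membership entries clamped at 1e-12 in KL computation")
    }
    U[bad] <- 1e-12
  }
  pos <- T_ > 0
  sum(T_[pos] * log(T_[pos] / U[pos]))
}

#' Pairwise affinity matrix from pseudo-labels and the hybrid kernel
#'
#' \deqn{Aff_{x,u} = \omega(z_x, z_u)^\delta} when the pseudo-labels of x
#' and u agree, 0 otherwise. Symmetric with unit diagonal.
#'
#' @param latent Latent code matrix.
#' @param pseudo_labels Integer vector of per-point cluster pseudo-labels.
#' @param spec A [kernel_spec] with resolved sigma.
#' @param delta Sharpening exponent (> 0).
#' @return b x b affinity matrix.
#' @export
compute_affinity <- function(latent, pseudo_labels, spec, delta = 1) {
  if (delta <= 0) stop("delta must be > 0")
  K <- hybrid_kernel_matrix(as.matrix(latent), spec)
  same <- outer(pseudo_labels, pseudo_labels, "==")
  A <- unname((K^delta) * same)
  diag(A) <- 1
  A
}

#' Combined deep fuzzy clustering loss
#'
#' Reconstruction loss (mean squared error plus weight decay) plus
#' `eta1` times the KL self-training loss plus `eta2` times the
#' affinity-weighted latent spread
#' \eqn{\sum_{x,u} \|z_x - z_u\|^2 Aff_{x,u}}.
#'
#' @param model An `autoencoder`.
#' @param X Input batch (rows = samples), already normalized.
#' @param state List with `latent`, `membership`, `target`, `affinity`
#'   (as produced during training).
#' @param config An [idfc_config].
#' @return Scalar loss.
#' @export
total_loss <- function(model, X, state, config) {
  recon <- reconstruction_loss(model, X, config$weight_decay)
  kl <- kl_loss(state$target, state$membership)
  D2 <- as.matrix(stats::dist(state$latent))^2
  aff_term <- sum(D2 * state$affinity)
  recon + config$eta1 * kl + config$eta2 * aff_term
}

# Gradient of eta1*KL + eta2*affinity term with respect to the latent codes,
# holding target, pseudo-labels and affinity fixed (the self-training
# convention: those are refreshed once per batch, before the step).
# dKL/dz_x = sum_w (2p / D_xw) (T_xw - U_xw) (z_x - beta_w), p = 1/(fuz-1).
latent_gradient <- function(Z, centers, U, T_, Aff, config) {
  p <- 1 / (config$fuzzifier - 1)
  d2 <- cluster_dist2(Z, centers)
  D <- membership_D(d2, centers, config$balance)
  # where the guard floor D = d2/2 is active, dD/dz is halved
  A <- 2 * p * (T_ - U) / D * ifelse(D == pmax(0.5 * d2, 1e-12) &
                                       config$balance > 0, 0.5, 1)
  g_kl <- rowSums(A) * Z - A %*% centers
  rs <- rowSums(Aff)
  g_aff <- 4 * (rs * Z - Aff %*% Z)
  clip_rows(config$eta1 * g_kl + config$eta2 * g_aff, 10)
}

# Cap per-row gradient norms; spikes arise when a latent point sits almost
# on a cluster center (1/D factor in the membership gradient).
clip_rows <- function(G, max_norm) {
  nrm <- sqrt(rowSums(G^2))
  sc <- pmin(1, max_norm / pmax(nrm, 1e-12))
  G * sc
}

# Numerical gradient of eta1*KL(T || U(Z, centers)) with respect to the
# centers (T fixed). The center block is tiny (C x latent_dim), so central
# differences are exact enough and keep the membership formula the single
# source of truth.
center_gradient <- function(Z, centers, T_, config, h = 1e-6) {
  G <- matrix(0, nrow(centers), ncol(centers))
  # the between-cluster penalty is held fixed at the current centers during
  # the step (as T and Aff are); otherwise shrinking one center into the
  # centroid is a degenerate descent direction for the KL term
  pen <- balance_penalty(centers, config$balance)
  f <- function(B) {
    D <- membership_D(cluster_dist2(Z, B), B, config$balance, pen = pen)
    U <- D^(-1 / (config$fuzzifier - 1))
    U <- U / rowSums(U)
    suppressWarnings(kl_loss(T_, U))
  }
  for (i in seq_len(nrow(centers))) {
    for (j in seq_len(ncol(centers))) {
      Bp <- centers; Bp[i, j] <- Bp[i, j] + h
      Bm <- centers; Bm[i, j] <- Bm[i, j] - h
      G[i, j] <- (f(Bp) - f(Bm)) / (2 * h)
    }
  }
  config$eta1 * G
}

#' Fit the deep fuzzy clustering partitioner
#'
#' Pretrains the autoencoder on the reconstruction loss, initializes
#' cluster centers by classical fuzzy c-means on the latent codes, then
#' alternates per batch: refresh membership, target, pseudo-labels and
#' affinity, and take one gradient step on the combined loss over the
#' network weights and the centers. Fully deterministic given
#' `config$seed`.
#'
#' @param X A [data_matrix] or numeric matrix (rows = samples), expected to
#'   be min-max normalized.
#' @param config An [idfc_config].
#' @return List of class `idfc_fit` with elements `model` (autoencoder),
#'   `state` (latent, centers, membership, target, affinity,
#'   pseudo_labels, resolved kernel), `loss_trajectory` (combined loss per
#'   epoch over the full data), and `config`.
#' @export
fit_idfc <- function(X, config = idfc_config()) {
  V <- if (inherits(X, "data_matrix")) X$values else as.matrix(X)
  n <- nrow(V)
  if (config$n_clusters > n) stop("n_clusters exceeds the number of samples")
  bn <- if (is.null(config$batch_size)) min(256L, n) else min(config$batch_size, n)

  model <- init_autoencoder(ncol(V), config$hidden_dim, config$latent_dim,
                            seed = derive_seed(config$seed, "ae_init"))
  rng <- local_rng(derive_seed(config$seed, "idfc_batches"))

  # -- stage 1: reconstruction-only pretraining
  for (ep in seq_len(config$pretrain_epochs)) {
    ord <- rng$sample(seq_len(n))
    for (batch in split_batches(ord, bn)) {
      Xb <- V[batch, , drop = FALSE]
      fw <- ae_forward(model, Xb)
      gr <- ae_gradients(model, Xb, fw, config$weight_decay)
      model <- ae_step(model, gr, config$pretrain_learning_rate %||% config$learning_rate)
    }
  }

  # -- stage 2: resolve kernel bandwidth and initialize centers on latent codes
  Z <- encode(model, V)
  kspec <- resolve_sigma(config$kernel, Z)
  centers <- init_centers_fcm(Z, config$n_clusters, config$fuzzifier,
                              seed = derive_seed(config$seed, "centers"))

  # -- stage 3: joint self-training
  trajectory <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- rng$sample(seq_len(n))
    for (batch in split_batches(ord, bn)) {
      Xb <- V[batch, , drop = FALSE]
      fw <- ae_forward(model, Xb)
      Zb <- fw$Z
      U <- compute_membership(Zb, centers, config$fuzzifier, config$balance)
      T_ <- compute_target(U)
      pl <- max.col(U, ties.method = "first")
      Aff <- compute_affinity(Zb, pl, kspec, config$delta)
      gz <- latent_gradient(Zb, centers, U, T_, Aff, config)
      gr <- ae_gradients(model, Xb, fw, config$weight_decay, grad_z_extra = gz)
      gc_ <- center_gradient(Zb, centers, T_, config)
      model <- ae_step(model, gr, config$learning_rate)
      centers <- centers - config$learning_rate * clip_rows(gc_, 10)
    }
    st <- idfc_state(model, V, centers, kspec, config)
    trajectory[ep] <- total_loss(model, V, st, config)
    if (!is.finite(trajectory[ep])) {
      stop("non-finite combined loss at epoch ", ep,
           "; reduce the learning rate or check the input scale")
    }
  }

  state <- idfc_state(model, V, centers, kspec, config)
  structure(list(model = model, state = state,
                 loss_trajectory = trajectory, config = config),
            class = "idfc_fit")
}

# Full-data fuzzy state snapshot for a given model + centers.
idfc_state <- function(model, V, centers, kspec, config) {
  Z <- encode(model, V)
  U <- compute_membership(Z, centers, config$fuzzifier, config$balance)
  T_ <- compute_target(U)
  pl <- max.col(U, ties.method = "first")
  Aff <- compute_affinity(Z, pl, kspec, config$delta)
  list(latent = Z, centers = centers, membership = U, target = T_,
       affinity = Aff, pseudo_labels = pl, kernel = kspec)
}

split_batches <- function(ord, bn) {
  split(ord, ceiling(seq_along(ord) / bn))
}

# Classical fuzzy c-means initialization of the centers, itself seeded
# from a multi-start k-means solution on the latent codes (fuzzy c-means
# from a random start is prone to poor local optima in a compact latent
# space). Falls back to the k-means centers if the fuzzy fit degenerates.
init_centers_fcm <- function(Z, C, fuzzifier, seed) {
  rng <- local_rng(seed)
  km <- rng$with(stats::kmeans(Z, centers = C, nstart = 10))
  res <- rng$with(tryCatch(
    e1071::cmeans(Z, centers = km$centers, m = fuzzifier, iter.max = 100),
    error = function(e) NULL))
  if (is.null(res) || nrow(res$centers) < C) res <- km
  unname(as.matrix(res$centers))
}

#' Assign samples to partitions from a fitted fuzzy state
#'
#' Each sample goes to its argmax-membership cluster (ties toward the lower
#' cluster index). Any partition that does not contain at least 2 samples
#' of every class present in `labels` is merged into the partition with the
#' nearest center, repeatedly, so that downstream per-partition classifier
#' training is well-posed.
#'
#' @param state A fuzzy state (the `state` element of an `idfc_fit`), or any
#'   list with `membership` and `centers`.
#' @param labels Class labels aligned with the membership rows (optional;
#'   when omitted the class-coverage rule is skipped and only empty
#'   partitions are dropped).
#' @return Object of class `partition_set` with `assignment` (integer per
#'   sample) and `partitions` (list of index vectors).
#' @export
assign_partitions <- function(state, labels = NULL) {
  U <- state$membership
  assignment <- max.col(U, ties.method = "first")
  centers <- as.matrix(state$centers)
  active <- sort(unique(assignment))

  lab <- if (is.null(labels)) NULL else factor(labels)
  valid <- function(ids) {
    vapply(ids, function(p) {
      if (is.null(lab)) return(sum(assignment == p) > 0)
      all(table(lab[assignment == p]) >= 2)
    }, logical(1))
  }

  repeat {
    ok <- valid(active)
    if (all(ok)) break
    if (length(active) == 1L) {
      stop("cannot form a valid partition: dataset too small or degenerate")
    }
    bad <- active[which(!ok)[1]]
    others <- setdiff(active, bad)
    d2 <- colSums((t(centers[others, , drop = FALSE]) - centers[bad, ])^2)
    target <- others[which.min(d2)]
    assignment[assignment == bad] <- target
    active <- others
  }
  parts <- lapply(active, function(p) which(assignment == p))
  names(parts) <- paste0("P", seq_along(parts))
  # renumber assignments 1..k in center order
  renum <- match(assignment, active)
  structure(list(assignment = renum, partitions = parts,
                 cluster_ids = active), class = "partition_set")
}
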