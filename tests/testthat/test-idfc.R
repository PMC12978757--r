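test_that("hybrid kernel matches its closed form and boundary cases", {
  ks <- kernel_spec(0.5, 1)
  expect_equal(hybrid_kernel(c(1, 2), c(1, 2), ks), 1)
  expect_equal(hybrid_kernel(c(0, 0), c(1, 0), ks),
               0.5 * exp(-0.5) + 0.5 * exp(-1))
  # alpha = 1: pure Gaussian
  ks1 <- kernel_spec(1, 2)
  expect_equal(hybrid_kernel(c(0, 0), c(3, 4), ks1), exp(-25 / 8))
  expect_error(hybrid_kernel(c(1, 2), c(1, 2, 3), ks), "length")
  expect_error(kernel_spec(0.5, -1), "sigma")

  set.seed(4)
  for (rep in 1:50) {
    a <- rnorm(5); b <- rnorm(5)
    al <- runif(1); sg <- runif(1, 0.5, 3)
    expect_equal(hybrid_kernel(a, b, kernel_spec(al, sg)),
                 oracle_kernel(a, b, al, sg), tolerance = 1e-12)
    expect_equal(hybrid_kernel(a, b, kernel_spec(al, sg)),
                 hybrid_kernel(b, a, kernel_spec(al, sg)))
  }
})

test_that("hybrid kernel Gram matrices are PSD with unit diagonal", {
  set.seed(11)
  for (rep in 1:50) {
    Z <- matrix(rnorm(20 * 3), 20, 3)
    ks <- kernel_spec(runif(1), runif(1, 0.5, 2))
    K <- sapply(1:20, function(i) sapply(1:20, function(j)
      hybrid_kernel(Z[i, ], Z[j, ], ks)))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(diag(K), rep(1, 20))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("fuzzy membership handles symmetry, the on-center limit, and oracles", {
  # equidistant point, mu = 0 -> (0.5, 0.5)
  U <- compute_membership(matrix(c(0.5, 0), 1, 2),
                          matrix(c(0, 1, 0, 0), 2, 2), 2, 0)
  expect_equal(as.vector(U), c(0.5, 0.5))
  # coincident with center 1 of 3 -> one-hot
  U2 <- compute_membership(matrix(c(0, 0), 1, 2),
                           matrix(c(0, 1, 2, 0, 1, 2), 3, 2), 2, 0.1)
  expect_equal(as.vector(U2), c(1, 0, 0))
  expect_error(compute_membership(matrix(1, 2, 2), matrix(1, 3, 2), 2, 0),
               "identical")

  # spec instance: 1-D points {0, 1}, centers {0.25, 0.75}, mu = 0.1
  U3 <- compute_membership(matrix(c(0, 1), 2, 1),
                           matrix(c(0.25, 0.75), 2, 1), 2, 0.1)
  expect_equal(U3, oracle_membership(matrix(c(0, 1), 2, 1),
                                     matrix(c(0.25, 0.75), 2, 1), 2, 0.1),
               tolerance = 1e-10)

  set.seed(21)
  for (rep in 1:100) {
    b <- sample(3:8, 1); C <- sample(2:4, 1); v <- sample(2:4, 1)
    Z <- matrix(rnorm(b * v), b, v)
    B <- matrix(rnorm(C * v, sd = 2), C, v)
    fuz <- runif(1, 1.3, 3); mu <- sample(c(0, runif(1, 0, 0.2)), 1)
    U <- compute_membership(Z, B, fuz, mu)
    expect_equal(U, oracle_membership(Z, B, fuz, mu), tolerance = 1e-10)
    expect_equal(rowSums(U), rep(1, b), tolerance = 1e-10)
    expect_true(all(U >= 0 & U <= 1))
  }
})

test_that("target distribution sharpens memberships per the double normalization", {
  # one-hot membership stays one-hot
  U <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(compute_target(U), U)
  # uniform membership, equal cluster sizes -> uniform target
  U2 <- matrix(1 / 3, 6, 3)
  expect_equal(compute_target(U2), U2)
  # spec instance
  U3 <- matrix(c(.9, .6, .2, .1, .4, .8), 3, 2)
  expect_equal(compute_target(U3), oracle_target(U3), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:100) {
    U <- random_simplex_rows(sample(3:10, 1), sample(2:4, 1))
    T_ <- compute_target(U)
    expect_equal(T_, oracle_target(U), tolerance = 1e-10)
    expect_equal(rowSums(T_), rep(1, nrow(U)), tolerance = 1e-10)
  }
})

test_that("KL loss is a divergence and matches direct summation", {
  U <- random_simplex_rows(4, 3)
  expect_equal(kl_loss(U, U), 0)
  # one-hot target vs (0.5, 0.5) rows -> 2 log 2
  T_ <- rbind(c(1, 0), c(0, 1))
  U2 <- matrix(0.5, 2, 2)
  expect_equal(kl_loss(T_, U2), 2 * log(2))
  expect_error(kl_loss(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")

  set.seed(41)
  for (rep in 1:100) {
    b <- sample(3:8, 1); C <- sample(2:4, 1)
    T_ <- random_simplex_rows(b, C); U <- random_simplex_rows(b, C)
    v <- kl_loss(T_, U)
    expect_equal(v, oracle_kl(T_, U), tolerance = 1e-10)
    expect_gte(v, 0)
  }
})

test_that("affinity matrix respects pseudo-labels and the kernel power", {
  ks <- kernel_spec(0.5, 1)
  Z <- matrix(rnorm(8), 4, 2)
  # all labels distinct -> identity
  A <- compute_affinity(Z, 1:4, ks, 1)
  expect_equal(A, diag(4))
  # identical same-label points -> affinity 1
  Z2 <- rbind(c(1, 1), c(1, 1))
  expect_equal(compute_affinity(Z2, c(1, 1), ks, 1)[1, 2], 1)

  set.seed(51)
  for (rep in 1:50) {
    Z <- matrix(rnorm(8), 4, 2)
    lab <- sample(1:2, 4, replace = TRUE)
    delta <- sample(1:3, 1)
    A <- compute_affinity(Z, lab, ks, delta)
    expect_equal(A, oracle_affinity(Z, lab, 0.5, 1, delta), tolerance = 1e-10)
    expect_equal(A, t(A))
  }
})

test_that("reconstruction loss equals a direct elementwise sum", {
  set.seed(61)
  m <- init_autoencoder(3, 4, 2, seed = 1)
  X <- matrix(rnorm(15), 5, 3)
  fw <- hdec:::ae_forward(m, X)
  manual <- mean(rowSums((fw$Xh - X)^2)) +
    1e-3 * (sum(m$W1^2) + sum(m$W2^2) + sum(m$W3^2) + sum(m$W4^2))
  expect_equal(reconstruction_loss(m, X, 1e-3), manual, tolerance = 1e-12)
  # zero input, zero biases: only the decay term survives at gamma > 0
  X0 <- matrix(0, 4, 3)
  pen <- sum(m$W1^2) + sum(m$W2^2) + sum(m$W3^2) + sum(m$W4^2)
  expect_equal(reconstruction_loss(m, X0, 2) -
                 reconstruction_loss(m, X0, 1), pen)
  expect_error(reconstruction_loss(m, matrix(0, 2, 5), 0), "dimension")
})

test_that("combined loss decomposes into its three terms", {
  set.seed(71)
  m <- init_autoencoder(4, 5, 2, seed = 2)
  X <- matrix(runif(24), 6, 4)
  cfg <- idfc_config(n_clusters = 2, latent_dim = 2, hidden_dim = 5,
                     eta1 = 0.3, eta2 = 0.05, balance = 0,
                     kernel = kernel_spec(0.5, 1))
  Z <- encode(m, X)
  U <- compute_membership(Z, matrix(rnorm(4), 2, 2), 2, 0)
  T_ <- compute_target(U)
  pl <- max.col(U, ties.method = "first")
  Aff <- compute_affinity(Z, pl, cfg$kernel, 1)
  st <- list(latent = Z, membership = U, target = T_, affinity = Aff)
  tot <- total_loss(m, X, st, cfg)
  aff_term <- sum(as.matrix(dist(Z))^2 * Aff)
  expect_equal(tot, reconstruction_loss(m, X, cfg$weight_decay) +
                 0.3 * kl_loss(T_, U) + 0.05 * aff_term, tolerance = 1e-10)
  # eta1 = eta2 = 0 -> reconstruction only
  cfg0 <- cfg; cfg0$eta1 <- 0; cfg0$eta2 <- 0
  expect_equal(total_loss(m, X, st, cfg0),
               reconstruction_loss(m, X, cfg$weight_decay))
  # identical latent points: affinity term contributes nothing
  stI <- st; stI$latent <- matrix(1, 6, 2)
  expect_equal(total_loss(m, X, stI, cfg0),
               reconstruction_loss(m, X, cfg$weight_decay))
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  X <- matrix(runif(30), 6, 5)
  m <- init_autoencoder(5, 4, 2, seed = 3)
  cfg <- idfc_config(n_clusters = 2, latent_dim = 2, hidden_dim = 4,
                     balance = 0.05, eta1 = 0.3, eta2 = 0.1,
                     kernel = kernel_spec(0.5, 1))
  centers <- matrix(c(0.2, 0.1, -0.3, 0.4), 2, 2)
  fw <- hdec:::ae_forward(m, X)
  U <- compute_membership(fw$Z, centers, cfg$fuzzifier, cfg$balance)
  T_ <- compute_target(U)
  pl <- max.col(U, ties.method = "first")
  Aff <- compute_affinity(fw$Z, pl, cfg$kernel, cfg$delta)
  gz <- hdec:::latent_gradient(fw$Z, centers, U, T_, Aff, cfg)
  gr <- hdec:::ae_gradients(m, X, fw, cfg$weight_decay, grad_z_extra = gz)

  loss_of <- function(mm) {
    Z <- encode(mm, X)
    Um <- compute_membership(Z, centers, cfg$fuzzifier, cfg$balance)
    D2 <- as.matrix(dist(Z))^2
    reconstruction_loss(mm, X, cfg$weight_decay) +
      cfg$eta1 * kl_loss(T_, Um) + cfg$eta2 * sum(D2 * Aff)
  }
  h <- 1e-6
  for (probe in list(list("W1", 1, 1), list("W2", 2, 1), list("W4", 3, 2),
                     list("b1", 2, NULL), list("b3", 1, NULL))) {
    fld <- probe[[1]]; i <- probe[[2]]; j <- probe[[3]]
    mp <- m; mn <- m
    if (is.null(j)) {
      mp[[fld]][i] <- mp[[fld]][i] + h; mn[[fld]][i] <- mn[[fld]][i] - h
      g <- gr[[fld]][i]
    } else {
      mp[[fld]][i, j] <- mp[[fld]][i, j] + h
      mn[[fld]][i, j] <- mn[[fld]][i, j] - h
      g <- gr[[fld]][i, j]
    }
    expect_equal(g, (loss_of(mp) - loss_of(mn)) / (2 * h), tolerance = 1e-5)
  }
})

test_that("fit produces consistent state, is deterministic, and rejects bad input", {
  gen <- generate_clustered(synthetic_spec(
    n_samples = 45, n_features = 15, n_informative = 3,
    n_latent_clusters = 3, cluster_separation = 8, seed = 2))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  cfg <- idfc_config(epochs = 10, pretrain_epochs = 20, seed = 9)
  fit <- fit_idfc(Xn, cfg)
  expect_equal(rowSums(fit$state$membership), rep(1, 45), tolerance = 1e-10)
  expect_equal(rowSums(fit$state$target), rep(1, 45), tolerance = 1e-10)
  expect_equal(fit$state$affinity, t(fit$state$affinity))
  expect_equal(length(fit$loss_trajectory), 10L)
  fit2 <- fit_idfc(Xn, cfg)
  expect_identical(fit$state$membership, fit2$state$membership)
  expect_identical(fit$loss_trajectory, fit2$loss_trajectory)

  expect_error(fit_idfc(Xn$values[1:2, ], idfc_config(n_clusters = 3)),
               "exceeds")
})

test_that("degenerate schedule reduces to fuzzy c-means on the raw latent", {
  gen <- generate_clustered(synthetic_spec(
    n_samples = 40, n_features = 12, n_informative = 3,
    n_latent_clusters = 2, cluster_separation = 8, seed = 3))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  cfg <- idfc_config(n_clusters = 2, epochs = 0, pretrain_epochs = 0, seed = 4)
  fit <- fit_idfc(Xn, cfg)
  # state equals a direct membership computation on the untrained encoder
  m <- init_autoencoder(12, cfg$hidden_dim, cfg$latent_dim,
                        seed = hdec:::derive_seed(4, "ae_init"))
  Z <- encode(m, Xn$values)
  expect_equal(fit$state$latent, Z)
  U <- compute_membership(Z, fit$state$centers, cfg$fuzzifier, cfg$balance)
  expect_equal(fit$state$membership, U)
  # reproducible
  fitb <- fit_idfc(Xn, cfg)
  expect_identical(max.col(fit$state$membership),
                   max.col(fitb$state$membership))
})

test_that("full-batch small-step training yields a non-increasing loss", {
  gen <- generate_clustered(synthetic_spec(
    n_samples = 60, n_features = 20, n_informative = 3,
    n_latent_clusters = 3, cluster_separation = 6, seed = 2))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  fit <- fit_idfc(Xn, idfc_config(seed = 2, epochs = 60, pretrain_epochs = 100,
                                  learning_rate = 1e-4))
  expect_lte(max(diff(fit$loss_trajectory)), 1e-9)
})

test_that("partition assignment follows argmax and merges invalid partitions", {
  # one-hot memberships -> argmax positions
  st <- list(membership = diag(3)[c(1, 2, 3, 2, 1, 3), ],
             centers = matrix(c(0, 5, 10, 0, 0, 0), 3, 2))
  ps <- assign_partitions(st)
  expect_equal(ps$assignment, c(1L, 2L, 3L, 2L, 1L, 3L))
  expect_equal(lengths(ps$partitions), c(P1 = 2L, P2 = 2L, P3 = 2L))

  # a singleton partition merges into the nearest-center partition
  U <- rbind(diag(3)[rep(1, 4), ], diag(3)[rep(2, 4), ], diag(3)[3, , drop = FALSE])
  lab <- factor(c("A", "A", "B", "B", "A", "A", "B", "B", "A"))
  st2 <- list(membership = U, centers = matrix(c(0, 10, 11, 0, 0, 0), 3, 2))
  ps2 <- assign_partitions(st2, lab)
  expect_equal(length(ps2$partitions), 2L)
  expect_equal(ps2$assignment[9], 2L)  # joined the closer center (cluster 2)

  # impossible invariant -> error
  st3 <- list(membership = diag(2)[c(1, 2), ], centers = matrix(0:1, 2, 1))
  expect_error(assign_partitions(st3, factor(c("A", "B"))), "valid partition")
})
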