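test_that("conventional-KNN CV accuracy behaves at the extremes", {
  # perfectly separable blobs
  X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 5, 0.1), 20, 2))
  y <- rep(c("A", "B"), each = 20)
  expect_equal(knn_cv_accuracy(X, y, seed = 1), 1.0)

  # pure noise stays in the chance band
  set.seed(5)
  Xn <- matrix(rnorm(400), 200, 2)
  yn <- rep(c("A", "B"), 100)
  acc <- knn_cv_accuracy(Xn, yn, seed = 2)
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)

  expect_error(knn_cv_accuracy(X, rep("A", 40)), "single-class")
  expect_warning(knn_cv_accuracy(X[c(1:20, 21:23), ], y[c(1:20, 21:23)],
                                 folds = 5, seed = 1), "reducing folds")
  # determinism
  expect_identical(knn_cv_accuracy(Xn, yn, seed = 7),
                   knn_cv_accuracy(Xn, yn, seed = 7))
})

test_that("value parameters reward informative and punish harmful features", {
  # constant feature: its removal cannot change any distance -> nu = 1
  set.seed(9)
  base <- c(rnorm(20, 0), rnorm(20, 3))
  X <- cbind(base, 0, rnorm(40))
  y <- rep(c("A", "B"), each = 20)
  vp <- compute_value_params(X, y, seed = 3)
  expect_equal(vp$value_params, 1 - (vp$acc_0 - vp$acc_e))
  expect_equal(vp$value_params[2], 1, tolerance = 1e-10)

  # the informative feature gets the largest value parameter
  hits <- 0
  for (s in 1:10) {
    gen <- generate_classification(synthetic_spec(
      n_samples = 100, n_features = 5, n_informative = 1, effect_size = 2,
      n_latent_clusters = 0, seed = 100 + s))
    v <- compute_value_params(gen$data$values, gen$data$labels, seed = s)
    hits <- hits + (which.max(v$value_params) == gen$informative)
  }
  expect_gte(hits, 9)
})

test_that("weights normalize value parameters onto the simplex", {
  expect_equal(compute_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(compute_weights(c(1, 3)), c(0.25, 0.75))
  set.seed(15)
  for (rep in 1:20) {
    v <- runif(sample(2:10, 1), 0.01, 2)
    expect_equal(sum(compute_weights(v)), 1, tolerance = 1e-10)
  }
  expect_error(compute_weights(c(1, -1)), "value_params > 0")
})

test_that("weighted Minkowski distance is a metric matching hand arithmetic", {
  W <- c(0.25, 0.75)
  expect_equal(wminkowski_distance(c(1, 2), c(1, 2), W, 2), 0)
  expect_equal(wminkowski_distance(c(0, 0), c(1, 2), W, 2), sqrt(3.25))
  expect_error(wminkowski_distance(c(0, 0), c(1, 2), W, 0.5), "rho")

  # uniform weights, rho = 2: Euclidean / sqrt(t)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(wminkowski_distance(a, b, rep(0.25, 4), 2),
               sqrt(sum((a - b)^2)) / 2, tolerance = 1e-12)

  set.seed(25)
  for (rep in 1:100) {
    t_ <- sample(2:5, 1)
    W <- compute_weights(runif(t_, 0.1, 1))
    rho <- runif(1, 1, 3)
    x <- rnorm(t_); y <- rnorm(t_); z <- rnorm(t_)
    dxy <- wminkowski_distance(x, y, W, rho)
    expect_equal(dxy, oracle_wminkowski(x, y, W, rho), tolerance = 1e-12)
    expect_equal(dxy, wminkowski_distance(y, x, W, rho))
    expect_lte(dxy, wminkowski_distance(x, z, W, rho) +
                 wminkowski_distance(z, y, W, rho) + 1e-12)
  }
})

test_that("zero-weight features do not affect distances", {
  W <- c(0.5, 0.5, 0)
  a <- c(1, 2, 99); b <- c(0, 0, -99)
  expect_equal(wminkowski_distance(a, b, W, 2),
               wminkowski_distance(a[1:2], b[1:2], c(0.5, 0.5), 2))
})

test_that("class prediction uses average neighbour distance per class", {
  # query at 0: neighbours A at +-1 (avg 1), B at 0.5 (avg 0.5) -> B
  tr <- cbind(c(1, -1, 0.5, 3, -3), 0)
  y <- c("A", "A", "B", "A", "A")
  model <- structure(list(train_matrix = tr, train_labels = factor(y),
                          feature_weights = c(0.5, 0.5), value_params = c(1, 1),
                          baseline_accuracy = NA, ablation_accuracies = NA,
                          minkowski_order = 2, k = 3L, scope = "neighbors"),
                     class = "iknn")
  expect_equal(as.character(predict(model, matrix(c(0, 0), 1, 2))), "B")
  # all k neighbours one class -> that class
  model$k <- 2L
  expect_equal(as.character(predict(model, matrix(c(-2, 0), 1, 2))), "A")
})

test_that("uniform weights and rho = 2 reproduce Euclidean neighbour sets", {
  set.seed(35)
  gen <- generate_classification(synthetic_spec(
    n_samples = 60, n_features = 6, n_informative = 2, effect_size = 1.5,
    n_latent_clusters = 0, seed = 4))
  X <- gen$data$values; y <- gen$data$labels
  model <- fit_iknn(X, y, k = 5, seed = 2)
  model$feature_weights <- rep(1 / 6, 6)   # force the conventional limit
  Q <- matrix(rnorm(100 * 6), 100, 6)
  D <- hdec:::wminkowski_cross(Q, X, model$feature_weights, 2)
  for (i in 1:100) {
    nb_w <- order(D[i, ], seq_len(nrow(X)))[1:5]
    nb_e <- oracle_knn_neighbors(X, Q[i, ], 5)
    expect_equal(nb_w, nb_e)
  }
})

test_that("feature weighting helps when one feature dominates", {
  wins <- 0
  for (s in 1:7) {
    gen <- generate_classification(synthetic_spec(
      n_samples = 120, n_features = 8, n_informative = 1, effect_size = 3,
      n_latent_clusters = 0, seed = 200 + s))
    sp <- stratified_split(gen$data, 0.7, seed = s)
    tr <- gen$data[sp$train, ]; te <- gen$data[sp$test, ]
    m <- fit_iknn(tr$values, tr$labels, k = 5, seed = s)
    acc_i <- mean(as.character(predict(m, te$values)) ==
                    as.character(te$labels))
    # conventional KNN: uniform weights
    mu <- m; mu$feature_weights <- rep(1 / 8, 8)
    acc_u <- mean(as.character(predict(mu, te$values)) ==
                    as.character(te$labels))
    wins <- wins + (acc_i >= acc_u)
  }
  expect_gte(wins, 4)
})
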