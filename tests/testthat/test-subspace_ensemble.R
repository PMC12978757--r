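fused_of <- function(idx) structure(list(indices = idx), class = "fused_features")

test_that("subspace draws respect size, weights, and the overlap bonus", {
  cfg <- ensemble_config(subspace_ratio = 0.5, overlap_coeff = 0.3)
  sp <- draw_subspace(fused_of(1:100), cfg, 1, rng_seed = 5)
  expect_equal(length(sp$primary_indices), 50L)
  expect_true(all(sp$primary_indices %in% 1:100))
  expect_false(any(duplicated(sp$primary_indices)))
  expect_true(all(sp$weight_vector >= 0.5 & sp$weight_vector <= 1.5))
  shared <- sp$primary_indices %in% sp$secondary_indices
  expect_equal(sp$column_multipliers,
               sp$weight_vector * (1 + 0.3 * shared))
  # lambda = 0: multipliers equal the weights
  cfg0 <- ensemble_config(subspace_ratio = 0.5, overlap_coeff = 0)
  sp0 <- draw_subspace(fused_of(1:100), cfg0, 1, rng_seed = 5)
  expect_equal(sp0$column_multipliers, sp0$weight_vector)
  # determinism
  expect_identical(sp$primary_indices,
                   draw_subspace(fused_of(1:100), cfg, 1, rng_seed = 5)$primary_indices)
  # tiny ratio floors at 2 columns
  cfg_t <- ensemble_config(subspace_ratio = 0.01)
  expect_equal(length(draw_subspace(fused_of(1:10), cfg_t, 1, 1)$primary_indices), 2L)
})

test_that("applying a subspace selects and scales columns", {
  X <- matrix(rnorm(50), 5, 10)
  sp <- structure(list(primary_indices = c(2L, 7L, 9L),
                       column_multipliers = c(1, 1, 1)),
                  class = "subspace_spec")
  expect_equal(apply_subspace(X, sp), X[, c(2, 7, 9)])
  sp$column_multipliers <- c(2, 0.5, 3)
  one <- matrix(1, 1, 10)
  expect_equal(as.vector(apply_subspace(one, sp)), c(2, 0.5, 3))
  # brute force
  man <- X[, c(2, 7, 9)]
  for (j in 1:3) man[, j] <- man[, j] * c(2, 0.5, 3)[j]
  expect_equal(apply_subspace(X, sp), man)
  sp$primary_indices <- c(2L, 99L, 9L)
  expect_error(apply_subspace(X, sp), "out of range")
})

test_that("rotation construction yields orthogonal block-diagonal matrices", {
  set.seed(45)
  cfg <- ensemble_config()
  for (rep in 1:10) {
    S <- matrix(rnorm(100 * 9), 100, 9)
    rot <- build_rotation(S, NULL, cfg, rng_seed = rep)
    R <- rot$rotation
    expect_equal(max(abs(t(R) %*% R - diag(9))), 0, tolerance = 1e-6)
    expect_setequal(unlist(rot$groups), 1:9)
    expect_equal(rot$n_subsample, 75L)     # 75% of 100 rows per group PCA
    expect_true(rot$group_size %in% c(2, 3, 4))
  }
  # single group: the rotation IS that PCA loading matrix
  cfg1 <- ensemble_config(group_size_choices = 3L)
  S3 <- matrix(rnorm(60), 20, 3)
  rot3 <- build_rotation(S3, NULL, cfg1, rng_seed = 2)
  expect_equal(length(rot3$groups), 1L)
  expect_equal(max(abs(t(rot3$rotation) %*% rot3$rotation - diag(3))), 0,
               tolerance = 1e-6)
  # zero-variance group -> identity loadings
  Sz <- cbind(matrix(1, 20, 2), matrix(rnorm(40), 20, 2))
  cfgz <- ensemble_config(group_size_choices = 2L)
  rotz <- build_rotation(Sz, NULL, cfgz, rng_seed = 3)
  expect_equal(max(abs(t(rotz$rotation) %*% rotz$rotation - diag(4))), 0,
               tolerance = 1e-6)
  expect_error(build_rotation(matrix(1, 3, 2), NULL, cfg, 1), "at least 4")
})

test_that("mixed-space enhancement is the stated affine blend", {
  set.seed(55)
  S <- matrix(rnorm(12), 3, 4)
  rot <- build_rotation(matrix(rnorm(80), 20, 4), NULL,
                        ensemble_config(group_size_choices = 2L), rng_seed = 1)
  expect_equal(mixed_enhance(S, rot, 1), S)
  # alpha = 0: rotation preserves row norms
  e0 <- mixed_enhance(S, rot, 0)
  expect_equal(sqrt(rowSums(e0^2)), sqrt(rowSums(S^2)), tolerance = 1e-8)
  for (a in c(0, 0.25, 0.5, 1)) {
    expect_equal(mixed_enhance(S, rot, a), a * S + (1 - a) * S %*% rot$rotation,
                 tolerance = 1e-12)
  }
  expect_error(mixed_enhance(matrix(1, 2, 3), rot, 0.5), "shape")
})

test_that("plurality voting matches exhaustive enumeration of 3 binary voters", {
  classes <- c("A", "B")
  pats <- expand.grid(v1 = classes, v2 = classes, v3 = classes,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pats))) {
    votes_chr <- unlist(pats[r, ])
    counts <- matrix(c(sum(votes_chr == "A"), sum(votes_chr == "B")), 1, 2,
                     dimnames = list(NULL, classes))
    out <- hdec:::plurality_vote(counts, classes, NULL, 3)
    expected <- names(which.max(table(factor(votes_chr, classes))))
    expect_equal(as.character(out$labels), expected)
    expect_equal(unname(out$vote_fractions[1, expected]), max(counts) / 3)
  }
  # tie on 2 voters: score sum decides, then lowest class index
  tie <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, classes))
  sc <- matrix(c(0.2, 0.9), 1, 2)
  expect_equal(as.character(hdec:::plurality_vote(tie, classes, sc, 2)$labels), "B")
  expect_equal(as.character(hdec:::plurality_vote(tie, classes, NULL, 2)$labels), "A")
})

test_that("ensemble fit is deterministic and assigns learners in order", {
  gen <- generate_classification(synthetic_spec(
    n_samples = 60, n_features = 30, n_informative = 8, effect_size = 2,
    n_latent_clusters = 0, seed = 6))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  cfg <- ensemble_config(seed = 3)
  fused <- fused_of(1:30)
  fit <- fit_ensemble(Xn$values, Xn$labels, fused, cfg)
  expect_equal(vapply(fit$blocks, `[[`, character(1), "kind"),
               c("random_forest", "svm", "iknn"))
  p1 <- predict(fit, Xn$values)
  fitb <- fit_ensemble(Xn$values, Xn$labels, fused, cfg)
  p2 <- predict(fitb, Xn$values)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$vote_fractions, p2$vote_fractions)
  expect_identical(fit$blocks[[2]]$spec$primary_indices,
                   fitb$blocks[[2]]$spec$primary_indices)
})

test_that("prediction is invariant to block order", {
  gen <- generate_classification(synthetic_spec(
    n_samples = 50, n_features = 20, n_informative = 5, effect_size = 2,
    n_latent_clusters = 0, seed = 8))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  fit <- fit_ensemble(Xn$values, Xn$labels, fused_of(1:20),
                      ensemble_config(seed = 4))
  p <- predict(fit, Xn$values)
  fit_rev <- fit
  fit_rev$blocks <- rev(fit$blocks)
  p_rev <- predict(fit_rev, Xn$values)
  expect_identical(p$labels, p_rev$labels)
  expect_identical(p$vote_fractions, p_rev$vote_fractions)
})

test_that("with all enhancements off a single-block ensemble equals its learner", {
  gen <- generate_classification(synthetic_spec(
    n_samples = 60, n_features = 15, n_informative = 5, effect_size = 1.5,
    n_latent_clusters = 0, seed = 9))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  cfg <- ensemble_config(n_blocks = 1, learner_kinds = "random_forest",
                         subspace_ratio = 1, overlap_coeff = 0,
                         alpha_mse = 1, weight_range = c(1, 1), seed = 11)
  expect_warning(fit <- fit_ensemble(Xn$values, Xn$labels, fused_of(1:15), cfg),
                 NA)
  p_ens <- predict(fit, Xn$values)$labels
  direct <- fit_learner("random_forest", Xn$values, Xn$labels,
                        seed = fit$blocks[[1]]$learner_seed)
  p_dir <- predict(direct, Xn$values)
  expect_identical(as.character(p_ens), as.character(p_dir))
})

test_that("even block counts on binary tasks warn about vote ties", {
  gen <- generate_classification(synthetic_spec(
    n_samples = 40, n_features = 10, n_informative = 3, effect_size = 2,
    n_latent_clusters = 0, seed = 10))
  Xn <- apply_minmax(fit_minmax(gen$data), gen$data)
  expect_warning(
    fit_ensemble(Xn$values, Xn$labels, fused_of(1:10),
                 ensemble_config(n_blocks = 2,
                                 learner_kinds = c("random_forest", "svm"),
                                 seed = 1)),
    "tie")
})
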