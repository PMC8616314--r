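test_that("between-class scatter matches the summation formula", {
  x <- rbind(c(1, 1, 3, 3), c(0, 2, 2, 4))
  sc <- between_class_scatter(x, c(0, 0, 1, 1))
  expect_equal(sc$S, matrix(4, 2, 2))
  expect_equal(unname(sc$class_means[, "0"]), c(1, 1))
  expect_equal(unname(sc$class_means[, "1"]), c(3, 3))
  expect_equal(unname(sc$grand_mean), c(2, 2))
  expect_equal(sc$class_sizes, c(2L, 2L))

  # equal class means collapse S to zero
  x0 <- rbind(c(1, 2, 1, 2), c(3, 4, 3, 4))
  expect_equal(between_class_scatter(x0, c(0, 0, 1, 1))$S, matrix(0, 2, 2))

  # permuting samples leaves S unchanged
  perm <- c(3, 1, 4, 2)
  expect_equal(between_class_scatter(x[, perm], c(0, 0, 1, 1)[perm])$S, sc$S)

  expect_error(between_class_scatter(x, c(1, 1, 1, 1)), "both classes")
})

test_that("unitizing whitens the scatter and falls back gracefully", {
  u <- unitize_scatter(matrix(4, 2, 2))
  expect_equal(u$W, matrix(0.25, 2, 1))
  expect_equal(u$eigenvalues, 8)
  expect_false(u$degenerate)
  expect_equal(t(u$W) %*% matrix(4, 2, 2) %*% u$W, matrix(1, 1, 1))

  z <- unitize_scatter(matrix(0, 3, 3))
  expect_true(z$degenerate)
  expect_equal(z$W, matrix(1 / sqrt(3), 3, 1))

  expect_error(unitize_scatter(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("whitening and rank properties hold over random fixtures", {
  set.seed(101)
  for (i in 1:300) {
    p <- sample(2:4, 1)
    sc <- random_scatter_fixture(p)
    # two classes: rank(S) <= 1
    expect_lte(sum(eigen(sc$S, symmetric = TRUE)$values > 1e-8), 1)
    u <- unitize_scatter(sc)
    if (!u$degenerate) {
      expect_equal(t(u$W) %*% sc$S %*% u$W, diag(ncol(u$W)), tolerance = 1e-8)
      # retained eigenvector parallel to the class-mean difference
      d <- sc$class_means[, 2] - sc$class_means[, 1]
      cosine <- abs(sum(u$W[, 1] * d)) /
        (sqrt(sum(u$W[, 1]^2)) * sqrt(sum(d^2)))
      expect_gte(cosine, 1 - 1e-8)
    }
  }
})

test_that("fused rows reproduce the worked example and the closed-form oracle", {
  b <- worked_example_bundle()
  fit <- fit_feature_fusion(b, standardize = FALSE)
  expect_equal(unname(fit$fused$values[, 1]), c(0.25, 0.75, 1.25, 1.75))
  expect_equal(unname(fit$transform$W[, 1]), c(0.25, 0.25))

  # oracle equivalence: eigen path vs closed-form rank-1 eigenpair
  set.seed(77)
  for (i in 1:60) {
    p <- sample(2:4, 1)
    n <- 30
    labels <- rep(c(0, 1), each = n / 2)
    x <- matrix(rnorm(p * n), p, n) + outer(runif(p, -1.5, 1.5), labels)
    b2 <- modality_bundle(lapply(seq_len(p), function(k) {
      make_table(matrix(x[k, ], n, 1), paste0("m", k), labels)
    }))
    fitted <- fit_feature_fusion(b2, standardize = FALSE)
    oracle <- oracle_fused_row(x, labels)
    expect_equal(unname(fitted$fused$values[, 1]),
                 align_sign(oracle, fitted$fused$values[, 1]),
                 tolerance = 1e-8)
  }
})

test_that("fusion output is rectangular, oriented, and registry sized", {
  reg <- default_feature_registry()
  sc <- default_study_scenario(n_train = 40, n_test = 10)
  fit <- fit_feature_fusion(sc$train, registry = reg)
  expect_equal(ncol(fit$fused$values), 109)
  expect_identical(fit$fused$sample_ids, sc$train[[1]]$sample_ids)
  # sign convention: positive class mean >= negative class mean per feature
  pos <- sc$train_labels == 1
  gaps <- colMeans(fit$fused$values[pos, ]) - colMeans(fit$fused$values[!pos, ])
  expect_true(all(gaps >= -1e-12))
})

test_that("duplicated modality fuses to the original ranking", {
  labels <- rep(c(0, 1), each = 10)
  v <- rnorm(20) + labels
  b <- modality_bundle(list(
    make_table(matrix(v, 20, 1), "A", labels),
    make_table(matrix(v, 20, 1), "B", labels)
  ))
  fit <- fit_feature_fusion(b, standardize = FALSE)
  expect_equal(order(fit$fused$values[, 1]), order(v))
})

test_that("a fitted transform applies without refitting", {
  sim <- simulate_multimodal_features(
    simulation_config(n_per_class = 25, p = 3, m = 6, delta = 1, seed = 9)
  )
  fit <- fit_feature_fusion(sim$bundle)

  # consistency: applying to the training bundle reproduces training output
  reapplied <- apply_feature_fusion(fit$transform, sim$bundle)
  expect_equal(reapplied$values, fit$fused$values)

  # single held-out unlabeled sample works
  one <- subset_bundle(sim$bundle, sample_ids = sim$bundle[[1]]$sample_ids[1])
  one_nolab <- modality_bundle(lapply(one, function(t) {
    feature_table(t$values, t$sample_ids, t$feature_names, t$modality_id)
  }))
  fused_one <- apply_feature_fusion(fit$transform, one_nolab)
  expect_equal(fused_one$values[1, ], fit$fused$values[1, ])

  # no silent modality reordering
  flipped <- subset_bundle(sim$bundle, modalities = rev(names(sim$bundle)))
  expect_error(apply_feature_fusion(fit$transform, flipped),
               "modality order mismatch")
})

test_that("sequence combinations enumerate 15 feature types for 4 sequences", {
  ids <- c("T1WI", "CE_T1WI", "T2WI", "T2_FLAIR")
  combos <- enumerate_sequence_combinations(ids)
  expect_length(combos, 15)
  expect_equal(sum(lengths(combos) == 1), 4)
  expect_equal(sum(lengths(combos) == 2), 6)
  expect_equal(sum(lengths(combos) == 3), 4)
  expect_equal(sum(lengths(combos) == 4), 1)
  expect_identical(combos, enumerate_sequence_combinations(ids))
  expect_identical(combos[[1]], "T1WI")
  expect_identical(combos[[15]], ids)
})
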