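test_that("the default grid is the 15-model Cartesian product in stable order", {
  zoo <- build_model_zoo()
  expect_length(zoo, 15)
  ids <- vapply(zoo, spec_id, character(1))
  expect_equal(anyDuplicated(ids), 0)
  # selectors outer, classifiers inner
  expect_identical(ids[1:3], paste0("anova+", registered_classifiers()))
  expect_identical(ids, vapply(build_model_zoo(), spec_id, character(1)))

  expect_length(build_model_zoo(list(selectors = "mrmr",
                                     classifiers = "logistic")), 1)
  expect_error(build_model_zoo(list(selectors = "pca")), "unknown selector")
  expect_error(build_model_zoo(list(classifiers = "knn")), "unknown classifier")
})

test_that("every registered selector returns k training-set features", {
  set.seed(31)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, sprintf("f%02d", 1:12)))
  x[, 1] <- x[, 1] + 2 * y   # one strong feature
  for (sel in registered_selectors()) {
    got <- select_features(sel, x, y, k = 4, seed = 1)
    expect_length(got, 4)
    expect_true(all(got %in% colnames(x)))
    # the strong feature should always make the cut
    expect_true("f01" %in% got)
  }
})

test_that("stratified CV is deterministic, stratified, and leak-free", {
  sim <- simulate_multimodal_features(
    simulation_config(n_per_class = 30, p = 1, m = 8, delta = 1.2,
                      informative_fraction = 0.5, seed = 17)
  )
  tab <- sim$bundle[[1]]
  spec <- model_spec("anova", "logistic", selector_k = 3)

  r1 <- run_stratified_cv(spec, tab, folds = 5, seed = 5)
  r2 <- run_stratified_cv(spec, tab, folds = 5, seed = 5)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$selected_features, r2$selected_features)
  expect_equal(r1$acc_i, mean(r1$per_fold$acc))

  # stratification: each fold's class ratio within 1 sample of global
  y <- tab$labels
  fold_id <- radfusion:::stratified_folds(y, 5, derive_seed(5, "cv_folds"))
  for (f in 1:5) {
    expect_lte(abs(sum(y[fold_id == f] == 1) - mean(y) * sum(fold_id == f)), 1)
  }

  # selection is refit inside folds on training rows only: poisoning a
  # fold's held-out rows leaves that fold's selection unchanged
  f <- 1
  poisoned <- tab$values
  poisoned[fold_id == f, ] <- matrix(rnorm(sum(fold_id == f) * ncol(poisoned),
                                           sd = 100),
                                     sum(fold_id == f))
  tab_p <- feature_table(poisoned, tab$sample_ids, tab$feature_names,
                         tab$modality_id, labels = y)
  rp <- run_stratified_cv(spec, tab_p, folds = 5, seed = 5)
  expect_identical(rp$selected_features[[f]], r1$selected_features[[f]])
})

test_that("CV hits the separable limit and stays null on shuffled labels", {
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 1] <- y * 10 + rnorm(n, sd = 0.01)
  tab <- make_table(x, "A", y)
  sep <- run_stratified_cv(model_spec("anova", "logistic", selector_k = 2),
                           tab, folds = 5, seed = 2)
  expect_equal(sep$mean_auc, 1)

  # null: with labels shuffled independently of the features, the CV AUC
  # (averaged over a few independent shuffles to tame single-run noise)
  # stays near chance
  set.seed(404)
  n2 <- 200
  x2 <- matrix(rnorm(n2 * 10), n2, 10, dimnames = list(NULL, paste0("f", 1:10)))
  null_aucs <- vapply(1:5, function(r) {
    y2 <- sample(rep(c(0, 1), each = n2 / 2))
    run_stratified_cv(model_spec("anova", "logistic", selector_k = 3),
                      make_table(x2, "A", y2), folds = 5, seed = 8)$mean_auc
  }, numeric(1))
  expect_gt(mean(null_aucs), 0.4)
  expect_lt(mean(null_aucs), 0.6)
})

test_that("ranking sorts by AUC with accuracy and id tie-breaks", {
  fake <- function(sel, clf, auc, acc) {
    structure(list(spec = model_spec(sel, clf), mean_auc = auc,
                   mean_acc = acc, acc_i = acc), class = "cv_report")
  }
  a <- fake("anova", "logistic", 0.9, 0.8)
  b <- fake("mrmr", "logistic", 0.8, 0.9)
  c1 <- fake("relieff", "svm_rbf", 0.7, 0.7)
  expect_identical(rank_models(list(c1, a, b)), list(a, b, c1))

  # AUC tie -> higher accuracy first
  t1 <- fake("anova", "logistic", 0.85, 0.80)
  t2 <- fake("mrmr", "logistic", 0.85, 0.70)
  expect_identical(rank_models(list(t2, t1)), list(t1, t2))

  # full tie -> lexicographic spec id, invariant to input order
  u1 <- fake("anova", "logistic", 0.85, 0.8)
  u2 <- fake("mutinfo", "logistic", 0.85, 0.8)
  expect_identical(rank_models(list(u2, u1)), rank_models(list(u1, u2)))
})

test_that("top-k screening refits deployable models", {
  sim <- simulate_multimodal_features(
    simulation_config(n_per_class = 25, p = 1, m = 6, delta = 1.5,
                      informative_fraction = 0.5, seed = 23)
  )
  tab <- sim$bundle[[1]]
  specs <- build_model_zoo(list(selectors = c("anova", "mutinfo"),
                                classifiers = "logistic", selector_k = 3))
  reports <- run_model_zoo(specs, tab, folds = 3, seed = 4)
  ranked <- rank_models(reports)

  top1 <- select_top_k(ranked, 1, tab, seed = 4)
  expect_length(top1, 1)
  top_all <- select_top_k(ranked, length(ranked), tab, seed = 4)
  expect_length(top_all, length(ranked))
  expect_error(select_top_k(ranked, 0, tab), "positive")
  expect_error(select_top_k(ranked, 5, tab), "exceeds")

  scores <- predict_model(top1[[1]], tab)
  expect_true(all(scores >= 0 & scores <= 1))
})
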