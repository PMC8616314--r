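test_that("metrics match the rank AUC and brute-force concordance", {
  m <- compute_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(m$AUC, 0.75)

  perfect <- compute_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(perfect$AUC, 1)
  expect_equal(perfect$ACC, 1)

  expect_equal(compute_metrics(rep(0.7, 10), rep(c(0, 1), 5))$AUC, 0.5)

  # brute-force all-pairs oracle, with ties credited 0.5
  brute_auc <- function(scores, labels) {
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(55)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(compute_metrics(scores, labels)$AUC,
                 brute_auc(scores, labels))
  }

  # confusion identities at an explicit threshold
  ms <- compute_metrics(c(0.2, 0.6, 0.4, 0.9), c(0, 0, 1, 1), threshold = 0.5)
  expect_equal(ms$ACC, (ms$TP + ms$TN) / 4)
  expect_equal(ms$SEN, ms$TP / (ms$TP + ms$FN))
  expect_equal(ms$SPE, ms$TN / (ms$TN + ms$FP))
  expect_true(is.na(compute_metrics(c(0.1, 0.9), c(1, 1))$AUC))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  for (i in 1:5) {
    labels <- rbinom(80, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(80) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_metrics(scores, labels)$AUC, ref, tolerance = 1e-12)
  }
})

test_that("paired Wilcoxon flags degeneracy and detects shifts", {
  x <- rnorm(20)
  deg <- paired_wilcoxon(x, x)
  expect_true(deg$degenerate)
  expect_equal(deg$n_effective, 0L)

  shifted <- paired_wilcoxon(x + 1, x)
  expect_false(shifted$degenerate)
  expect_lt(shifted$p_value, 0.05)

  # under the null of symmetric noise, p > 0.05 in most replicates
  set.seed(66)
  ps <- replicate(20, paired_wilcoxon(rnorm(50), rnorm(50))$p_value)
  expect_gte(sum(ps > 0.05), 15)
})

test_that("VOI sweep bookkeeping, null cells, and signal cells behave", {
  set.seed(14)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  noise_tab <- function() make_table(matrix(rnorm(n * 6), n, 6), "A", y)
  signal <- matrix(rnorm(n * 6), n, 6)
  signal[, 1] <- signal[, 1] + 3 * y
  tables <- list(
    seqA = list(ET = make_table(signal, "A", y), pTE = noise_tab()),
    seqB = list(ET = noise_tab(), pTE = NULL)
  )
  specs <- tiny_zoo(c("anova", "mutinfo"), "logistic")
  sw <- voi_sweep(tables, specs = specs, folds = 3, seed = 2)

  # 3 present cells x 2 models x 3 folds records; absent cell reported
  expect_equal(nrow(sw$records), 3 * 2 * 3)
  expect_identical(sw$absent, "seqB:pTE")

  cells <- sw$cells
  auc_of <- function(sq, voi) cells$mean_auc[cells$sequence == sq & cells$voi == voi]
  expect_gt(auc_of("seqA", "ET"), auc_of("seqA", "pTE"))
  expect_gt(auc_of("seqA", "ET"), 0.85)
  expect_lt(abs(auc_of("seqB", "ET") - 0.5), 0.25)

  # cell means invariant to model evaluation order
  sw_rev <- voi_sweep(tables, specs = rev(specs), folds = 3, seed = 2)
  a <- sw_rev$cells[order(sw_rev$cells$sequence, sw_rev$cells$voi), ]
  b <- cells[order(cells$sequence, cells$voi), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("sequence sweep enumerates subsets and is consistent on singletons", {
  sim <- simulate_multimodal_features(
    simulation_config(n_per_class = 20, p = 2, m = 6, delta = 1.2,
                      informative_fraction = 0.5, mode = "disjoint", seed = 19)
  )
  specs <- tiny_zoo("anova", "logistic")
  sw <- sequence_sweep(sim$bundle, specs = specs, folds = 3, seed = 7)
  expect_identical(sort(unique(sw$records$subset)),
                   sort(c("mod1", "mod2", "mod1+mod2")))
  expect_equal(nrow(sw$records), 3 * 1 * 3)

  # singleton route equals the plain zoo on the same folds (deterministic spec)
  direct <- run_model_zoo(specs, sim$bundle[["mod1"]], folds = 3, seed = 7)
  expect_equal(sort(sw$records$auc[sw$records$subset == "mod1"]),
               sort(direct[[1]]$per_fold$auc))
})

test_that("reader comparison scores readers, MDT vote, and degeneracy", {
  set.seed(27)
  n <- 40
  labels <- rep(c(0, 1), each = n / 2)
  model_scores <- pmin(pmax(labels * 0.8 + runif(n, 0, 0.4), 0), 1)
  perfect <- labels
  flawed <- labels
  flawed[c(1, 2, 21, 22)] <- 1 - flawed[c(1, 2, 21, 22)]
  readers <- cbind(r1 = perfect, r2 = flawed, r3 = flawed)

  rc <- reader_comparison(model_scores, labels, readers, n_boot = 100, seed = 3)
  expect_equal(rc$readers$r1$AUC, 1)
  expect_equal(rc$readers$r1$ACC, 1)
  expect_equal(rc$mdt$ACC, rc$readers$r2$ACC)  # 2-of-3 vote follows the pair

  # three readers voting (1,1,0) on a sample -> MDT class 1
  expect_equal(majority_vote_predict(matrix(c(1, 1, 0), 1, 3)), 1L)

  # reader identical to the thresholded model -> degenerate comparison
  binary_model <- as.numeric(perfect)
  rc_deg <- reader_comparison(binary_model, labels,
                              cbind(r1 = perfect, r2 = perfect, r3 = perfect),
                              n_boot = 50, seed = 4)
  deg_rows <- rc_deg$comparisons[rc_deg$comparisons$opponent == "r1", ]
  expect_true(all(deg_rows$degenerate))

  expect_error(reader_comparison(model_scores[-1], labels, readers),
               "align")
})

test_that("top-feature frequency counts qualifying selections only", {
  fake_report <- function(auc, feats) {
    structure(list(spec = model_spec("anova", "logistic"), mean_auc = auc,
                   mean_acc = auc, acc_i = auc,
                   selected_features = feats),
              class = "cv_report")
  }
  reports <- list(
    fake_report(0.9, list(c("f1", "f2"), c("f1", "f3"))),
    fake_report(0.85, list(c("f1"), c("f2"))),
    fake_report(0.6, list(c("f9"), c("f9")))   # below the floor
  )
  freq <- top_feature_frequency(reports, auc_floor = 0.8)
  expect_equal(attr(freq, "qualifying_models"), 2L)
  expect_false("f9" %in% freq$feature)
  expect_equal(freq$count[freq$feature == "f1"], 3L)
  expect_true(all(diff(freq$count) <= 0))
  expect_equal(freq$rank, seq_len(nrow(freq)))

  empty <- top_feature_frequency(reports, auc_floor = 1.1)
  expect_equal(nrow(empty), 0)
})

test_that("class-mean midpoint analysis separates classes and counts ties below", {
  tab <- make_table(matrix(c(1, 2, 3, 5, 6, 7), 6, 1), "A",
                    labels = c(0, 0, 0, 1, 1, 1))
  res <- class_mean_threshold_analysis(tab)
  expect_equal(res$M, 4)
  expect_equal(res$pct_below_negative, 100)
  expect_equal(res$pct_above_positive, 100)
  expect_equal(res$pct_below_positive + res$pct_above_positive, 100)

  # identical class distributions: percentages near 50/50
  v <- rep(c(1, 2, 3, 4), 2)
  tab2 <- make_table(matrix(v, 8, 1), "A", labels = rep(c(0, 1), each = 4))
  res2 <- class_mean_threshold_analysis(tab2)
  expect_equal(res2$pct_below_positive, 50)

  # a value exactly at M counts as below
  tab3 <- make_table(matrix(c(0, 2, 2, 4), 4, 1), "A", labels = c(0, 0, 1, 1))
  res3 <- class_mean_threshold_analysis(tab3)  # M = 2
  expect_equal(res3$M, 2)
  expect_equal(res3$pct_below_positive, 50)    # the value 2 sits below
})

test_that("the fitted pipeline never reads held-out labels before scoring", {
  sc <- default_study_scenario(n_train = 40, n_test = 16)
  specs <- tiny_zoo(c("anova", "mutinfo"), "logistic")
  pipe <- fit_pipeline(sc$train, specs = specs, top_k = 2, folds = 3, seed = 9)
  pred <- predict_pipeline(pipe, sc$test)

  # poison the test labels: predictions must not move
  poisoned <- modality_bundle(lapply(sc$test, function(t) {
    feature_table(t$values, t$sample_ids, t$feature_names, t$modality_id,
                  labels = rep(1L, length(t$sample_ids)))
  }))
  pred_poisoned <- predict_pipeline(pipe, poisoned)
  expect_equal(pred_poisoned$score, pred$score)
})
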