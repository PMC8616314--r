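#' Build the model grid
#'
#' Cartesian product of the configured feature selectors and classifiers,
#' in deterministic order (selectors outer, classifiers inner). The default
#' configuration yields the fifteen-model grid: five selectors times three
#' classifiers.
#'
#' @param config A list with optional entries `selectors`, `classifiers`,
#'   `selector_k` (default 10), `hyperparameters`, `seed` (default 1).
#' @return A list of `model_spec` objects.
#' @export
#' @examples
#' length(build_model_zoo())  # 15
build_model_zoo <- function(config = list()) {
  selectors <- config$selectors %||% registered_selectors()
  classifiers <- config$classifiers %||% registered_classifiers()
  bad_sel <- setdiff(selectors, registered_selectors())
  if (length(bad_sel) > 0) {
    rf_stop(sprintf("unknown selector(s): %s; registered: %s",
                    paste(bad_sel, collapse = ", "),
                    paste(registered_selectors(), collapse = ", ")))
  }
  bad_clf <- setdiff(classifiers, registered_classifiers())
  if (length(bad_clf) > 0) {
    rf_stop(sprintf("unknown classifier(s): %s; registered: %s",
                    paste(bad_clf, collapse = ", "),
                    paste(registered_classifiers(), collapse = ", ")))
  }
  out <- list()
  for (s in selectors) {
    for (cl in classifiers) {
      out[[length(out) + 1]] <- model_spec(s, cl,
                                           selector_k = config$selector_k %||% 10,
                                           hyperparameters = config$hyperparameters %||% list(),
                                           seed = config$seed %||% 1)
    }
  }
  out
}

#' @rdname build_model_zoo
#' @param selector_id,classifier_id Registered ids.
#' @param selector_k Number of features the selector keeps (>= 1).
#' @param hyperparameters Named list passed to the classifier.
#' @param seed Integer seed.
#' @export
model_spec <- function(selector_id, classifier_id, selector_k = 10,
                       hyperparameters = list(), seed = 1) {
  if (!selector_id %in% registered_selectors()) {
    rf_stop(sprintf("unknown selector '%s'", selector_id))
  }
  if (!classifier_id %in% registered_classifiers()) {
    rf_stop(sprintf("unknown classifier '%s'", classifier_id))
  }
  stopifnot(selector_k >= 1)
  structure(
    list(selector_id = selector_id, classifier_id = classifier_id,
         selector_k = as.integer(selector_k),
         hyperparameters = hyperparameters, seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' Model spec identifier
#' @param spec A `model_spec`.
#' @return `"<selector>+<classifier>"`.
#' @export
spec_id <- function(spec) paste(spec$selector_id, spec$classifier_id, sep = "+")

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (k = %d)\n", spec_id(x), x$selector_k))
  invisible(x)
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin, keeping each fold's class ratio within 1 sample of global
stratified_folds <- function(labels, folds, seed) {
  if (folds < 2) rf_validation_error("need at least 2 folds")
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- sample(idx)
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

extract_xy <- function(table, labels = NULL) {
  stopifnot(inherits(table, "feature_table"))
  y <- labels %||% table$labels
  if (is.null(y)) rf_validation_error("labels are required")
  if (!is_binary01(y)) rf_validation_error("labels must be 0/1")
  list(x = table$values, y = as.integer(y))
}

# fit one spec (selector then classifier) on a training matrix
fit_spec <- function(spec, x, y, seed) {
  feats <- select_features(spec$selector_id, x, y,
                           k = min(spec$selector_k, ncol(x)),
                           seed = derive_seed(seed, paste0("sel_", spec$selector_id)))
  clf <- get_classifier(spec$classifier_id)
  model <- clf$fit(x[, feats, drop = FALSE], y, spec$hyperparameters,
                   derive_seed(seed, paste0("clf_", spec_id(spec))))
  structure(list(spec = spec, features = feats, model = model),
            class = "trained_model")
}

#' Class-1 probability of a trained model
#'
#' @param trained A `trained_model` (from [train_model()] or
#'   [select_top_k()]).
#' @param table A `feature_table` (or numeric matrix) carrying at least the
#'   model's selected features.
#' @return Numeric vector of class-1 scores in `[0, 1]`.
#' @export
predict_model <- function(trained, table) {
  stopifnot(inherits(trained, "trained_model"))
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  missing <- setdiff(trained$features, colnames(x))
  if (length(missing) > 0) {
    rf_validation_error(sprintf("missing feature(s) for prediction: %s",
                                paste(missing, collapse = ", ")))
  }
  clf <- get_classifier(trained$spec$classifier_id)
  clf$predict_prob(trained$model, x[, trained$features, drop = FALSE])
}

#' Train one model on a full cohort
#'
#' Runs the spec's feature selector on all supplied samples, then fits its
#' classifier on the selected features.
#'
#' @param spec A `model_spec`.
#' @param table A `feature_table` (fused or raw).
#' @param labels Binary labels; default: the table's own.
#' @param seed Seed (default: the spec's).
#' @return A `trained_model`.
#' @export
train_model <- function(spec, table, labels = NULL, seed = spec$seed) {
  xy <- extract_xy(table, labels)
  if (length(unique(xy$y)) < 2) rf_validation_error("both classes must be present")
  fit_spec(spec, xy$x, xy$y, seed)
}

#' Stratified k-fold cross-validation of one model
#'
#' For each fold, the feature selector is refit on the training folds only
#' (no leakage), the classifier is fit on the selected features, and the
#' held-out fold is scored. AUC uses the rank (Mann-Whitney) formulation;
#' ACC/SEN/SPE use the 0.5-thresholded confusion table.
#'
#' @param spec A `model_spec`.
#' @param table A `feature_table` (fused or raw).
#' @param labels Binary labels; default: the table's own.
#' @param folds Number of folds (default 5).
#' @param seed Seed controlling fold shuffling and stochastic learners.
#' @return A `cv_report`: per-fold metrics and selected features, plus
#'   aggregates (`mean_auc`, `mean_acc` alias `acc_i`, `sd_auc`, ...).
#' @export
run_stratified_cv <- function(spec, table, labels = NULL, folds = 5,
                              seed = spec$seed) {
  xy <- extract_xy(table, labels)
  if (length(unique(xy$y)) < 2) rf_validation_error("both classes must be present")
  fold_id <- stratified_folds(xy$y, folds, derive_seed(seed, "cv_folds"))
  cv_over_folds(spec, xy$x, xy$y, fold_id, seed)
}

# shared fold loop; fold_id is a precomputed assignment so that a whole zoo
# can be evaluated on identical folds
cv_over_folds <- function(spec, x, y, fold_id, seed,
                          selection_cache = NULL) {
  folds <- max(fold_id)
  fold_rows <- vector("list", folds)
  selected <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      rf_stop(sprintf("fold %d lacks a class after stratification", f))
    }
    cache_key <- paste(spec$selector_id, spec$selector_k, f, sep = "|")
    feats <- NULL
    if (!is.null(selection_cache)) feats <- selection_cache[[cache_key]]
    if (is.null(feats)) {
      feats <- select_features(
        spec$selector_id, x[tr, , drop = FALSE], y[tr],
        k = min(spec$selector_k, ncol(x)),
        seed = derive_seed(seed, paste0("sel_", spec$selector_id, "_f", f))
      )
      if (!is.null(selection_cache)) selection_cache[[cache_key]] <- feats
    }
    clf <- get_classifier(spec$classifier_id)
    model <- clf$fit(x[tr, feats, drop = FALSE], y[tr], spec$hyperparameters,
                     derive_seed(seed, paste0("clf_", spec_id(spec), "_f", f)))
    scores <- clf$predict_prob(model, x[te, feats, drop = FALSE])
    ms <- compute_metrics(scores, y[te])
    fold_rows[[f]] <- data.frame(fold = f, auc = ms$AUC, acc = ms$ACC,
                                 sen = ms$SEN, spe = ms$SPE)
    selected[[f]] <- feats
  }
  per_fold <- do.call(rbind, fold_rows)
  structure(
    list(
      spec = spec,
      per_fold = per_fold,
      selected_features = selected,
      mean_auc = mean(per_fold$auc), sd_auc = stats::sd(per_fold$auc),
      mean_acc = mean(per_fold$acc), sd_acc = stats::sd(per_fold$acc),
      mean_sen = mean(per_fold$sen), mean_spe = mean(per_fold$spe),
      acc_i = mean(per_fold$acc)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: AUC %.3f (sd %.3f), ACC %.3f over %d folds\n",
              spec_id(x$spec), x$mean_auc, x$sd_auc, x$mean_acc,
              nrow(x$per_fold)))
  invisible(x)
}

#' Cross-validate a whole model grid on shared folds
#'
#' All specs are evaluated on the identical stratified fold assignment;
#' per-fold feature selections are cached per selector so a selector paired
#' with several classifiers is only run once per fold.
#'
#' @param specs List of `model_spec` (default: the full 15-model grid).
#' @param table A `feature_table`.
#' @param labels Binary labels; default: the table's own.
#' @param folds Number of folds (default 5).
#' @param seed Seed shared by the grid.
#' @return List of `cv_report`, one per spec, in input order.
#' @export
run_model_zoo <- function(specs = build_model_zoo(), table, labels = NULL,
                          folds = 5, seed = 1) {
  xy <- extract_xy(table, labels)
  fold_id <- stratified_folds(xy$y, folds, derive_seed(seed, "cv_folds"))
  cache <- new.env(parent = emptyenv())
  lapply(specs, function(spec) {
    cv_over_folds(spec, xy$x, xy$y, fold_id, seed, selection_cache = cache)
  })
}

#' Rank cross-validated models
#'
#' Sorted by mean AUC descending; ties broken by mean accuracy, then by
#' spec id lexicographically, so the ranking is invariant to input order.
#'
#' @param reports List of `cv_report`.
#' @return The reports, reordered.
#' @export
rank_models <- function(reports) {
  stopifnot(length(reports) >= 1)
  auc <- vapply(reports, `[[`, numeric(1), "mean_auc")
  acc <- vapply(reports, `[[`, numeric(1), "mean_acc")
  ids <- vapply(reports, function(r) spec_id(r$spec), character(1))
  reports[order(-auc, -acc, ids)]
}

#' Screen the top-k models and refit on the full cohort
#'
#' Takes the first `k` of a ranked report list and refits each
#' (selector + classifier) on all supplied training samples for deployment.
#'
#' @param ranked Ranked list of `cv_report` (see [rank_models()]).
#' @param k Number of models to keep (default 3).
#' @param table Training `feature_table` for the refit.
#' @param labels Binary labels; default: the table's own.
#' @param seed Seed for the refits.
#' @return List of `k` `trained_model` objects; each carries its
#'   cross-validated report in `$cv_report`.
#' @export
select_top_k <- function(ranked, k = 3, table, labels = NULL, seed = 1) {
  if (k <= 0) rf_stop("k must be positive")
  if (k > length(ranked)) rf_stop("k exceeds the number of ranked models")
  lapply(ranked[seq_len(k)], function(report) {
    tm <- train_model(report$spec, table, labels,
                      seed = derive_seed(seed, paste0("refit_", spec_id(report$spec))))
    tm$cv_report <- report
    tm
  })
}
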