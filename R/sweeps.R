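# Evaluation harnesses: VOI sweep (which tumor sub-volume discriminates
# best), sequence-combination sweep (which fused sequence subset wins),
# reader comparison, top-feature frequency, and class-mean thresholds.

#' Sweep feature tables over a (sequence, VOI) grid
#'
#' For every grid cell, all supplied models are evaluated by stratified
#' k-fold cross-validation on that cell's single feature table (no fusion),
#' and the fold-level AUCs are recorded. The report aggregates the mean AUC
#' over models and folds per cell. Missing cells are reported as absent,
#' not errors.
#'
#' @param tables A nested named list `tables[[sequence]][[voi]]` of
#'   `feature_table` objects (NULL entries allowed).
#' @param labels Binary labels shared by all cells (default: taken from
#'   each table).
#' @param specs Model grid (default: the full fifteen-model grid).
#' @param folds CV folds (default 5).
#' @param seed Seed.
#' @return An object of class `sweep_report`: `records` (long data frame
#'   sequence/voi/model/fold/auc) and `cells` (mean AUC per cell).
#' @export
voi_sweep <- function(tables, labels = NULL, specs = build_model_zoo(),
                      folds = 5, seed = 1) {
  stopifnot(is.list(tables), length(tables) >= 1)
  records <- list()
  absent <- character(0)
  for (sq in names(tables)) {
    for (voi in names(tables[[sq]])) {
      tab <- tables[[sq]][[voi]]
      if (is.null(tab)) {
        absent <- c(absent, paste(sq, voi, sep = ":"))
        next
      }
      reports <- run_model_zoo(specs, tab, labels, folds = folds,
                               seed = derive_seed(seed, paste(sq, voi)))
      for (r in reports) {
        records[[length(records) + 1]] <- data.frame(
          sequence = sq, voi = voi, model = spec_id(r$spec),
          fold = r$per_fold$fold, auc = r$per_fold$auc
        )
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(sequence = character(0), voi = character(0),
               model = character(0), fold = integer(0), auc = numeric(0))
  cells <- stats::aggregate(auc ~ sequence + voi, data = records, FUN = mean)
  names(cells)[names(cells) == "auc"] <- "mean_auc"
  structure(list(records = records, cells = cells, absent = absent,
                 axis = "voi"),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> %d cells, %d fold-level records\n",
              nrow(x$cells), nrow(x$records)))
  print(x$cells)
  invisible(x)
}

#' Sweep all sequence combinations through the fusion pipeline
#'
#' Enumerates every subset of the bundle's modalities (singletons, pairs,
#' triples, quadruple). Singleton subsets evaluate the raw per-sequence
#' table; subsets of two or more refit the fusion transform inside each CV
#' training fold and apply it to the fold's held-out split, honoring the
#' train/test separation at cross-validation scale. Every subset is scored
#' by the full model grid on shared folds.
#'
#' @param bundle A [modality_bundle()] (2-4 modalities).
#' @param labels Binary labels (default: the bundle's).
#' @param specs Model grid (default: the full fifteen-model grid).
#' @param folds CV folds (default 5).
#' @param seed Seed.
#' @param tol Fusion eigenvalue tolerance.
#' @return A `sweep_report` whose axis is the modality subset (label
#'   `"A+B"`).
#' @export
sequence_sweep <- function(bundle, labels = NULL, specs = build_model_zoo(),
                           folds = 5, seed = 1, tol = 1e-10) {
  stopifnot(inherits(bundle, "modality_bundle"))
  labels <- labels %||% bundle_labels(bundle)
  if (is.null(labels)) rf_validation_error("labels are required")
  y <- as.integer(labels)
  subsets <- enumerate_sequence_combinations(names(bundle))
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "cv_folds"))
  records <- list()
  for (subset in subsets) {
    label <- paste(subset, collapse = "+")
    # fused (or raw) train/test matrices per fold
    fold_data <- lapply(seq_len(folds), function(f) {
      tr_ids <- bundle[[1]]$sample_ids[fold_id != f]
      te_ids <- bundle[[1]]$sample_ids[fold_id == f]
      if (length(subset) == 1) {
        tab <- bundle[[subset]]
        tr_idx <- match(tr_ids, tab$sample_ids)
        te_idx <- match(te_ids, tab$sample_ids)
        list(xtr = tab$values[tr_idx, , drop = FALSE],
             xte = tab$values[te_idx, , drop = FALSE])
      } else {
        btr <- subset_bundle(bundle, sample_ids = tr_ids, modalities = subset)
        bte <- subset_bundle(bundle, sample_ids = te_ids, modalities = subset)
        fit <- fit_feature_fusion(btr, labels = y[fold_id != f], tol = tol)
        list(xtr = fit$fused$values,
             xte = apply_feature_fusion(fit$transform, bte)$values)
      }
    })
    cache <- new.env(parent = emptyenv())
    for (spec in specs) {
      for (f in seq_len(folds)) {
        ytr <- y[fold_id != f]
        yte <- y[fold_id == f]
        key <- paste(spec$selector_id, spec$selector_k, f, sep = "|")
        feats <- cache[[key]]
        if (is.null(feats)) {
          feats <- select_features(
            spec$selector_id, fold_data[[f]]$xtr, ytr,
            k = min(spec$selector_k, ncol(fold_data[[f]]$xtr)),
            seed = derive_seed(seed, paste0(label, "_sel_", spec$selector_id, "_f", f))
          )
          cache[[key]] <- feats
        }
        clf <- get_classifier(spec$classifier_id)
        model <- clf$fit(fold_data[[f]]$xtr[, feats, drop = FALSE], ytr,
                         spec$hyperparameters,
                         derive_seed(seed, paste0(label, "_clf_", spec_id(spec), "_f", f)))
        scores <- clf$predict_prob(model, fold_data[[f]]$xte[, feats, drop = FALSE])
        ms <- compute_metrics(scores, yte)
        records[[length(records) + 1]] <- data.frame(
          subset = label, size = length(subset), model = spec_id(spec),
          fold = f, auc = ms$AUC
        )
      }
    }
  }
  records <- do.call(rbind, records)
  cells <- stats::aggregate(auc ~ subset + size, data = records, FUN = mean)
  names(cells)[names(cells) == "auc"] <- "mean_auc"
  cells <- cells[order(cells$size, cells$subset), ]
  rownames(cells) <- NULL
  structure(list(records = records, cells = cells, absent = character(0),
                 axis = "sequence_subset"),
            class = "sweep_report")
}

#' Compare a model against human readers
#'
#' Computes a metric set per reader, the MDT plurality vote over readers,
#' and paired Wilcoxon signed-rank comparisons of model vs. reader metrics
#' over stratified bootstrap resamples of the test cohort (the resampling
#' provides the pairing on a single test set; resampling is stratified by
#' class so AUC stays defined in every replicate).
#'
#' @param model_scores Numeric class-1 scores of the model on the test set.
#' @param labels True binary labels.
#' @param readers A samples x readers matrix (or data frame) of predicted
#'   classes in `{0, 1}`, rows aligned with `labels`. Column names identify
#'   readers.
#' @param threshold Model decision threshold (default 0.5).
#' @param n_boot Bootstrap replicates for the paired comparison
#'   (default 2000).
#' @param seed Seed.
#' @return A list: `model` (metric_set), `readers` (list of metric_set),
#'   `mdt` (metric_set of the plurality vote), `comparisons` (data frame of
#'   Wilcoxon p-values per opponent and metric, with degenerate flags).
#' @export
reader_comparison <- function(model_scores, labels, readers, threshold = 0.5,
                              n_boot = 2000, seed = 1) {
  readers <- as.matrix(readers)
  n <- length(labels)
  if (nrow(readers) != n || length(model_scores) != n) {
    rf_validation_error("readers and model scores must align with labels")
  }
  if (is.null(colnames(readers))) {
    colnames(readers) <- paste0("reader_", seq_len(ncol(readers)))
  }
  model_metrics <- compute_metrics(model_scores, labels, threshold)
  reader_metrics <- lapply(seq_len(ncol(readers)), function(j) {
    compute_metrics(readers[, j], labels, threshold = 0.5)
  })
  names(reader_metrics) <- colnames(readers)
  mdt_votes <- majority_vote_predict(readers)
  mdt_metrics <- compute_metrics(mdt_votes, labels, threshold = 0.5)

  opponents <- c(as.list(as.data.frame(readers)),
                 list(MDT = mdt_votes))
  metric_names <- c("AUC", "ACC", "SEN", "SPE")
  set.seed(derive_seed(seed, "reader_boot"))
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels != 1)
  boot_idx <- replicate(n_boot, c(sample(idx_pos, replace = TRUE),
                                  sample(idx_neg, replace = TRUE)),
                        simplify = FALSE)
  metric_series <- function(scores, thr) {
    vapply(boot_idx, function(ii) {
      m <- compute_metrics(scores[ii], labels[ii], thr)
      c(m$AUC, m$ACC, m$SEN, m$SPE)
    }, numeric(4))
  }
  model_series <- metric_series(model_scores, threshold)
  rows <- list()
  for (op in names(opponents)) {
    op_series <- metric_series(opponents[[op]], 0.5)
    for (k in seq_along(metric_names)) {
      cmp <- paired_wilcoxon(model_series[k, ], op_series[k, ])
      rows[[length(rows) + 1]] <- data.frame(
        opponent = op, metric = metric_names[k],
        p_value = cmp$p_value, degenerate = cmp$degenerate
      )
    }
  }
  list(model = model_metrics, readers = reader_metrics, mdt = mdt_metrics,
       comparisons = do.call(rbind, rows))
}

#' Frequency of selected features across qualifying models
#'
#' Counts, over all cross-validated models whose mean AUC exceeds
#' `auc_floor`, how often each feature was selected (across folds), ranked
#' descending with a stable tie-break by feature name.
#'
#' @param reports List of `cv_report` carrying per-fold selected features.
#' @param auc_floor Qualification floor on mean AUC (strict `>`;
#'   default 0.8).
#' @return A data frame `feature`, `count`, `rank`; attribute
#'   `qualifying_models` records the rule's outcome.
#' @export
top_feature_frequency <- function(reports, auc_floor = 0.8) {
  qualifying <- Filter(function(r) r$mean_auc > auc_floor, reports)
  counts <- table(unlist(lapply(qualifying, function(r) {
    unlist(r$selected_features)
  })))
  if (length(counts) == 0) {
    out <- data.frame(feature = character(0), count = integer(0),
                      rank = integer(0))
  } else {
    df <- data.frame(feature = names(counts), count = as.integer(counts),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$feature), ]
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    out <- df
  }
  attr(out, "qualifying_models") <- length(qualifying)
  attr(out, "auc_floor") <- auc_floor
  out
}

#' Class-mean midpoint threshold analysis
#'
#' For each feature, M is the midpoint of the two class means; the report
#' gives, per class, the percentage of samples below and above M. A value
#' exactly equal to M is counted as below. With well-separated classes the
#' positive class sits almost entirely on one side of M.
#'
#' @param table A `feature_table`.
#' @param labels Binary labels (default: the table's).
#' @param features Optional subset of feature names (default: all).
#' @param positive_class Positive label (default 1).
#' @return A data frame with one row per feature: class means, `M`, and
#'   percentage below/above per class (percentages sum to 100 within
#'   class).
#' @export
class_mean_threshold_analysis <- function(table, labels = NULL,
                                          features = NULL,
                                          positive_class = 1) {
  xy <- extract_xy(table, labels)
  if (length(unique(xy$y)) < 2) rf_validation_error("both classes must be present")
  features <- features %||% colnames(xy$x)
  missing <- setdiff(features, colnames(xy$x))
  if (length(missing) > 0) {
    rf_validation_error(sprintf("unknown feature(s): %s",
                                paste(missing, collapse = ", ")))
  }
  pos <- xy$y == positive_class
  rows <- lapply(features, function(f) {
    v <- xy$x[, f]
    m1 <- mean(v[pos])
    m0 <- mean(v[!pos])
    M <- (m1 + m0) / 2
    data.frame(
      feature = f,
      mean_positive = m1, mean_negative = m0, M = M,
      pct_below_positive = 100 * mean(v[pos] <= M),
      pct_above_positive = 100 * mean(v[pos] > M),
      pct_below_negative = 100 * mean(v[!pos] <= M),
      pct_above_negative = 100 * mean(v[!pos] > M),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
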