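# Feature-selection methods for the model grid. Each selector scores every
# feature on the training split only and returns the names of the top k.
# Registered by id; the default grid uses all five.

# two-class one-way ANOVA F statistic per feature, vectorized
anova_f_scores <- function(x, y) {
  n <- nrow(x)
  g1 <- y == 1
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  mg <- colMeans(x)
  ssb <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ssw <- colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2, m0)^2)
  f <- (ssb / 1) / (ssw / pmax(n - 2, 1))
  f[!is.finite(f)] <- 0
  f
}

# mutual information with the class label after equal-frequency binning
mutual_info_scores <- function(x, y, bins = 8) {
  n <- nrow(x)
  py <- table(factor(y, levels = c(0, 1))) / n
  apply(x, 2, function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(0)
    b <- cut(v, breaks = br, include.lowest = TRUE)
    joint <- table(b, factor(y, levels = c(0, 1))) / n
    px <- rowSums(joint)
    mi <- 0
    for (i in seq_along(px)) {
      for (j in 1:2) {
        if (joint[i, j] > 0) {
          mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
        }
      }
    }
    mi
  })
}

# ReliefF for a binary outcome: accumulate, over every sample, the
# difference between mean feature distance to the k nearest misses and to
# the k nearest hits (features scaled to [0,1] first)
relieff_scores <- function(x, y, k_neighbors = 10) {
  n <- nrow(x)
  rng <- apply(x, 2, function(v) {
    r <- max(v) - min(v)
    if (r <= 0) 1 else r
  })
  xs <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, `/`)
  d <- as.matrix(stats::dist(xs))
  diag(d) <- Inf
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    diff <- which(y != y[i])
    same <- same[same != i]
    if (length(same) == 0 || length(diff) == 0) next
    hits <- same[order(d[i, same])][seq_len(min(k_neighbors, length(same)))]
    misses <- diff[order(d[i, diff])][seq_len(min(k_neighbors, length(diff)))]
    dh <- colMeans(abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ])))
    dm <- colMeans(abs(sweep(xs[misses, , drop = FALSE], 2, xs[i, ])))
    w <- w + (dm - dh)
  }
  w / n
}

# rank features by how early they enter the L1-regularized logistic path
# (ties broken by absolute coefficient size at the densest lambda)
l1_logistic_scores <- function(x, y, seed = 1) {
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  scores <- rep(-Inf, ncol(x))
  if (sum(keep) >= 2) {
    set.seed(seed)
    fit <- glmnet::glmnet(x[, keep, drop = FALSE], factor(y),
                          family = "binomial", nlambda = 60)
    beta <- as.matrix(fit$beta)
    entry <- apply(beta, 1, function(b) {
      nz <- which(abs(b) > 0)
      if (length(nz) == 0) Inf else nz[1]
    })
    last <- abs(beta[, ncol(beta)])
    scores[keep] <- -entry + last / (max(last) + 1) # earlier entry = higher
  }
  scores
}

# minimum-redundancy-maximum-relevance: greedy forward selection with
# binned mutual information as relevance and mean absolute Pearson
# correlation with already-selected features as redundancy
mrmr_select <- function(x, y, k) {
  rel <- mutual_info_scores(x, y)
  m <- ncol(x)
  selected <- integer(0)
  remaining <- seq_len(m)
  cx <- suppressWarnings(stats::cor(x))
  cx[!is.finite(cx)] <- 0
  for (step in seq_len(min(k, m))) {
    if (length(selected) == 0) {
      score <- rel[remaining]
    } else {
      red <- rowMeans(abs(cx[remaining, selected, drop = FALSE]))
      score <- rel[remaining] - red
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

top_k_by_score <- function(scores, feature_names, k) {
  ord <- order(scores, decreasing = TRUE)
  feature_names[ord[seq_len(min(k, length(ord)))]]
}

.selector_registry <- list(
  anova = function(x, y, k, seed) top_k_by_score(anova_f_scores(x, y), colnames(x), k),
  mutinfo = function(x, y, k, seed) top_k_by_score(mutual_info_scores(x, y), colnames(x), k),
  relieff = function(x, y, k, seed) top_k_by_score(relieff_scores(x, y), colnames(x), k),
  l1logistic = function(x, y, k, seed) top_k_by_score(l1_logistic_scores(x, y, seed), colnames(x), k),
  mrmr = function(x, y, k, seed) colnames(x)[mrmr_select(x, y, k)]
)

#' Registered feature selectors and classifiers
#'
#' The default model grid is the Cartesian product of five feature
#' selection methods (`anova`, `mutinfo`, `relieff`, `l1logistic`, `mrmr`)
#' and three classifiers (`logistic`, `svm_rbf`, `random_forest`),
#' giving fifteen models.
#'
#' @return Character vector of registered ids.
#' @export
registered_selectors <- function() names(.selector_registry)

#' Run a registered selector
#'
#' @param selector_id One of [registered_selectors()].
#' @param x Numeric training matrix (samples x features, named columns).
#' @param y Binary labels (0/1).
#' @param k Number of features to keep.
#' @param seed Integer seed for stochastic selectors.
#' @return Character vector of selected feature names (length `<= k`).
#' @export
select_features <- function(selector_id, x, y, k, seed = 1) {
  fn <- .selector_registry[[selector_id]]
  if (is.null(fn)) {
    rf_stop(sprintf("unknown selector '%s'; registered: %s", selector_id,
                    paste(registered_selectors(), collapse = ", ")))
  }
  stopifnot(k >= 1)
  fn(x, y, k, seed)
}
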