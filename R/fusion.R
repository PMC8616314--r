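# Level-1 fusion: for each radiomics feature, the values observed across
# the p MRI sequences form a p x n matrix X. The between-class scatter of
# X's columns is whitened to a transformation W (W' S W = I), and W' X
# compresses X to a single fused row per feature. With two classes S has
# rank <= 1, so each feature fuses to exactly one value per sample.

#' Between-class scatter of a cross-modality feature matrix
#'
#' For a p x n matrix `x` (rows = modalities, columns = samples) with binary
#' class labels, computes `S = sum_i n_i (xbar_i - xbar)(xbar_i - xbar)'`
#' where `xbar_i` is the class-i column mean and `xbar` the grand mean over
#' all n columns.
#'
#' @param x Numeric p x n matrix for one feature (p modalities, n samples).
#' @param labels Binary labels (0/1), length n; both classes must be present.
#' @return An object of class `scatter_matrix`: list with `S` (p x p),
#'   `class_sizes`, `class_means` (p x 2 matrix, columns named by class),
#'   `grand_mean`.
#' @export
#' @examples
#' x <- rbind(c(1, 1, 3, 3), c(0, 2, 2, 4))
#' between_class_scatter(x, c(0, 0, 1, 1))$S   # [[4,4],[4,4]]
between_class_scatter <- function(x, labels) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (length(labels) != n) rf_validation_error("labels length must equal ncol(x)")
  if (!is_binary01(labels)) rf_validation_error("labels must be 0/1")
  classes <- sort(unique(labels))
  if (length(classes) < 2) rf_validation_error("both classes must be present")
  grand <- rowMeans(x)
  p <- nrow(x)
  S <- matrix(0, p, p)
  class_means <- matrix(NA_real_, p, length(classes),
                        dimnames = list(rownames(x), as.character(classes)))
  class_sizes <- integer(length(classes))
  for (i in seq_along(classes)) {
    idx <- labels == classes[i]
    ni <- sum(idx)
    mi <- rowMeans(x[, idx, drop = FALSE])
    d <- mi - grand
    S <- S + ni * tcrossprod(d)
    class_means[, i] <- mi
    class_sizes[i] <- ni
  }
  structure(
    list(S = S, class_sizes = class_sizes, class_means = class_means,
         grand_mean = grand, classes = classes),
    class = "scatter_matrix"
  )
}

#' Whiten (unitize) a between-class scatter matrix
#'
#' Eigendecomposes `S = Q L Q'`, retains eigenpairs with eigenvalue above
#' `tol` relative to the largest, and returns `W = Q_r L_r^{-1/2}` so that
#' `W' S W = I_r`. With two classes `S` has rank at most 1, so `r = 1` and
#' `W' X` is a single row. If no eigenpair survives (zero between-class
#' scatter) the transform is degenerate and falls back to the uniform
#' average column `W = (1/sqrt(p)) * 1`, so the feature is retained rather
#' than dropped.
#'
#' @param S A p x p symmetric positive-semidefinite matrix, or a
#'   `scatter_matrix`.
#' @param tol Relative eigenvalue retention threshold (default `1e-10`).
#' @return List with `W` (p x r), `eigenvalues` (the retained ones),
#'   `degenerate` flag.
#' @export
#' @examples
#' u <- unitize_scatter(matrix(4, 2, 2))
#' u$W                      # (0.25, 0.25)
#' t(u$W) %*% matrix(4, 2, 2) %*% u$W   # identity
unitize_scatter <- function(S, tol = 1e-10) {
  if (inherits(S, "scatter_matrix")) S <- S$S
  S <- as.matrix(S)
  p <- nrow(S)
  if (ncol(S) != p) rf_validation_error("S must be square")
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8 * max(1, max(abs(S)))) {
    rf_validation_error("S is not symmetric within tolerance")
  }
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  keep <- e$values > tol * max(lmax, .Machine$double.eps)
  if (!any(keep)) {
    return(list(W = matrix(1 / sqrt(p), p, 1), eigenvalues = numeric(0),
                degenerate = TRUE))
  }
  vals <- e$values[keep]
  W <- e$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(vals), length(vals))
  list(W = W, eigenvalues = vals, degenerate = FALSE)
}

#' Fit the cross-modality feature fusion on training data
#'
#' For each of the m features: assembles the p x n cross-modality matrix
#' from the (z-scored) bundle, computes the between-class scatter, whitens
#' it to `W`, and stores the fused row `W' X`. Rows are stacked into the
#' fused m x n feature matrix, returned as a regular feature table (one
#' fused value per feature per sample). `W` is sign-oriented so that the
#' positive class has the larger fused mean, making outputs deterministic
#' across eigensolvers.
#'
#' @param bundle A [modality_bundle()] with p >= 2 modalities (training
#'   samples).
#' @param labels Binary labels; defaults to the labels carried by the bundle.
#' @param registry Optional [feature_registry()]; if given, every member
#'   table must match it exactly.
#' @param tol Eigenvalue retention tolerance, see [unitize_scatter()].
#' @param positive_class Label treated as positive (default 1).
#' @param standardize Fit a per-(modality, feature) z-scoring on these
#'   samples and store it in the transform (default `TRUE`).
#' @return A list with `transform` (class `fusion_transform`) and `fused`
#'   (class `fused_feature_table`, also a `feature_table`).
#' @export
fit_feature_fusion <- function(bundle, labels = NULL, registry = NULL,
                               tol = 1e-10, positive_class = 1,
                               standardize = TRUE) {
  stopifnot(inherits(bundle, "modality_bundle"))
  if (length(bundle) < 2) rf_validation_error("fusion requires at least 2 modalities")
  labels <- labels %||% bundle_labels(bundle)
  if (is.null(labels)) rf_validation_error("labels are required to fit the fusion")
  if (!is_binary01(labels) || length(unique(labels)) < 2) {
    rf_validation_error("labels must be 0/1 with both classes present")
  }
  if (!is.null(registry)) {
    for (t in bundle) validate_against_registry(t, registry, strict = TRUE)
  }
  std <- NULL
  zb <- bundle
  if (standardize) {
    std <- fit_standardizer(bundle)
    zb <- apply_standardizer(std, bundle)
  }
  feature_names <- zb[[1]]$feature_names
  sample_ids <- zb[[1]]$sample_ids
  p <- length(zb)
  m <- length(feature_names)
  n <- length(sample_ids)
  # p x n slab per feature: mods[[k]]$values is n x m
  vals <- lapply(zb, `[[`, "values")
  W_mat <- matrix(NA_real_, p, m, dimnames = list(names(zb), feature_names))
  eigenvalues <- rep(NA_real_, m)
  degenerate <- logical(m)
  fused <- matrix(NA_real_, m, n, dimnames = list(feature_names, sample_ids))
  pos <- labels == positive_class
  for (j in seq_len(m)) {
    X <- do.call(rbind, lapply(vals, function(v) v[, j]))
    sc <- between_class_scatter(X, labels)
    u <- unitize_scatter(sc, tol = tol)
    w <- u$W[, 1]
    row <- drop(crossprod(w, X))
    if (mean(row[pos]) < mean(row[!pos])) {
      w <- -w
      row <- -row
    }
    W_mat[, j] <- w
    eigenvalues[j] <- if (u$degenerate) 0 else u$eigenvalues[1]
    degenerate[j] <- u$degenerate
    fused[j, ] <- row
  }
  if (all(degenerate)) {
    warning("all features have zero between-class scatter; fusion is degenerate",
            call. = FALSE)
  }
  transform <- structure(
    list(W = W_mat, eigenvalues = eigenvalues, degenerate = degenerate,
         standardizer = std, modality_order = names(zb),
         feature_names = feature_names, positive_class = positive_class,
         tol = tol),
    class = "fusion_transform"
  )
  fused_table <- feature_table(t(fused), sample_ids, feature_names,
                               paste(names(zb), collapse = "+"),
                               labels = labels)
  attr(fused_table, "provenance") <- list(
    modalities = names(zb), tol = tol,
    degenerate_features = feature_names[degenerate]
  )
  class(fused_table) <- c("fused_feature_table", class(fused_table))
  list(transform = transform, fused = fused_table)
}

#' @export
print.fusion_transform <- function(x, ...) {
  cat(sprintf(
    "<fusion_transform> %d modalities [%s] -> %d fused features (%d degenerate)\n",
    length(x$modality_order), paste(x$modality_order, collapse = ", "),
    length(x$feature_names), sum(x$degenerate)
  ))
  invisible(x)
}

#' Apply a fitted fusion transform to new data
#'
#' Standardizes the bundle with the statistics stored at training time and
#' projects with the stored `W`; nothing is refitted. The bundle's modality
#' order and feature names must match the transform exactly (no silent
#' reordering). Labels are not needed; a single held-out sample works.
#'
#' @param transform A `fusion_transform` from [fit_feature_fusion()].
#' @param bundle A [modality_bundle()] with matching modalities and features.
#' @return A `fused_feature_table`.
#' @export
apply_feature_fusion <- function(transform, bundle) {
  stopifnot(inherits(transform, "fusion_transform"),
            inherits(bundle, "modality_bundle"))
  if (!identical(names(bundle), transform$modality_order)) {
    rf_validation_error(sprintf(
      "modality order mismatch: transform has [%s], bundle has [%s]",
      paste(transform$modality_order, collapse = ", "),
      paste(names(bundle), collapse = ", ")
    ))
  }
  if (!identical(bundle[[1]]$feature_names, transform$feature_names)) {
    rf_validation_error("feature names do not match the fitted transform")
  }
  zb <- bundle
  if (!is.null(transform$standardizer)) {
    zb <- apply_standardizer(transform$standardizer, bundle)
  }
  vals <- lapply(zb, `[[`, "values")
  n <- length(zb[[1]]$sample_ids)
  m <- length(transform$feature_names)
  fused <- matrix(NA_real_, n, m,
                  dimnames = list(zb[[1]]$sample_ids, transform$feature_names))
  for (j in seq_len(m)) {
    X <- do.call(rbind, lapply(vals, function(v) v[, j]))
    fused[, j] <- drop(crossprod(transform$W[, j], X))
  }
  out <- feature_table(fused, zb[[1]]$sample_ids, transform$feature_names,
                       paste(names(zb), collapse = "+"),
                       labels = bundle_labels(bundle))
  attr(out, "provenance") <- list(
    modalities = names(zb), tol = transform$tol,
    degenerate_features = transform$feature_names[transform$degenerate]
  )
  class(out) <- c("fused_feature_table", class(out))
  out
}

#' Enumerate sequence combinations for fusion
#'
#' With 4 sequences there are 15 feature types: 4 singletons, 6 pairs,
#' 4 triples and the quadruple, ordered singles first, then pairs, triples,
#' quadruple (each block in lexicographic combination order).
#'
#' @param modality_ids Character vector of distinct modality ids (2 to 4).
#' @return A list of character vectors (subsets).
#' @export
#' @examples
#' length(enumerate_sequence_combinations(c("T1WI", "CE_T1WI", "T2WI", "T2_FLAIR")))
enumerate_sequence_combinations <- function(modality_ids) {
  if (anyDuplicated(modality_ids)) rf_validation_error("modality ids must be distinct")
  p <- length(modality_ids)
  if (p < 2 || p > 4) rf_validation_error("need between 2 and 4 modality ids")
  out <- list()
  for (k in seq_len(p)) {
    cmb <- utils::combn(modality_ids, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
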