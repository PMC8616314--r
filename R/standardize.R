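#' Fit a per-modality, per-feature standardizer
#'
#' Learns location (mean) and scale (sample standard deviation) for every
#' (modality, feature) pair on a training subset only. The cross-modality
#' scatter fusion is scale sensitive, so features are z-scored per modality
#' before fusion; the fitted statistics travel with the fusion transform so
#' that held-out data are standardized with training statistics and never
#' refitted.
#'
#' Features with zero training variance keep their location but get scale 1
#' and are flagged (they are retained, not dropped, so registry alignment
#' across modalities is preserved).
#'
#' @param bundle A [modality_bundle()].
#' @param sample_ids Optional subset of sample ids to learn from (default:
#'   all samples in the bundle). At least 2 samples are required.
#' @return An object of class `standardizer`: per modality a list with
#'   `location`, `scale`, and `zero_variance` (logical per feature).
#' @export
fit_standardizer <- function(bundle, sample_ids = NULL) {
  stopifnot(inherits(bundle, "modality_bundle"))
  if (is.null(sample_ids)) sample_ids <- bundle[[1]]$sample_ids
  if (length(sample_ids) < 2) rf_validation_error("need at least 2 samples to fit a standardizer")
  stats_per_mod <- lapply(bundle, function(t) {
    idx <- match(sample_ids, t$sample_ids)
    if (anyNA(idx)) rf_validation_error("standardizer subset contains unknown sample ids")
    v <- t$values[idx, , drop = FALSE]
    location <- colMeans(v)
    scale <- apply(v, 2, stats::sd)
    zero_variance <- scale <= 0 | !is.finite(scale)
    if (any(zero_variance)) {
      warning(sprintf(
        "modality '%s': %d zero-variance feature(s) flagged; scale set to 1",
        t$modality_id, sum(zero_variance)
      ), call. = FALSE)
      scale[zero_variance] <- 1
    }
    list(location = location, scale = scale, zero_variance = zero_variance)
  })
  structure(
    list(per_modality = stats_per_mod,
         modality_order = names(bundle),
         feature_names = bundle[[1]]$feature_names,
         n_fit = length(sample_ids)),
    class = "standardizer"
  )
}

#' Apply a fitted standardizer
#'
#' Transforms every value to `(value - location) / scale` using the stored
#' training statistics. Sample order is unchanged. Every (modality, feature)
#' of the bundle must have been seen at fit time.
#'
#' @param std A `standardizer` from [fit_standardizer()].
#' @param bundle A [modality_bundle()].
#' @return A standardized `modality_bundle`.
#' @export
apply_standardizer <- function(std, bundle) {
  stopifnot(inherits(std, "standardizer"), inherits(bundle, "modality_bundle"))
  missing_mod <- setdiff(names(bundle), names(std$per_modality))
  if (length(missing_mod) > 0) {
    rf_validation_error(sprintf("standardizer has no statistics for modality: %s",
                                paste(missing_mod, collapse = ", ")))
  }
  out <- lapply(names(bundle), function(id) {
    t <- bundle[[id]]
    s <- std$per_modality[[id]]
    unseen <- setdiff(t$feature_names, names(s$location))
    if (length(unseen) > 0) {
      rf_validation_error(sprintf(
        "modality '%s': feature(s) unseen at fit time: %s",
        id, paste(utils::head(unseen, 5), collapse = ", ")
      ))
    }
    loc <- s$location[t$feature_names]
    sc <- s$scale[t$feature_names]
    v <- sweep(sweep(t$values, 2, loc, `-`), 2, sc, `/`)
    feature_table(v, t$sample_ids, t$feature_names, t$modality_id, labels = t$labels)
  })
  modality_bundle(out)
}

#' Label-stratified cohort split
#'
#' Splits sample ids into named partitions (default mirrors a 121/62/61
#' training / testing-1 / testing-2 design on 244 samples) preserving class
#' proportions within each partition to within one sample per class
#' (largest-remainder apportionment within class). Deterministic under
#' `seed`.
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param labels Binary labels (0/1) aligned with `sample_ids`.
#' @param fractions Named numeric vector summing to 1; names become the
#'   partition names. Default `c(training = 121, testing_1 = 62,
#'   testing_2 = 61) / 244`.
#' @param seed Integer seed.
#' @return An object of class `cohort_split`: a named list of disjoint
#'   sample-id vectors covering all ids.
#' @export
#' @examples
#' sp <- split_cohort(sprintf("s%03d", 1:244), rep(c(1, 0), c(131, 113)), seed = 7)
#' lengths(sp)
split_cohort <- function(sample_ids,
                         labels,
                         fractions = c(training = 121, testing_1 = 62, testing_2 = 61) / 244,
                         seed = 1) {
  sample_ids <- as.character(sample_ids)
  stopifnot(length(sample_ids) == length(labels))
  if (anyDuplicated(sample_ids)) rf_validation_error("duplicate sample ids")
  if (!is_binary01(labels)) rf_validation_error("labels must be 0/1")
  if (abs(sum(fractions) - 1) > 1e-8) rf_validation_error("fractions must sum to 1")
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("partition_", seq_along(fractions))
  }
  k <- length(fractions)
  parts <- stats::setNames(vector("list", k), names(fractions))
  for (nm in names(parts)) parts[[nm]] <- character(0)

  set.seed(derive_seed(seed, "split_cohort"))
  for (cls in sort(unique(labels))) {
    ids <- sample_ids[labels == cls]
    ids <- sample(ids)
    # largest-remainder apportionment of this class across partitions
    exact <- fractions * length(ids)
    base <- floor(exact)
    rem <- exact - base
    extra <- length(ids) - sum(base)
    if (extra > 0) {
      give <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    offset <- 0
    for (i in seq_len(k)) {
      take <- base[i]
      parts[[i]] <- c(parts[[i]], ids[seq_len(take) + offset])
      offset <- offset + take
    }
  }
  empty_class <- vapply(seq_len(k), function(i) {
    fractions[i] > 0 && length(parts[[i]]) > 0 &&
      length(unique(labels[match(parts[[i]], sample_ids)])) < length(unique(labels))
  }, logical(1))
  if (any(empty_class)) {
    warning(sprintf("partition(s) missing a class: %s",
                    paste(names(fractions)[empty_class], collapse = ", ")),
            call. = FALSE)
  }
  structure(parts, class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split>", paste(sprintf("%s: %d", names(x), lengths(x)),
                              collapse = ", "), "\n")
  invisible(x)
}
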