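#' Construct a per-modality feature table
#'
#' A feature table holds the radiomics features of one MRI sequence
#' (modality): one row per sample, one column per feature, with unique
#' sample ids and feature names and an optional binary class label per
#' sample (positive class = 1, by convention GBM).
#'
#' @param values Numeric matrix, samples x features. No missing values.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param feature_names Character vector of unique feature names.
#' @param modality_id Single string naming the sequence (e.g. `"T1WI"`).
#' @param labels Optional integer vector in `{0, 1}`, one per sample.
#' @return An object of class `feature_table`.
#' @export
#' @examples
#' ft <- feature_table(matrix(1:4, 2, 2), c("s1", "s2"), c("f1", "f2"), "T1WI",
#'                     labels = c(0, 1))
#' ft$values
feature_table <- function(values, sample_ids, feature_names, modality_id,
                          labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (nrow(values) != length(sample_ids)) {
    rf_validation_error("number of rows does not match number of sample ids")
  }
  if (ncol(values) != length(feature_names)) {
    rf_validation_error("number of columns does not match number of feature names")
  }
  if (anyDuplicated(sample_ids)) {
    rf_validation_error(sprintf(
      "duplicate sample id(s): %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(feature_names)) {
    rf_validation_error("duplicate feature names")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, , drop = TRUE]
    rf_validation_error(sprintf(
      "non-finite value at sample '%s', feature '%s'",
      sample_ids[bad[1]], feature_names[bad[2]]
    ))
  }
  if (!is.null(labels)) {
    if (length(labels) != length(sample_ids)) {
      rf_validation_error("labels length does not match sample count")
    }
    if (!is_binary01(labels)) {
      rf_validation_error("labels must be coded 0/1 with no missing values")
    }
    labels <- as.integer(labels)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(
      modality_id = as.character(modality_id)[1],
      sample_ids = sample_ids,
      feature_names = feature_names,
      values = values,
      labels = labels
    ),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> modality '%s': %d samples x %d features%s\n",
    x$modality_id, length(x$sample_ids), length(x$feature_names),
    if (is.null(x$labels)) "" else sprintf(
      ", labels 1/0 = %d/%d", sum(x$labels == 1), sum(x$labels == 0)
    )
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from CSV
#'
#' Expects a header with a `sample_id` column, an optional `label` column
#' (0/1), and one column per feature. Row order is preserved. Duplicate
#' sample ids, non-numeric feature cells, and missing labels (when labels
#' are requested) are hard errors.
#'
#' @param path Path to a CSV file (UTF-8, '.' decimal separator).
#' @param modality_id Modality identifier to attach.
#' @param require_labels If `TRUE`, a complete `label` column must be present.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, modality_id, require_labels = FALSE) {
  if (!file.exists(path)) rf_validation_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    rf_validation_error(sprintf("%s: no 'sample_id' column", path))
  }
  sample_ids <- as.character(df$sample_id)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    if (anyNA(labels)) {
      if (require_labels) rf_validation_error(sprintf("%s: missing label values", path))
      labels <- NULL
    }
  } else if (require_labels) {
    rf_validation_error(sprintf("%s: labels requested but no 'label' column", path))
  }
  feat_cols <- setdiff(names(df), c("sample_id", "label"))
  if (length(feat_cols) == 0) rf_validation_error(sprintf("%s: no feature columns", path))
  for (cl in feat_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        rf_validation_error(sprintf(
          "%s: non-numeric value in column '%s', row %d (sample '%s')",
          path, cl, bad[1], sample_ids[bad[1]]
        ))
      }
      df[[cl]] <- vn
    }
  }
  feature_table(as.matrix(df[feat_cols]), sample_ids, feat_cols, modality_id,
                labels = labels)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: writes `sample_id`, `label` (if
#' present), then the feature columns, preserving order.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(table$labels)) df$label <- table$labels
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a feature table against a registry
#'
#' @param table A `feature_table`.
#' @param registry A [feature_registry()].
#' @param strict If `TRUE`, any mismatch is an error enumerating the
#'   offending names; otherwise a report is returned.
#' @return A list with elements `missing` (registry features absent from the
#'   table), `extra` (table features not in the registry), and `ok`.
#' @export
validate_against_registry <- function(table, registry, strict = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(registry, "feature_registry"))
  want <- registry_feature_names(registry)
  have <- table$feature_names
  report <- list(
    missing = setdiff(want, have),
    extra = setdiff(have, want)
  )
  report$ok <- length(report$missing) == 0 && length(report$extra) == 0
  if (strict && !report$ok) {
    rf_validation_error(sprintf(
      "feature table '%s' does not match registry; missing: [%s]; extra: [%s]",
      table$modality_id,
      paste(report$missing, collapse = ", "),
      paste(report$extra, collapse = ", ")
    ))
  }
  report
}

#' Bundle feature tables from several modalities
#'
#' All member tables must share identical sample ids (same order) and
#' identical feature names. Fusion requires at least two modalities;
#' a single-table bundle is allowed for pass-through workflows.
#'
#' @param tables A list of `feature_table` objects (1 to 4 modalities).
#' @return An object of class `modality_bundle` (a named list of tables).
#' @export
modality_bundle <- function(tables) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  stopifnot(is.list(tables), length(tables) >= 1)
  if (!all(vapply(tables, inherits, logical(1), "feature_table"))) {
    rf_validation_error("all bundle members must be feature_table objects")
  }
  if (length(tables) > 4) {
    rf_validation_error("at most 4 modalities are supported")
  }
  ids <- vapply(tables, function(t) t$modality_id, character(1))
  if (anyDuplicated(ids)) rf_validation_error("duplicate modality ids in bundle")
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$sample_ids, ref$sample_ids)) {
      rf_validation_error(sprintf(
        "modality '%s' has different sample ids/order than '%s'",
        t$modality_id, ref$modality_id
      ))
    }
    if (!identical(t$feature_names, ref$feature_names)) {
      rf_validation_error(sprintf(
        "modality '%s' has different feature names than '%s'",
        t$modality_id, ref$modality_id
      ))
    }
  }
  names(tables) <- ids
  structure(tables, class = "modality_bundle")
}

#' @export
print.modality_bundle <- function(x, ...) {
  cat(sprintf(
    "<modality_bundle> %d modalities [%s]: %d samples x %d features\n",
    length(x), paste(names(x), collapse = ", "),
    length(x[[1]]$sample_ids), length(x[[1]]$feature_names)
  ))
  invisible(x)
}

bundle_labels <- function(bundle) {
  for (t in bundle) if (!is.null(t$labels)) return(t$labels)
  NULL
}

bundle_modalities <- function(bundle) {
  vapply(bundle, function(t) t$modality_id, character(1))
}

#' Subset a bundle by sample ids and/or modalities
#'
#' @param bundle A `modality_bundle`.
#' @param sample_ids Optional sample ids to keep (in the given order).
#' @param modalities Optional modality ids to keep.
#' @return A `modality_bundle`.
#' @export
subset_bundle <- function(bundle, sample_ids = NULL, modalities = NULL) {
  stopifnot(inherits(bundle, "modality_bundle"))
  tabs <- unclass(bundle)
  if (!is.null(modalities)) {
    missing <- setdiff(modalities, names(tabs))
    if (length(missing) > 0) {
      rf_validation_error(sprintf("modalities not in bundle: %s",
                                  paste(missing, collapse = ", ")))
    }
    tabs <- tabs[modalities]
  }
  if (!is.null(sample_ids)) {
    tabs <- lapply(tabs, function(t) {
      idx <- match(sample_ids, t$sample_ids)
      if (anyNA(idx)) {
        rf_validation_error("sample id(s) not present in bundle")
      }
      feature_table(t$values[idx, , drop = FALSE], sample_ids,
                    t$feature_names, t$modality_id,
                    labels = if (is.null(t$labels)) NULL else t$labels[idx])
    })
  }
  modality_bundle(tabs)
}
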