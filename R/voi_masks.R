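# Binary 3-D mask utilities for the VOI workflow: Dice conformity between
# two raters' delineations, the intersection-consensus rule, morphological
# union, and enumeration of the seven VOI types built from the three base
# labels nET (non-enhanced tumor), ET (enhanced tumor), pTE (peritumoral
# edema).

.voi_base_labels <- c("nET", "ET", "pTE")

#' Construct a binary voxel mask
#'
#' @param voxels A 3-D array; coerced to binary (non-zero = inside).
#' @param spacing Optional length-3 voxel spacing in mm.
#' @param label Optional VOI label (`nET`, `ET`, `pTE`, or a `+`-joined union).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(voxels, spacing = NULL, label = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3) rf_validation_error("mask must be a 3-D array")
  if (anyNA(voxels)) rf_validation_error("mask contains missing values")
  vox <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (!is.null(spacing)) stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(voxels = vox, spacing = spacing, label = label),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask>%s %s, %d voxels set\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Read / write a binary mask as NIfTI
#'
#' Values are binarized on read (non-zero = inside). No resampling is ever
#' performed: combining masks of different grid shapes is an error, not an
#' implicit regrid.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param label Optional VOI label to attach.
#' @return [read_mask()] returns a `voxel_mask`; [write_mask()] returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, label = NULL) {
  if (!file.exists(path)) rf_validation_error(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  spacing <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) NULL)
  voxel_mask(array(as.numeric(img), dim = dim(img)[1:3]), spacing = spacing,
             label = label)
}

#' @rdname read_mask
#' @param mask A `voxel_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = dim(mask$voxels)))
  if (!is.null(mask$spacing)) RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    rf_validation_error(sprintf(
      "mask shape mismatch: %s vs %s",
      paste(dim(a$voxels), collapse = "x"), paste(dim(b$voxels), collapse = "x")
    ))
  }
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks are defined as perfectly
#' conforming (Dice 1) with a warning; the formula is otherwise undefined
#' there.
#'
#' @param a,b `voxel_mask` objects on the same grid.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' m <- voxel_mask(array(c(rep(1, 4), rep(0, 4)), c(2, 2, 2)))
#' dice_coefficient(m, m)  # 1
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "voxel_mask"), inherits(b, "voxel_mask"))
  check_same_shape(a, b)
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Consensus of two delineations by the Dice rule
#'
#' If the Dice coefficient is strictly greater than `threshold` the
#' voxelwise intersection is accepted as the consensus VOI; otherwise the
#' discrepancy must be resolved by discussion and a needs-review outcome
#' carrying the Dice value is returned.
#'
#' @param a,b `voxel_mask` objects on the same grid.
#' @param threshold Dice threshold in `(0, 1]`; default 0.9. Equality routes
#'   to review (strict `>`).
#' @return Either a `voxel_mask` (the intersection) or an object of class
#'   `needs_review` with element `dice`.
#' @export
consensus_mask <- function(a, b, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  d <- dice_coefficient(a, b)
  if (d > threshold) {
    voxel_mask(a$voxels & b$voxels, spacing = a$spacing, label = a$label)
  } else {
    structure(list(dice = d, threshold = threshold), class = "needs_review")
  }
}

#' @export
print.needs_review <- function(x, ...) {
  cat(sprintf("<needs_review> Dice %.4f <= %.2f: resolve by consensus discussion\n",
              x$dice, x$threshold))
  invisible(x)
}

#' Morphological union of binary masks
#'
#' Voxelwise OR. Labels are concatenated with `+` in the canonical order
#' nET, ET, pTE (unlabeled inputs yield an unlabeled union).
#'
#' @param masks A list of `voxel_mask` objects on the same grid (at least 1).
#' @return A `voxel_mask`.
#' @export
mask_union <- function(masks) {
  if (inherits(masks, "voxel_mask")) masks <- list(masks)
  if (!is.list(masks) || length(masks) == 0) {
    rf_validation_error("mask_union needs at least one mask")
  }
  stopifnot(all(vapply(masks, inherits, logical(1), "voxel_mask")))
  for (m in masks[-1]) check_same_shape(masks[[1]], m)
  acc <- Reduce(function(x, y) x | y, lapply(masks, `[[`, "voxels"))
  labels <- unlist(lapply(masks, `[[`, "label"))
  label <- NULL
  if (length(labels) == length(masks)) {
    parts <- unique(unlist(strsplit(labels, "+", fixed = TRUE)))
    known <- intersect(.voi_base_labels, parts)
    label <- paste(c(known, setdiff(parts, known)), collapse = "+")
  }
  voxel_mask(acc, spacing = masks[[1]]$spacing, label = label)
}

#' Enumerate the seven VOI types
#'
#' The three base VOIs, their three pairwise morphological unions, and the
#' triple union, in canonical order.
#'
#' @param base_labels The three base labels; must be exactly
#'   `c("nET", "ET", "pTE")` (any order).
#' @return Character vector of length 7:
#'   `nET, ET, pTE, nET+ET, nET+pTE, ET+pTE, nET+ET+pTE`.
#' @export
enumerate_vois <- function(base_labels = .voi_base_labels) {
  if (!setequal(base_labels, .voi_base_labels) || length(base_labels) != 3) {
    rf_validation_error("base labels must be exactly nET, ET, pTE")
  }
  b <- .voi_base_labels
  c(b,
    apply(utils::combn(b, 2), 2, paste, collapse = "+"),
    paste(b, collapse = "+"))
}
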