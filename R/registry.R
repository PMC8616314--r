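# Canonical registry of the 109 radiomics features used throughout:
# first order (19), shape (15), GLCM (24), GLSZM (16), GLRLM (16),
# NGTDM (5), GLDM (14). Names follow the reference extractor's
# `<class>.<FeatureName>` dialect.

.registry_names <- list(
  firstorder = c(
    "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
    "Kurtosis", "Maximum", "MeanAbsoluteDeviation", "Mean", "Median",
    "Minimum", "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
    "Skewness", "StandardDeviation", "TotalEnergy", "Uniformity", "Variance"
  ),
  shape = c(
    "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
    "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "SphericalDisproportion",
    "Sphericity", "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume"
  ),
  glcm = c(
    "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
    "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
    "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
    "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
  ),
  glszm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"
  ),
  glrlm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"
  ),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"),
  gldm = c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"
  )
)

#' Construct a feature registry
#'
#' A registry is the canonical list of `(class, name)` feature identities a
#' feature table is validated against. The default registry carries the 109
#' features of the standard radiomics panel: 19 first-order, 15 shape,
#' 24 GLCM, 16 GLSZM, 16 GLRLM, 5 NGTDM and 14 GLDM features.
#'
#' @param entries A data frame with columns `class` and `name`. `class`
#'   must be one of `firstorder`, `shape`, `glcm`, `glszm`, `glrlm`,
#'   `ngtdm`, `gldm`.
#' @return An object of class `feature_registry`: a data frame with columns
#'   `class`, `name`, and `feature` (the `<class>.<name>` identifier).
#' @export
#' @examples
#' reg <- default_feature_registry()
#' nrow(reg)   # 109
#' table(reg$class)
feature_registry <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("class", "name") %in% names(entries)))
  allowed <- c("firstorder", "shape", "glcm", "glszm", "glrlm", "ngtdm", "gldm")
  bad <- setdiff(unique(entries$class), allowed)
  if (length(bad) > 0) {
    rf_stop(sprintf("unknown feature class(es): %s", paste(bad, collapse = ", ")))
  }
  feature <- paste(entries$class, entries$name, sep = ".")
  if (anyDuplicated(feature)) {
    rf_stop("duplicate (class, name) pairs in registry")
  }
  out <- data.frame(
    class = as.character(entries$class),
    name = as.character(entries$name),
    feature = feature,
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_registry", "data.frame")
  out
}

#' @rdname feature_registry
#' @export
default_feature_registry <- function() {
  entries <- do.call(rbind, lapply(names(.registry_names), function(cl) {
    data.frame(class = cl, name = .registry_names[[cl]], stringsAsFactors = FALSE)
  }))
  feature_registry(entries)
}

#' Feature identifiers of a registry
#'
#' @param registry A `feature_registry`.
#' @return Character vector of `<class>.<name>` identifiers, in registry order.
#' @export
registry_feature_names <- function(registry) {
  stopifnot(inherits(registry, "feature_registry"))
  registry$feature
}
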