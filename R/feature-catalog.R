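# The 91-feature catalog: 18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM,
# 14 GLDM, 5 NGTDM. Families in fixed order, names alphabetical within a
# family; this order is the canonical column order everywhere (CSV output,
# de-duplication passes, reports).
#
# Deprecated duplicates of the common extractor sets are excluded so the
# catalog closes at 91: first-order StandardDeviation (monotone in Variance),
# GLCM Dissimilarity (= DifferenceAverage), SumVariance (= ClusterTendency),
# SumAverage (= 2 * JointAverage for a symmetric GLCM) and MCC.

catalog_names <- list(
  firstorder = c(
    "10Percentile", "90Percentile", "Energy", "Entropy",
    "InterquartileRange", "Kurtosis", "Maximum", "Mean",
    "MeanAbsoluteDeviation", "Median", "Minimum", "Range",
    "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
    "TotalEnergy", "Uniformity", "Variance"),
  glcm = c(
    "Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MaximumProbability", "SumEntropy", "SumSquares"),
  glrlm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis"),
  glszm = c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
  gldm = c(
    "DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis"),
  ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength"))

#' The canonical 91-feature catalog
#'
#' Names and families of the 91 handcrafted radiomic features extracted by
#' [extract_features()]: 18 first-order intensity statistics plus texture
#' features from the five standard matrices (22 GLCM, 16 GLRLM, 16 GLSZM,
#' 14 GLDM, 5 NGTDM). The row order is the canonical feature order used for
#' every table column and for the greedy Spearman de-duplication pass.
#'
#' @return A `data.frame` with columns `name` (e.g. `"glcm_Contrast"`),
#'   `family` and `short_name`, with exactly 91 rows.
#' @export
feature_catalog <- function() {
  fam <- rep(names(catalog_names), lengths(catalog_names))
  short <- unlist(catalog_names, use.names = FALSE)
  data.frame(name = paste(fam, short, sep = "_"),
             family = fam, short_name = short,
             stringsAsFactors = FALSE)
}
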