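#' Canonical radiomic feature registry
#'
#' The extraction pipeline computes 94 features per patient per imaging plane,
#' spread over six classes: first-order statistics (FIRST, 19), gray-level
#' co-occurrence matrix (GLCM, 24), gray-level dependence matrix (GLDM, 14),
#' gray-level run length matrix (GLRLM, 16), gray-level size zone matrix
#' (GLSZM, 16) and neighborhood gray-tone difference matrix (NGTDM, 5).
#' After selection, 30 features remain, five per class, with SHAPE replacing
#' NGTDM in the selected set (shape descriptors are ingested from external
#' extractor tables, never computed natively here).
#'
#' Feature identifiers are `CLASS_FeatureName` strings, e.g.
#' `"GLCM_ClusterProminence"`.
#'
#' @return A tibble with columns `feature` (identifier), `class`, and `name`
#'   (the human-readable feature name); one row per selected feature (30 rows).
#' @examples
#' feature_registry()
#' @export
feature_registry <- function() {
  sel <- .acdx_selected
  tibble::tibble(
    feature = unlist(sel, use.names = FALSE),
    class = rep(names(sel), lengths(sel)),
    name = sub("^[A-Z]+_", "", unlist(sel, use.names = FALSE))
  )
}

# selected features per class, five each (canonical selection)
.acdx_selected <- list(
  FIRST = c("FIRST_Energy", "FIRST_Median", "FIRST_Minimum",
            "FIRST_TotalEnergy", "FIRST_Variance"),
  GLCM = c("GLCM_ClusterProminence", "GLCM_Contrast",
           "GLCM_DifferenceAverage", "GLCM_DifferenceVariance", "GLCM_Id"),
  GLDM = c("GLDM_DependenceVariance", "GLDM_GrayLevelNonUniformity",
           "GLDM_GrayLevelVariance", "GLDM_HighGrayLevelEmphasis",
           "GLDM_LargeDependenceLowGrayLevelEmphasis"),
  GLRLM = c("GLRLM_GrayLevelNonUniformity", "GLRLM_GrayLevelVariance",
            "GLRLM_HighGrayLevelRunEmphasis",
            "GLRLM_LongRunHighGrayLevelEmphasis",
            "GLRLM_RunLengthNonUniformity"),
  GLSZM = c("GLSZM_GrayLevelNonUniformity", "GLSZM_LargeAreaEmphasis",
            "GLSZM_LargeAreaHighGrayLevelEmphasis",
            "GLSZM_LargeAreaLowGrayLevelEmphasis", "GLSZM_ZoneVariance"),
  SHAPE = c("SHAPE_Flatness", "SHAPE_LeastAxisLength", "SHAPE_MeshVolume",
            "SHAPE_SurfaceArea", "SHAPE_VoxelVolume")
)

# per-class cardinalities of the full extraction (before selection)
.acdx_class_sizes <- c(
  FIRST = 19L, GLCM = 24L, GLDM = 14L, GLRLM = 16L, GLSZM = 16L, NGTDM = 5L
)

#' Extraction class cardinalities
#'
#' Number of features each extraction class produces before selection. The
#' six classes together yield 94 features per patient per plane.
#'
#' @return A named integer vector (FIRST, GLCM, GLDM, GLRLM, GLSZM, NGTDM).
#' @examples
#' sum(feature_class_sizes()) # 94
#' @export
feature_class_sizes <- function() .acdx_class_sizes

#' Selected features of one class
#'
#' @param class One of `"FIRST"`, `"GLCM"`, `"GLDM"`, `"GLRLM"`, `"GLSZM"`,
#'   `"SHAPE"`.
#' @return Character vector of the five canonical feature identifiers.
#' @examples
#' selected_features("GLCM")
#' @export
selected_features <- function(class) {
  class <- match.arg(class, names(.acdx_selected))
  .acdx_selected[[class]]
}

#' Action label for a discretized feature
#'
#' Renders a discretized feature value as a CCS action label:
#' the level (`L`, `M`, `H`), an underscore, then the lowercased feature name
#' (class prefix dropped), e.g. `H_clusterprominence`, `L_totalenergy`.
#' The rendering is injective over any one class's feature set.
#'
#' @param level Character vector of levels (`"L"`, `"M"` or `"H"`).
#' @param feature Character vector of feature identifiers.
#' @return Character vector of action labels.
#' @examples
#' action_label("H", "FIRST_TotalEnergy") # "H_totalenergy"
#' @export
action_label <- function(level, feature) {
  stopifnot(all(level %in% c("L", "M", "H")))
  paste0(level, "_", tolower(sub("^[A-Z]+_", "", feature)))
}
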