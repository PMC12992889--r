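#' @useDynLib pulmolayer, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate setNames
#' @import methods
NULL

#' CTVolume: a 3D CT image in Hounsfield units
#'
#' Container for a 3D scalar field in Hounsfield units (HU) together with its
#' voxel spacing. Axes follow the RAS convention used throughout the package:
#' axis 1 = left-right, axis 2 = anteroposterior (the baseline projection ray),
#' axis 3 = craniocaudal.
#'
#' @slot data 3D numeric array of HU values.
#' @slot spacing numeric(3), voxel size in mm per axis (strictly positive).
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 strictly positive finite values (mm)")
    if (anyNA(object@data)) return("HU values must be finite")
    TRUE
  }
)

#' Construct a CTVolume
#'
#' @param data 3D numeric array of HU values.
#' @param spacing voxel spacing in mm, length 3 (recycled if length 1).
#' @return A [CTVolume-class] object.
#' @export
CTVolume <- function(data, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("CTVolume", data = data, spacing = as.numeric(spacing))
}

#' LungMaskSet: per-side lung masks with proximal-vessel additions
#'
#' Holds the two roles a lung mask plays in this pipeline: the *initial*
#' segmentation (lungs with intrapulmonary vessels, the output of an automatic
#' lung segmentation tool) and the *addition* mask holding the proximal vessel
#' trunks that such tools exclude and that are restored separately. The *full*
#' mask of a side is the union of the two and is what the layering operates on.
#'
#' @slot initialLeft,initialRight logical 3D arrays, the automatic-segmentation
#'   role.
#' @slot additionLeft,additionRight logical 3D arrays, the proximal-vessel
#'   role (may be all-FALSE).
#' @slot spacing numeric(3) voxel spacing in mm.
#' @export
setClass("LungMaskSet",
  representation(initialLeft = "array", initialRight = "array",
                 additionLeft = "array", additionRight = "array",
                 spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@initialLeft)
    for (s in c("initialRight", "additionLeft", "additionRight"))
      if (!identical(dim(slot(object, s)), d))
        return("all masks must share one grid")
    fl <- object@initialLeft | object@additionLeft
    fr <- object@initialRight | object@additionRight
    if (any(fl & fr)) return("left and right full masks must be disjoint")
    TRUE
  }
)

#' Construct a LungMaskSet
#'
#' @param initialLeft,initialRight logical 3D arrays.
#' @param additionLeft,additionRight logical 3D arrays; default empty.
#' @param spacing voxel spacing in mm (length 3).
#' @return A [LungMaskSet-class] object.
#' @export
LungMaskSet <- function(initialLeft, initialRight,
                        additionLeft = array(FALSE, dim(initialLeft)),
                        additionRight = array(FALSE, dim(initialRight)),
                        spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("LungMaskSet",
      initialLeft = initialLeft, initialRight = initialRight,
      additionLeft = additionLeft, additionRight = additionRight,
      spacing = as.numeric(spacing))
}

#' OrderedFractionMap: central-to-peripheral voxel ordering for one lung
#'
#' Per-voxel cumulative lung-volume fraction at which each voxel was absorbed
#' during the HU threshold descent from the vessel cores. Fractions lie in
#' (0, 1] inside the lung's full mask and are NA outside; the maximum is
#' exactly 1. The inclusion-step ordinal is kept as a diagnostic.
#'
#' @slot fraction 3D numeric array, (0,1] in-mask, NA outside.
#' @slot stepIndex 3D integer array of 0-based inclusion steps, NA outside.
#' @slot nVoxels integer, number of in-mask voxels.
#' @slot degenerate logical, TRUE when the ordering collapsed to a single tie
#'   group (constant-HU mask).
#' @export
setClass("OrderedFractionMap",
  representation(fraction = "array", stepIndex = "array",
                 nVoxels = "integer", degenerate = "logical"),
  validity = function(object) {
    fr <- object@fraction[!is.na(object@fraction)]
    if (length(fr) != object@nVoxels) return("fraction/nVoxels mismatch")
    if (length(fr) == 0L) return("no in-mask voxels")
    if (any(fr <= 0) || any(fr > 1)) return("fractions must lie in (0, 1]")
    if (abs(max(fr) - 1) > 1e-12) return("maximum fraction must be exactly 1")
    TRUE
  }
)

#' LayerMaskSet: the four equal-volume concentric layers of one lung
#'
#' Labels 1-4 identify the quartile layers Q1 (most central, absorbed first
#' during the threshold descent) through Q4 (most peripheral); 0 marks voxels
#' outside the lung. The layers are pairwise disjoint and their union is the
#' lung's full mask. `tieSpillover` records, for each of the three internal
#' quartile boundaries, how many voxels belong to a tie group straddling that
#' boundary (the resolution limit of the equal-volume split).
#'
#' @slot labels 3D integer array with values 0-4.
#' @slot tieSpillover named numeric(3), voxels in boundary-straddling tie
#'   groups at the 0.25/0.50/0.75 cuts.
#' @slot nVoxels integer, in-mask voxel count.
#' @export
setClass("LayerMaskSet",
  representation(labels = "array", tieSpillover = "numeric",
                 nVoxels = "integer"),
  validity = function(object) {
    lab <- object@labels
    if (!all(lab %in% 0:4)) return("labels must be integers 0-4")
    if (sum(lab > 0L) != object@nVoxels) return("labels/nVoxels mismatch")
    TRUE
  }
)

#' MIPSet: the eleven standardized-angle projections of one masked lung
#'
#' Eleven 2D maximum-intensity projections, windowed to [0, 1], of one lung
#' under one masking scheme, with the (axis, angle) of each view.
#'
#' @slot images numeric array size x size x 11, pixel values in [0, 1].
#' @slot views data.frame with columns axis, angle_deg, is_baseline,
#'   inplane_deg, one row per image.
#' @slot scheme character, masking-scheme name (see [maskingSchemes()]).
#' @slot side "left" or "right".
#' @slot window numeric(2): display window (level HU, width HU).
#' @export
setClass("MIPSet",
  representation(images = "array", views = "data.frame", scheme = "character",
                 side = "character", window = "numeric"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 3L) return("images must be a 3D array (h, w, view)")
    if (d[3] != nrow(object@views)) return("image/view count mismatch")
    if (min(object@images) < 0 || max(object@images) > 1)
      return("pixel values must lie in [0, 1]")
    if (!object@side %in% c("left", "right")) return("side must be left/right")
    TRUE
  }
)

#' ExperimentResult: one masking scheme's cross-validated performance
#'
#' @slot scheme masking-scheme name.
#' @slot task character label of the classification task.
#' @slot aurocPerShuffle numeric, one fold-and-repeat-averaged AUROC per
#'   shuffle.
#' @slot rawAuroc data.frame (shuffle, fold, repeat_, auroc), the diagnostic
#'   fold-level values.
#' @slot patientScores data.frame (case_id, label, score): per-patient mean
#'   hold-out lung-maximum score.
#' @export
setClass("ExperimentResult",
  representation(scheme = "character", task = "character",
                 aurocPerShuffle = "numeric", rawAuroc = "data.frame",
                 patientScores = "data.frame"),
  validity = function(object) {
    if (any(object@aurocPerShuffle < 0 | object@aurocPerShuffle > 1,
            na.rm = TRUE))
      return("AUROC values must lie in [0, 1]")
    TRUE
  }
)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %dx%dx%d, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LungMaskSet", function(object) {
  cat(sprintf(paste0("LungMaskSet grid %s | initial L/R: %d/%d vox | ",
                     "addition L/R: %d/%d vox\n"),
              paste(dim(object@initialLeft), collapse = "x"),
              sum(object@initialLeft), sum(object@initialRight),
              sum(object@additionLeft), sum(object@additionRight)))
})

setMethod("show", "OrderedFractionMap", function(object) {
  cat(sprintf("OrderedFractionMap: %d voxels, %d inclusion steps%s\n",
              object@nVoxels, max(object@stepIndex, na.rm = TRUE) + 1L,
              if (object@degenerate) " [degenerate: single tie group]" else ""))
})

setMethod("show", "LayerMaskSet", function(object) {
  counts <- tabulate(object@labels[object@labels > 0L], nbins = 4L)
  cat(sprintf("LayerMaskSet: N=%d | Q1-Q4 = %s | tie spillover %s\n",
              object@nVoxels, paste(counts, collapse = "/"),
              paste(object@tieSpillover, collapse = "/")))
})

setMethod("show", "MIPSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("MIPSet: %d views %dx%d | scheme %s | %s lung | window L%g/W%g\n",
              d[3], d[1], d[2], object@scheme, object@side,
              object@window[1], object@window[2]))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult [%s | %s]: AUROC mean %.3f (min-max %.3f-%.3f) over %d shuffles\n",
              object@scheme, object@task, mean(object@aurocPerShuffle),
              min(object@aurocPerShuffle), max(object@aurocPerShuffle),
              length(object@aurocPerShuffle)))
})
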