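#' Access the HU array of a CTVolume
#' @param x a [CTVolume-class]
#' @return 3D numeric array of HU values.
#' @export
setGeneric("ctData", function(x) standardGeneric("ctData"))

#' @rdname ctData
#' @export
setMethod("ctData", "CTVolume", function(x) x@data)

#' Voxel spacing in mm
#' @param x a volume, mask set or fraction-map object
#' @return numeric(3), mm per voxel along each axis.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "LungMaskSet", function(x) x@spacing)

#' Extract a mask array from a LungMaskSet
#'
#' @param x a [LungMaskSet-class]
#' @param side "left" or "right"
#' @param role "full" (initial plus additions; the layering input),
#'   "initial" (automatic-segmentation role) or "addition" (proximal-vessel
#'   role).
#' @return logical 3D array.
#' @export
maskArray <- function(x, side = c("left", "right"),
                      role = c("full", "initial", "addition")) {
  stopifnot(is(x, "LungMaskSet"))
  side <- match.arg(side)
  role <- match.arg(role)
  ini <- slot(x, if (side == "left") "initialLeft" else "initialRight")
  add <- slot(x, if (side == "left") "additionLeft" else "additionRight")
  switch(role, full = ini | add, initial = ini, addition = add)
}

#' Per-voxel ordering fraction
#' @param x an [OrderedFractionMap-class]
#' @return 3D numeric array in (0,1] inside the mask, NA outside.
#' @export
setGeneric("fractionMap", function(x) standardGeneric("fractionMap"))

#' @rdname fractionMap
#' @export
setMethod("fractionMap", "OrderedFractionMap", function(x) x@fraction)

#' Per-voxel inclusion step of the threshold descent
#' @param x an [OrderedFractionMap-class]
#' @return 3D integer array (0-based step), NA outside the mask.
#' @export
setGeneric("stepIndexMap", function(x) standardGeneric("stepIndexMap"))

#' @rdname stepIndexMap
#' @export
setMethod("stepIndexMap", "OrderedFractionMap", function(x) x@stepIndex)

#' Extract one quartile layer as a logical mask
#' @param x a [LayerMaskSet-class]
#' @param layer "Q1", "Q2", "Q3" or "Q4"
#' @return logical 3D array.
#' @export
layerMask <- function(x, layer = c("Q1", "Q2", "Q3", "Q4")) {
  stopifnot(is(x, "LayerMaskSet"))
  layer <- match.arg(layer)
  x@labels == match(layer, c("Q1", "Q2", "Q3", "Q4"))
}

#' Integer label array of a LayerMaskSet (0 outside, 1-4 = Q1-Q4)
#' @param x a [LayerMaskSet-class]
#' @return 3D integer array.
#' @export
layerLabels <- function(x) {
  stopifnot(is(x, "LayerMaskSet"))
  x@labels
}

#' Images and view table of a MIPSet
#' @param x a [MIPSet-class]
#' @return `mipImages`: numeric array (size, size, n_views);
#'   `mipViews`: data.frame of view specifications.
#' @export
mipImages <- function(x) { stopifnot(is(x, "MIPSet")); x@images }

#' @rdname mipImages
#' @export
mipViews <- function(x) { stopifnot(is(x, "MIPSet")); x@views }

#' Shuffle-level AUROC estimates of an experiment
#' @param x an [ExperimentResult-class]
#' @return numeric vector, one AUROC per shuffle.
#' @export
aurocPerShuffle <- function(x) {
  stopifnot(is(x, "ExperimentResult"))
  x@aurocPerShuffle
}

#' Patient-level averaged hold-out scores of an experiment
#' @param x an [ExperimentResult-class]
#' @return data.frame (case_id, label, score).
#' @export
patientScores <- function(x) {
  stopifnot(is(x, "ExperimentResult"))
  x@patientScores
}
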