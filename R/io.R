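#' Read and write pipeline objects as NIfTI
#'
#' Volumes and masks travel as NIfTI-1 with the voxel spacing encoded in the
#' header (RAS orientation assumed: axis 1 left-right, axis 2
#' anteroposterior, axis 3 craniocaudal). The ordered fraction map is
#' written as a float volume with -1 outside the mask; a layer mask set is
#' written as a single labeled volume (1-4 = Q1-Q4, 0 outside).
#'
#' @param vol a [CTVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readCTVolume` returns a [CTVolume-class]; the writers return
#'   `path` invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
writeCTVolume <- function(vol, path) {
  stopifnot(is(vol, "CTVolume"))
  img <- RNifti::asNifti(vol@data, reference = NULL)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
readCTVolume <- function(path) {
  img <- RNifti::readNifti(path)
  CTVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname nifti-io
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @export
writeMask <- function(mask, spacing, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti-io
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  list(mask = array(as.numeric(img) > 0.5, dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname nifti-io
#' @param masks a [LungMaskSet-class].
#' @param dir output directory (created on demand).
#' @export
writeLungMaskSet <- function(masks, dir) {
  stopifnot(is(masks, "LungMaskSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("left", "right"))
    for (role in c("initial", "addition"))
      writeMask(maskArray(masks, side, role), masks@spacing,
                file.path(dir, paste0(role, "_", side, ".nii.gz")))
  invisible(dir)
}

#' @rdname nifti-io
#' @export
readLungMaskSet <- function(dir) {
  rd <- function(nm) readMask(file.path(dir, paste0(nm, ".nii.gz")))
  il <- rd("initial_left"); ir <- rd("initial_right")
  al <- rd("addition_left"); ar <- rd("addition_right")
  LungMaskSet(il$mask, ir$mask, al$mask, ar$mask, il$spacing)
}

#' @rdname nifti-io
#' @param ofm an [OrderedFractionMap-class].
#' @export
writeFractionMap <- function(ofm, spacing, path) {
  stopifnot(is(ofm, "OrderedFractionMap"))
  fr <- ofm@fraction
  fr[is.na(fr)] <- -1
  img <- RNifti::asNifti(fr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti-io
#' @param layers a [LayerMaskSet-class].
#' @export
writeLayerMaskSet <- function(layers, spacing, path) {
  stopifnot(is(layers, "LayerMaskSet"))
  img <- RNifti::asNifti(array(as.integer(layers@labels), dim(layers@labels)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a cohort manifest as CSV
#'
#' @param cohort a [generateCohort()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortManifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "PhantomCohort"))
  utils::write.csv(cohort$cases, path, row.names = FALSE)
  invisible(path)
}
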