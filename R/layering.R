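#' Order lung voxels from the central vessels to the periphery
#'
#' Implements the iterative threshold-descent ordering that underlies the
#' equal-volume layering. The in-mask voxels attaining the in-mask HU maximum
#' (in CTPA these are in the contrast-filled central vessels) form the seed at
#' step 0. The inclusion threshold then descends in decrements of `huStep`;
#' at each step, all not-yet-included in-mask voxels at or above the threshold
#' join the region, after which a morphological closing (ball of
#' `closingRadiusMM`, in physical mm, so the behaviour is spacing-invariant)
#' is applied to the included region and clipped to the mask, absorbing nearby
#' low-attenuation parenchyma enclosed by vessels; voxels closed in receive
#' the same step index. The descent continues until all in-mask voxels are
#' included. Each voxel's ordering fraction is the cumulative included count
#' at the end of its inclusion step divided by the mask size, so tie groups
#' share one value, the maximum is exactly 1, and the quartile rule is
#' well-defined.
#'
#' With `closingRadiusMM = 0` the ordering is exactly a sort of the in-mask
#' voxels by descending HU with ties grouped per threshold step (one distinct
#' integer HU per step when `huStep = 1`).
#'
#' @param vol a [CTVolume-class].
#' @param lungMask logical 3D array, the lung's *full* mask (initial plus
#'   proximal additions) on the same grid as `vol`.
#' @param closingRadiusMM closing-ball radius in mm; 0 disables the closing.
#'   Default 4 mm.
#' @param huStep threshold decrement in HU per step (>= 1). Default 1 HU; a
#'   coarser step trades ordering resolution (more voxels per tie group) for
#'   speed.
#' @return An [OrderedFractionMap-class].
#' @export
computeOrderedFractionMap <- function(vol, lungMask, closingRadiusMM = 4,
                                      huStep = 1) {
  stopifnot(is(vol, "CTVolume"))
  if (!identical(dim(vol@data), dim(lungMask)))
    stop("mask and volume grids differ")
  if (!any(lungMask)) stop("lung mask is empty")
  if (huStep < 1) stop("huStep must be >= 1 HU")

  res <- cpp_threshold_descent(as.numeric(vol@data), as.logical(lungMask),
                               dim(vol@data), vol@spacing,
                               closingRadiusMM, huStep)
  n <- as.integer(res$n_mask)
  step <- array(res$step, dim(vol@data))
  step[step < 0L] <- NA_integer_
  frac <- array(NA_real_, dim(vol@data))
  frac[!is.na(step)] <- res$cum_count[step[!is.na(step)] + 1L] / n

  degenerate <- length(unique(frac[!is.na(frac)])) == 1L
  if (degenerate)
    warning("degenerate ordering: all in-mask voxels share one tie group ",
            "(constant HU?)")
  new("OrderedFractionMap", fraction = frac, stepIndex = step,
      nVoxels = n, degenerate = degenerate)
}

#' Split an ordered lung into four equal-volume concentric layers
#'
#' Cuts the ordering fraction at 0.25 increments: layer Qk holds the voxels
#' with fraction in ((k-1)/4, k/4]. Q1 is the most central quarter of the
#' lung volume (absorbed first, around the proximal vessels) and Q4 the most
#' peripheral. Because tie groups share one fraction value, a whole group
#' lands in a single layer; layer sizes deviate from N/4 by at most the size
#' of the largest tie group straddling a boundary, which is recorded in the
#' `tieSpillover` diagnostic.
#'
#' @param ofm an [OrderedFractionMap-class].
#' @return A [LayerMaskSet-class].
#' @export
quartileMasks <- function(ofm) {
  stopifnot(is(ofm, "OrderedFractionMap"))
  frac <- ofm@fraction
  lab <- array(0L, dim(frac))
  inm <- !is.na(frac)
  lab[inm] <- pmin(4L, as.integer(ceiling(frac[inm] * 4 - 1e-12)))

  # tie groups occupy the cumulative-fraction interval (start, end]; a group
  # straddles a quartile cut when start < cut < end
  fr <- sort(unique(frac[inm]))
  sizes <- tabulate(match(frac[inm], fr))
  ends <- fr
  starts <- c(0, fr[-length(fr)])
  spill <- vapply(c(0.25, 0.5, 0.75), function(b) {
    hit <- starts < b - 1e-12 & ends > b + 1e-12
    if (any(hit)) sum(sizes[hit]) else 0
  }, numeric(1))
  names(spill) <- c("0.25", "0.50", "0.75")

  new("LayerMaskSet", labels = lab, tieSpillover = spill,
      nVoxels = ofm@nVoxels)
}

#' The eleven masking schemes
#'
#' Enumerates the masking schemes compared by the pipeline: the full lung
#' (Q1-Q4), progressively larger central combinations (Q1, Q1-Q2, Q1-Q3),
#' combinations excluding central layers (Q2-Q4, Q3-Q4), each single layer,
#' and `initial` — the automatic lung segmentation *without* the manually
#' restored proximal vessels, serving as the reference for what a standard
#' lung-segmentation tool provides.
#'
#' @return Named list mapping scheme name to the layer subset it selects
#'   (`"initial"` maps to the string `"initial"`).
#' @export
maskingSchemes <- function() {
  list(
    full    = c("Q1", "Q2", "Q3", "Q4"),
    Q1      = "Q1",
    Q1Q2    = c("Q1", "Q2"),
    Q1Q2Q3  = c("Q1", "Q2", "Q3"),
    Q2      = "Q2",
    Q2Q3    = c("Q2", "Q3"),
    Q2Q3Q4  = c("Q2", "Q3", "Q4"),
    Q3      = "Q3",
    Q3Q4    = c("Q3", "Q4"),
    Q4      = "Q4",
    initial = "initial"
  )
}

#' Combine quartile layers into a region mask for one masking scheme
#'
#' @param layers a [LayerMaskSet-class] for one lung.
#' @param scheme a scheme name from [maskingSchemes()], or a character vector
#'   of layer names (subset of Q1-Q4).
#' @param initial logical 3D array: the initial segmentation (without
#'   proximal additions); required for the `"initial"` scheme only.
#' @return logical 3D array, the union of the selected layers (possibly empty
#'   for degenerate orderings; downstream operations reject empty masks).
#' @export
combineLayers <- function(layers, scheme, initial = NULL) {
  stopifnot(is(layers, "LayerMaskSet"))
  if (length(scheme) == 1L && scheme %in% names(maskingSchemes()))
    scheme <- maskingSchemes()[[scheme]]
  if (length(scheme) == 0L) stop("empty masking scheme")
  if (identical(scheme, "initial")) {
    if (is.null(initial)) stop("the 'initial' scheme needs the initial mask")
    return(initial)
  }
  if (!all(scheme %in% c("Q1", "Q2", "Q3", "Q4")))
    stop("scheme must reference Q1-Q4 or 'initial'")
  ks <- match(scheme, c("Q1", "Q2", "Q3", "Q4"))
  array(layers@labels %in% ks, dim(layers@labels))
}

#' Layer one lung end to end
#'
#' Convenience wrapper: ordering fraction map plus quartile masks for one
#' side of a [LungMaskSet-class].
#'
#' @inheritParams computeOrderedFractionMap
#' @param masks a [LungMaskSet-class].
#' @param side "left" or "right" (lungs are processed independently).
#' @return A [LayerMaskSet-class].
#' @export
computeLayers <- function(vol, masks, side = c("left", "right"),
                          closingRadiusMM = 4, huStep = 1) {
  side <- match.arg(side)
  full <- maskArray(masks, side, "full")
  quartileMasks(computeOrderedFractionMap(vol, full, closingRadiusMM, huStep))
}
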