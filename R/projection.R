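#' Build the standardized view set
#'
#' The default set holds eleven views: the anteroposterior (AP) baseline,
#' rotations about the vertical (craniocaudal) axis at +/-22.5, +/-45 and
#' +/-67.5 degrees, and rotations about the left-to-right horizontal axis at
#' +/-30 and +/-60 degrees. The exact angles are a free configuration of the
#' method; this default spans both rotation axes symmetrically.
#'
#' @param verticalAngles rotation angles (deg) about the vertical axis.
#' @param horizontalAngles rotation angles (deg) about the left-right
#'   horizontal axis.
#' @return data.frame with columns `axis` ("ap", "vertical", "horizontal"),
#'   `angle_deg`, `is_baseline`, `inplane_deg` (in-plane image rotation,
#'   filled by [augmentViews()]).
#' @export
makeViewSet <- function(verticalAngles = c(-67.5, -45, -22.5, 22.5, 45, 67.5),
                        horizontalAngles = c(-60, -30, 30, 60)) {
  stopifnot(all(abs(verticalAngles) <= 90), all(abs(horizontalAngles) <= 90))
  views <- rbind(
    data.frame(axis = "ap", angle_deg = 0, is_baseline = TRUE),
    if (length(verticalAngles))
      data.frame(axis = "vertical", angle_deg = verticalAngles,
                 is_baseline = FALSE),
    if (length(horizontalAngles))
      data.frame(axis = "horizontal", angle_deg = horizontalAngles,
                 is_baseline = FALSE))
  if (anyDuplicated(views[, c("axis", "angle_deg")]))
    stop("duplicate (axis, angle) pairs in view set")
  views$inplane_deg <- 0
  rownames(views) <- NULL
  views
}

#' Randomly jitter a view set for augmentation
#'
#' Perturbs each view's projection angle uniformly within
#' `+/-angleJitterDeg` and attaches an in-plane image rotation drawn
#' uniformly within `+/-inplaneJitterDeg` (both default 3 degrees).
#' Deterministic for a fixed seed; jitter ranges of 0 return the views
#' unchanged.
#'
#' @param views a view table from [makeViewSet()].
#' @param angleJitterDeg half-range of the projection-angle jitter.
#' @param inplaneJitterDeg half-range of the in-plane rotation jitter.
#' @param seed integer seed.
#' @return the jittered view table.
#' @export
augmentViews <- function(views, angleJitterDeg = 3, inplaneJitterDeg = 3,
                         seed = 1L) {
  stopifnot(angleJitterDeg >= 0, inplaneJitterDeg >= 0)
  withSeed(seed, {
    n <- nrow(views)
    if (angleJitterDeg > 0)
      views$angle_deg <- views$angle_deg +
        stats::runif(n, -angleJitterDeg, angleJitterDeg)
    if (inplaneJitterDeg > 0)
      views$inplane_deg <- views$inplane_deg +
        stats::runif(n, -inplaneJitterDeg, inplaneJitterDeg)
    views
  })
}

# centroid and bounding box (mm) of a nonempty mask
maskGeometry <- function(regionMask, sp) {
  idx <- which(regionMask)
  if (length(idx) == 0L) stop("region mask is empty")
  ii <- arrayInd(idx, dim(regionMask))
  mm <- sweep(ii - 0.5, 2, sp, "*")
  list(center = colMeans(mm),
       lo = apply(mm, 2, min) - sp / 2, hi = apply(mm, 2, max) + sp / 2)
}

rotAboutAxis <- function(axis, deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    ap = diag(3),
    vertical = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),     # about z
    horizontal = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),   # about x
    ray = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),          # about y
    stop("unknown rotation axis: ", axis))
}

#' Render one masked maximum-intensity projection
#'
#' Casts rays through the volume in the view frame obtained by rotating the
#' anteroposterior direction about the chosen axis, centred on the region
#' mask's centroid (so the lung stays in frame under rotation). Each ray
#' sample interpolates HU trilinearly (an implicit isotropic resampling) and
#' is gated by the nearest-neighbour-sampled region mask; the per-pixel
#' maximum is then windowed to \[0, 1\]. Because the mask gate is
#' nearest-neighbour and applied per sample, the projection over a union of
#' regions equals the pixelwise maximum of the per-region projections
#' exactly, and masked-out high-attenuation structures can never win the
#' maximum. Pixels whose ray never meets the region render as exactly 0 (the
#' window floor).
#'
#' @param vol a [CTVolume-class].
#' @param regionMask logical 3D array (nonempty), e.g. from
#'   [combineLayers()].
#' @param view one row of a [makeViewSet()] table (or a list with `axis`,
#'   `angle_deg`, `inplane_deg`).
#' @param window numeric(2): display window (level, width) in HU. Default
#'   c(200, 700), a CT-angiography-like window.
#' @param outSize output image side in pixels (>= 8), default 224.
#' @param sideMM physical side length (mm) of the square field of view;
#'   default: the maximum volume extent, so the whole lung fits at any
#'   rotation.
#' @param rayStepMM ray sampling step in mm; default `min(spacing)`.
#' @param frameMask optional mask defining the rotation centre and the
#'   sampled bounding box (default: `regionMask`). Rendering every masking
#'   scheme of one lung with the lung's *full* mask as the frame keeps the
#'   images of all schemes in a common geometry, and makes the projection
#'   over a union of regions exactly the pixelwise maximum of the per-region
#'   projections.
#' @param geom optional precomputed frame geometry (internal; lets
#'   [renderMIPSet()] share it across views).
#' @return outSize x outSize matrix with values in \[0, 1\].
#' @export
renderMIP <- function(vol, regionMask, view, window = c(200, 700),
                      outSize = 224L, sideMM = NULL, rayStepMM = NULL,
                      frameMask = NULL, geom = NULL) {
  stopifnot(is(vol, "CTVolume"))
  if (!identical(dim(vol@data), dim(regionMask)))
    stop("mask and volume grids differ")
  if (!any(regionMask)) stop("region mask is empty")
  if (is.null(geom))
    geom <- maskGeometry(if (is.null(frameMask)) regionMask else frameMask,
                         vol@spacing)
  if (outSize < 8L) stop("outSize must be >= 8 pixels")
  if (is.data.frame(view)) view <- as.list(view[1, ])

  sp <- vol@spacing
  gs <- dim(vol@data)
  ext <- gs * sp
  if (is.null(sideMM)) sideMM <- max(ext)
  if (is.null(rayStepMM)) rayStepMM <- min(sp)
  # even sample count: on even isotropic grids the baseline-view rays then
  # sample exactly at voxel centres (no interpolation at 0 degrees)
  nt <- ceiling(sqrt(sum(ext^2)) / rayStepMM)
  if (nt %% 2L == 1L) nt <- nt + 1L
  rayLen <- nt * rayStepMM

  R <- rotAboutAxis(view$axis, view$angle_deg) %*%
    rotAboutAxis("ray", if (is.null(view$inplane_deg)) 0 else view$inplane_deg)
  raw <- cpp_render_mip(as.numeric(vol@data), as.logical(regionMask), gs, sp,
                        R, geom$center, as.integer(outSize), sideMM, rayLen,
                        rayStepMM, geom$lo, geom$hi)
  lo <- window[1] - window[2] / 2
  img <- (raw - lo) / window[2]
  img[is.na(img)] <- 0
  pmin(pmax(img, 0), 1)
}

#' Render a full MIPSet for one lung under one masking scheme
#'
#' @inheritParams renderMIP
#' @param views view table from [makeViewSet()] (optionally jittered with
#'   [augmentViews()]).
#' @param scheme masking-scheme name recorded in the result.
#' @param side "left" or "right".
#' @return A [MIPSet-class].
#' @export
renderMIPSet <- function(vol, regionMask, views = makeViewSet(),
                         window = c(200, 700), outSize = 224L,
                         scheme = "full", side = "left", sideMM = NULL,
                         rayStepMM = NULL, frameMask = NULL) {
  if (!any(regionMask)) stop("region mask is empty")
  geom <- maskGeometry(if (is.null(frameMask)) regionMask else frameMask,
                       vol@spacing)
  imgs <- array(0, c(outSize, outSize, nrow(views)))
  for (k in seq_len(nrow(views)))
    imgs[, , k] <- renderMIP(vol, regionMask, views[k, ], window, outSize,
                             sideMM, rayStepMM, geom = geom)
  new("MIPSet", images = imgs, views = views, scheme = scheme, side = side,
      window = window)
}
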