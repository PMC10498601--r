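#' Segmentation parameters for Hounsfield-range thresholding
#'
#' The effective behavior of level-set thresholding as used for CT anatomy:
#' an inclusive HU window, optional Gaussian smoothing of the binary mask
#' (re-binarized at 0.5), and removal of small connected components.
#'
#' @param hu_lo,hu_hi Inclusive HU window bounds; `hu_lo < hu_hi`.
#' @param smoothing_sigma Gaussian sigma in mm applied to the binary mask
#'   (0 = off).
#' @param min_component_voxels Connected components (26-connectivity) smaller
#'   than this are removed (0 = keep all).
#' @return A `voxflap_segparams` object.
#' @export
segmentation_params <- function(hu_lo, hu_hi, smoothing_sigma = 0,
                                min_component_voxels = 0) {
  assert_that(is.numeric(hu_lo) && is.numeric(hu_hi) && hu_lo < hu_hi,
              "hu_lo must be strictly less than hu_hi")
  assert_that(smoothing_sigma >= 0, "smoothing_sigma must be >= 0 mm")
  assert_that(min_component_voxels >= 0, "min_component_voxels must be >= 0")
  structure(list(hu_lo = hu_lo, hu_hi = hu_hi,
                 smoothing_sigma = smoothing_sigma,
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "voxflap_segparams")
}

#' Segment a structure by Hounsfield range
#'
#' The mask is 1 exactly where `hu_lo <= HU <= hu_hi` (inclusive at both
#' ends), then optionally Gaussian-smoothed and re-binarized at 0.5, then
#' stripped of connected components smaller than `min_component_voxels`.
#' An all-zero result is valid and reported with a warning.
#'
#' @param vol A [scalar_volume].
#' @param params A [segmentation_params].
#' @param structure Structure name attached to the result.
#' @return A [label_mask] sharing the volume's geometry.
#' @export
threshold_segment <- function(vol, params, structure = "other") {
  stopifnot(inherits(vol, "voxflap_volume"),
            inherits(params, "voxflap_segparams"))
  m <- vol$data >= params$hu_lo & vol$data <= params$hu_hi
  if (params$smoothing_sigma > 0) {
    sm <- gauss_smooth_3d(array(as.numeric(m), dim(m)),
                          params$smoothing_sigma, vol$spacing)
    m <- sm >= 0.5
  }
  if (params$min_component_voxels > 0 && any(m)) {
    lab <- label_components_cpp(as.integer(m), dim(m), 26L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= params$min_component_voxels)
    m <- array(lab %in% keep & lab > 0L, dim(m))
  }
  if (!any(m))
    warning(sprintf("segmentation of '%s' in [%g, %g] HU is empty",
                    structure, params$hu_lo, params$hu_hi))
  label_mask(m, vol, structure = structure)
}

#' Sample a reference HU range from a spherical ROI
#'
#' Mirrors taking an intensity sample from the descending aorta: the mean HU
#' over a spherical region of interest defines a symmetric segmentation
#' window `mean +/- half_width`. The default half-width of 100 HU turns a
#' 1000 HU contrast sample into the 900-1100 HU vessel window.
#'
#' @param vol A [scalar_volume].
#' @param roi_center World point (mm) at the ROI center.
#' @param roi_radius ROI radius in mm.
#' @param half_width Half-width of the returned HU window (default 100).
#' @return List with `mean_hu` and `params` (a [segmentation_params]).
#' @export
sample_reference_range <- function(vol, roi_center, roi_radius,
                                   half_width = 100) {
  stopifnot(inherits(vol, "voxflap_volume"))
  assert_that(is_point3(roi_center) && roi_radius > 0,
              "roi_center must be a world point and roi_radius > 0")
  hit <- rasterize_capsules(dim(vol$data), vol$spacing, vol$origin,
                            list(list(p0 = roi_center, p1 = roi_center)),
                            roi_radius)
  if (!any(hit))
    stop_voxflap("ROI contains no voxel centers (outside the volume?)",
                 "voxflap_empty_roi")
  mu <- mean(vol$data[hit])
  list(mean_hu = mu,
       params = segmentation_params(mu - half_width, mu + half_width))
}

#' Scripted brush stroke
#'
#' Deterministic stand-in for manual freeform mask editing: a polyline of
#' world points swept by a sphere of the given radius (a chain of capsules).
#'
#' @param mode "fill" sets swept voxels to 1; "erase" sets them to 0.
#' @param centers n x 3 matrix (or length-3 vector) of world points (mm).
#' @param radius Brush radius in mm, > 0.
#' @return A `voxflap_brush` object.
#' @export
brush_stroke <- function(mode = c("fill", "erase"), centers, radius) {
  mode <- match.arg(mode)
  if (is.null(dim(centers))) centers <- matrix(centers, nrow = 1)
  centers <- as.matrix(centers)
  assert_that(ncol(centers) == 3 && nrow(centers) >= 1,
              "centers must be an n x 3 matrix with at least one point")
  assert_that(is.numeric(radius) && length(radius) == 1 && radius > 0,
              "radius must be a single positive number (mm)")
  structure(list(mode = mode, centers = centers, radius = radius),
            class = "voxflap_brush")
}

#' Apply a brush stroke to a mask
#'
#' Voxels whose centers lie within `radius` of the polyline through the
#' stroke centers are set to 1 (fill) or 0 (erase). Geometry is unchanged.
#'
#' @param mask A [label_mask].
#' @param stroke A [brush_stroke], or a list of them applied in order.
#' @return The edited [label_mask].
#' @export
apply_brush <- function(mask, stroke) {
  stopifnot(inherits(mask, "voxflap_mask"))
  if (is.list(stroke) && !inherits(stroke, "voxflap_brush")) {
    for (s in stroke) mask <- apply_brush(mask, s)
    return(mask)
  }
  stopifnot(inherits(stroke, "voxflap_brush"))
  ctr <- stroke$centers
  segs <- if (nrow(ctr) == 1) {
    list(list(p0 = ctr[1, ], p1 = ctr[1, ]))
  } else {
    lapply(seq_len(nrow(ctr) - 1),
           function(i) list(p0 = ctr[i, ], p1 = ctr[i + 1, ]))
  }
  hit <- rasterize_capsules(dim(mask$data), mask$spacing, mask$origin,
                            segs, stroke$radius)
  d <- mask$data
  d[hit] <- if (stroke$mode == "fill") 1L else 0L
  label_mask(d, mask, structure = mask$structure)
}
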