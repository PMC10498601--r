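#' Measured-grid plane array specification
#'
#' Two orthogonal families of parallel world-space planes, spaced
#' `spacing` mm apart with a plane of each family through `anchor` (the
#' umbilicus). Each plane carries a linear halo of the given `strength` that
#' fades to zero at `falloff` mm, so one band is `2 * falloff` mm wide
#' between zero crossings; the defaults (strength 100%, falloff 1 mm,
#' spacing 10 mm) give 2 mm bands on a 1 cm grid.
#'
#' @param spacing Plane spacing in mm (default 10); must exceed
#'   `2 * falloff` so bands cannot merge.
#' @param falloff Halo fall-off distance in mm (default 1).
#' @param strength Peak halo value in (0, 1\] (default 1 = 100%).
#' @param anchor World point (mm) on which both families are centered.
#' @param normals 2 x 3 matrix of unit plane normals, orthogonal to each
#'   other; default patient left-right (x) and superior-inferior (y).
#' @return A `voxflap_planes` object.
#' @export
plane_array_spec <- function(spacing = 10, falloff = 1, strength = 1,
                             anchor = c(0, 0, 0),
                             normals = rbind(c(1, 0, 0), c(0, 1, 0))) {
  assert_that(falloff > 0, "falloff must be > 0 mm")
  assert_that(spacing > 2 * falloff,
              "spacing must exceed 2 * falloff (bands must not merge)")
  assert_that(strength > 0 && strength <= 1, "strength must be in (0, 1]")
  assert_that(is_point3(anchor), "anchor must be a world point (mm)")
  normals <- matrix(as.numeric(normals), 2, 3)
  lens <- sqrt(rowSums(normals^2))
  assert_that(all(abs(lens - 1) < 1e-6), "normals must be unit vectors")
  assert_that(abs(sum(normals[1, ] * normals[2, ])) < 1e-6,
              "normals must be orthogonal")
  structure(list(spacing = spacing, falloff = falloff, strength = strength,
                 anchor = as.numeric(anchor), normals = normals),
            class = "voxflap_planes")
}

#' Evaluate the plane-halo field on a grid
#'
#' For each voxel center, `d` is the perpendicular distance to the nearest
#' plane of either family and the field is
#' `strength * max(0, 1 - d / falloff)`: a linear halo that peaks on each
#' plane and reaches zero at the fall-off distance. Values from the two
#' families combine by maximum, so band crossings never exceed `strength`.
#'
#' @param pspec A [plane_array_spec].
#' @param grid_spec A [grid_spec].
#' @return 3D field array on the grid.
#' @export
plane_field <- function(pspec, grid_spec) {
  stopifnot(inherits(pspec, "voxflap_planes"),
            inherits(grid_spec, "voxflap_gridspec"))
  d <- grid_spec$dims
  ax <- lapply(1:3, function(a)
    grid_spec$origin[a] + (seq_len(d[a]) - 1) * grid_spec$voxel_size)
  dist_family <- function(nrm) {
    # signed offset is separable across axes: u = sum_a nrm[a] * (x_a - anchor_a)
    u <- outer(outer(nrm[1] * (ax[[1]] - pspec$anchor[1]),
                     nrm[2] * (ax[[2]] - pspec$anchor[2]), "+"),
               nrm[3] * (ax[[3]] - pspec$anchor[3]), "+")
    abs(u - pspec$spacing * round(u / pspec$spacing))
  }
  dmin <- pmin(dist_family(pspec$normals[1, ]), dist_family(pspec$normals[2, ]))
  f <- pspec$strength * pmax(0, 1 - dmin / pspec$falloff)
  dim(f) <- d
  f
}

#' Stamp the measured grid onto a base structure
#'
#' Writes the plane-halo field into a material channel of the base grid via
#' superseding material arithmetic ([material_add()] with `combine = "max"`),
#' so only voxels inside the base shape receive grid material, the operation
#' is idempotent, and the shape channel is returned bit-identical: the grid
#' recolors the muscle without altering its morphology.
#'
#' @param base A `voxflap_grid` with the target material declared.
#' @param pspec A [plane_array_spec].
#' @param material Material channel name (default "grid").
#' @return The recolored `voxflap_grid`.
#' @export
apply_grid_overlay <- function(base, pspec, material = "grid") {
  stopifnot(inherits(base, "voxflap_grid"))
  f <- plane_field(pspec, base$spec)
  material_add(base, f, material, weight = 1, combine = "max")
}

#' Map perforator locations to measured-grid coordinates
#'
#' Projects each world point onto the two plane normals relative to the
#' anchor, giving signed offsets (u, v) in mm; the grid cell is
#' `floor(offset / spacing)` per axis (half-open cells, 0-based,
#' anchor-centered) and the offsets are also reported in cm to one decimal.
#'
#' @param points n x 3 matrix (or length-3 vector) of world points (mm).
#' @param pspec A [plane_array_spec].
#' @return Data frame with columns `point_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `cell_u`, `cell_v`, `offset_u_cm`, `offset_v_cm`.
#' @export
map_perforators_to_grid <- function(points, pspec) {
  stopifnot(inherits(pspec, "voxflap_planes"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  assert_that(ncol(points) == 3, "points must be n x 3 world coordinates")
  rel <- sweep(points, 2, pspec$anchor)
  u <- as.numeric(rel %*% pspec$normals[1, ])
  v <- as.numeric(rel %*% pspec$normals[2, ])
  data.frame(point_id = seq_len(nrow(points)),
             x_mm = points[, 1], y_mm = points[, 2], z_mm = points[, 3],
             cell_u = floor(u / pspec$spacing),
             cell_v = floor(v / pspec$spacing),
             offset_u_cm = round(u / 10, 1),
             offset_v_cm = round(v / 10, 1))
}

#' Write a perforator grid-coordinate report
#'
#' @param report Data frame from [map_perforators_to_grid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_perforator_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
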