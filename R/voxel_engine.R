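#' Voxel grid specification
#'
#' An isotropic voxel lattice over an axis-aligned world box. The box is
#' expanded by `padding` on every side (so isosurfaces can close at the grid
#' border) and discretized at `voxel_size`; voxel centers sit at
#' `origin + (index - 1) * voxel_size`.
#'
#' @param bounds 2 x 3 matrix, rows = (lo, hi) world corners in mm.
#' @param voxel_size Isotropic voxel edge length in mm (default 0.5).
#' @param padding Extra margin in mm added on every side (default 2).
#' @return A `voxflap_gridspec` object with `dims` and `origin` computed.
#' @export
grid_spec <- function(bounds, voxel_size = 0.5, padding = 2) {
  bounds <- matrix(as.numeric(bounds), 2, 3)
  assert_that(voxel_size > 0, "voxel_size must be > 0")
  assert_that(padding >= 0, "padding must be >= 0")
  lo <- bounds[1, ] - padding
  hi <- bounds[2, ] + padding
  assert_that(all(hi > lo), "bounds are degenerate after padding")
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size - 1e-9)))
  structure(list(voxel_size = voxel_size, bounds = bounds, padding = padding,
                 dims = dims, origin = lo + voxel_size / 2),
            class = "voxflap_gridspec")
}

#' @export
print.voxflap_gridspec <- function(x, ...) {
  cat(sprintf("<voxflap_gridspec> %s voxels @ %g mm, origin %s mm\n",
              paste(x$dims, collapse = "x"), x$voxel_size,
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Grid specification aligned to a volume's voxel lattice
#'
#' Builds a [grid_spec] whose voxels nest exactly in the volume's: with
#' `voxel_size` equal to the (isotropic) volume spacing the grid reproduces
#' the volume lattice, and with an integer refinement (e.g. half the spacing)
#' every source voxel maps to an exact block of grid voxels.
#'
#' @param x A [scalar_volume] or [label_mask].
#' @param voxel_size Grid voxel size in mm; must divide the volume spacing
#'   evenly for exact nesting (not enforced).
#' @param padding Margin in mm; rounded up to a multiple of `voxel_size` to
#'   preserve alignment.
#' @return A `voxflap_gridspec`.
#' @export
grid_spec_from_volume <- function(x, voxel_size = NULL, padding = 0) {
  sp <- x$spacing
  assert_that(max(abs(sp - sp[1])) < 1e-9,
              "volume spacing must be isotropic for an aligned grid")
  voxel_size <- voxel_size %||% sp[1]
  padding <- ceiling(padding / voxel_size) * voxel_size
  lo <- x$origin - sp / 2
  hi <- x$origin + (dim(x$data) - 1) * sp + sp / 2
  grid_spec(rbind(lo, hi), voxel_size = voxel_size, padding = padding)
}

same_spec <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    abs(a$voxel_size - b$voxel_size) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Multi-channel voxel grid
#'
#' The compositing substrate: one shape channel (occupancy/density in
#' \[0, 1\]) plus named material channels in \[0, 1\]. Material weight is
#' meaningful only where shape > 0, and the per-voxel material sum never
#' exceeds 1 (+ 1e-6).
#'
#' @param spec A [grid_spec].
#' @param materials Character vector of declared material channel names.
#' @param shape Optional initial shape array (defaults to all zero).
#' @return A `voxflap_grid` object.
#' @export
multichannel_grid <- function(spec, materials = character(), shape = NULL) {
  stopifnot(inherits(spec, "voxflap_gridspec"))
  if (is.null(shape)) shape <- array(0, spec$dims)
  assert_that(identical(dim(shape), as.integer(spec$dims)) ||
                identical(dim(shape), spec$dims),
              "shape array does not match the grid dimensions")
  assert_that(min(shape) >= 0 && max(shape) <= 1, "shape must lie in [0,1]")
  mats <- stats::setNames(
    lapply(materials, function(m) array(0, spec$dims)), materials)
  structure(list(spec = spec, shape = shape, materials = mats),
            class = "voxflap_grid")
}

#' @export
print.voxflap_grid <- function(x, ...) {
  cat(sprintf("<voxflap_grid> %s voxels @ %g mm, occupied volume %.1f mm^3\n",
              paste(x$spec$dims, collapse = "x"), x$spec$voxel_size,
              sum(x$shape) * x$spec$voxel_size^3))
  if (length(x$materials))
    cat("  materials:", paste(names(x$materials), collapse = ", "), "\n")
  invisible(x)
}

#' Rasterize a label mask onto a grid
#'
#' Nearest-neighbor resampling of the mask onto the grid's voxel centers.
#' For a grid aligned to the mask lattice (see [grid_spec_from_volume()])
#' this is exact: identity at equal spacing, block refinement at finer
#' spacing. An empty mask yields a valid empty grid with a warning.
#'
#' @param mask A [label_mask].
#' @param spec A [grid_spec].
#' @param materials Material channels to declare on the result.
#' @return A `voxflap_grid` whose shape is the resampled binary mask.
#' @export
from_mask <- function(mask, spec, materials = character()) {
  stopifnot(inherits(mask, "voxflap_mask"), inherits(spec, "voxflap_gridspec"))
  if (sum(mask$data) == 0)
    warning(sprintf("mask '%s' is empty; grid shape will be empty",
                    mask$structure))
  d <- spec$dims
  md <- dim(mask$data)
  idx <- lapply(1:3, function(a) {
    centers <- spec$origin[a] + (seq_len(d[a]) - 1) * spec$voxel_size
    i <- as.integer(round((centers - mask$origin[a]) / mask$spacing[a])) + 1L
    list(i = pmin(pmax(i, 1L), md[a]), ok = i >= 1L & i <= md[a])
  })
  shape <- array(as.numeric(
    mask$data[idx[[1]]$i, idx[[2]]$i, idx[[3]]$i]), d)
  if (!all(idx[[1]]$ok)) shape[!idx[[1]]$ok, , ] <- 0
  if (!all(idx[[2]]$ok)) shape[, !idx[[2]]$ok, ] <- 0
  if (!all(idx[[3]]$ok)) shape[, , !idx[[3]]$ok] <- 0
  multichannel_grid(spec, materials = materials, shape = shape)
}

#' Voxelize a watertight triangle mesh
#'
#' Occupancy by the parity (even-odd) rule: a voxel is inside iff a +x ray
#' through its center crosses the surface an odd number of times. Rays are
#' offset by a fixed sub-voxel jitter so they cannot hit triangle edges or
#' vertices; the offset is deterministic, so voxelization is reproducible.
#'
#' @param mesh A [triangle_mesh]; must be watertight (checked first; the
#'   error reports the open-edge count).
#' @param spec A [grid_spec].
#' @param materials Material channels to declare on the result.
#' @return A `voxflap_grid` with binary shape.
#' @export
voxelize_mesh <- function(mesh, spec, materials = character()) {
  stopifnot(inherits(mesh, "voxflap_mesh"), inherits(spec, "voxflap_gridspec"))
  wt <- check_watertight(mesh)
  if (!wt$passes)
    stop_voxflap(sprintf(
      "mesh is not watertight: %d open edges, %d non-manifold edges, %d flipped pairs, signed volume %.3f mm^3",
      wt$open_edges, wt$nonmanifold_edges, wt$flipped_pairs,
      wt$signed_volume_mm3), "voxflap_geometry_error", report = wt)
  occ <- voxelize_raycast_cpp(mesh$vertices, mesh$faces, spec$dims,
                              spec$origin, rep(spec$voxel_size, 3))
  multichannel_grid(spec, materials = materials,
                    shape = array(as.numeric(occ), spec$dims))
}

#' Compositing layer
#'
#' One entry of a [layer_stack]. Boolean operations (`replace`, `add`,
#' `subtract`) target the shape channel; `material_add` targets a named
#' material channel and leaves the morphology untouched.
#'
#' @param source A [label_mask], [triangle_mesh], `voxflap_grid` (same spec),
#'   plain array, or a function `function(spec)` returning a field array
#'   (e.g. [plane_field()] curried over its spec).
#' @param op One of "replace", "add", "subtract", "material_add".
#' @param target "shape" or "material:<name>".
#' @param weight Weight for `material_add` (default 1).
#' @return A `voxflap_layer`.
#' @export
layer <- function(source, op = c("replace", "add", "subtract", "material_add"),
                  target = "shape", weight = 1) {
  op <- match.arg(op)
  if (op == "material_add") {
    assert_that(startsWith(target, "material:"),
                "material_add must target a 'material:<name>' channel")
  } else {
    assert_that(target == "shape",
                sprintf("op '%s' must target the shape channel", op))
  }
  structure(list(source = source, op = op, target = target, weight = weight),
            class = "voxflap_layer")
}

#' Ordered layer stack
#'
#' Layers are evaluated strictly bottom-up; layer 1 is the base and must
#' `replace` the shape channel.
#'
#' @param ... [layer()] objects (or a single list of them).
#' @return A `voxflap_stack`.
#' @export
layer_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "voxflap_layer"))
    layers <- layers[[1]]
  assert_that(length(layers) >= 1, "a layer stack needs at least one layer")
  assert_that(all(vapply(layers, inherits, logical(1), "voxflap_layer")),
              "all stack entries must be layers")
  assert_that(layers[[1]]$op == "replace" && layers[[1]]$target == "shape",
              "layer 1 (the base) must 'replace' the shape channel")
  structure(list(layers = layers), class = "voxflap_stack")
}

# Evaluate a layer source to a field array on `spec`.
source_field <- function(source, spec) {
  if (inherits(source, "voxflap_mask")) return(from_mask(source, spec)$shape)
  if (inherits(source, "voxflap_mesh")) return(voxelize_mesh(source, spec)$shape)
  if (inherits(source, "voxflap_grid")) {
    assert_that(same_spec(source$spec, spec),
                "layer grid does not share the stack's grid spec",
                class = "voxflap_geometry_error")
    return(source$shape)
  }
  if (is.function(source)) {
    f <- source(spec)
    assert_that(identical(dim(f), as.integer(spec$dims)) ||
                  identical(dim(f), spec$dims),
                "layer field function returned wrong dimensions")
    return(f)
  }
  if (is.array(source)) {
    assert_that(identical(dim(source), as.integer(spec$dims)) ||
                  identical(dim(source), spec$dims),
                "layer array has wrong dimensions")
    return(source)
  }
  stop_voxflap("unsupported layer source type", "voxflap_config_error")
}

#' Evaluate a layer stack bottom-up
#'
#' Boolean layers act on binarized occupancy (threshold 0.5):
#' `subtract` gives `max(0, below - layer)` (voids), `add` gives
#' `min(1, below + layer)`. `material_add` layers write into their material
#' channel via [material_add()] and leave the shape untouched. Evaluation
#' order is strictly bottom-up, so subtraction is order-sensitive.
#'
#' @param stack A [layer_stack].
#' @param spec A [grid_spec].
#' @param materials Declared material channels; a `material_add` layer whose
#'   target is not declared raises a configuration error.
#' @return The composited `voxflap_grid`.
#' @export
composite <- function(stack, spec, materials = NULL) {
  stopifnot(inherits(stack, "voxflap_stack"), inherits(spec, "voxflap_gridspec"))
  if (is.null(materials)) {
    tg <- vapply(stack$layers, `[[`, character(1), "target")
    materials <- unique(sub("^material:", "", tg[startsWith(tg, "material:")]))
  }
  grid <- multichannel_grid(spec, materials = materials)
  for (li in seq_along(stack$layers)) {
    ly <- stack$layers[[li]]
    f <- source_field(ly$source, spec)
    if (ly$op == "material_add") {
      mat <- sub("^material:", "", ly$target)
      grid <- material_add(grid, f, mat, weight = ly$weight)
    } else {
      fb <- as.numeric(f > 0.5)
      grid$shape <- switch(ly$op,
        replace = array(fb, spec$dims),
        add = pmin(1, grid$shape + fb),
        subtract = pmax(0, grid$shape - fb))
      dim(grid$shape) <- spec$dims
    }
  }
  # material weight must vanish where shape does
  if (length(grid$materials)) {
    zero <- grid$shape == 0
    for (m in names(grid$materials)) grid$materials[[m]][zero] <- 0
  }
  grid
}

#' Add material weight by channel arithmetic
#'
#' Writes `weight * support` into one material channel for voxels with
#' support > 0 and shape > 0, clamped to 1, then proportionally scales the
#' *other* channels down wherever the per-voxel material sum would exceed 1.
#' The shape channel is returned bit-identical: material operations change
#' color only, never morphology.
#'
#' @param grid A `voxflap_grid`.
#' @param support 3D field (same dimensions) of weights in \[0, 1\].
#' @param material Declared material channel name.
#' @param weight Scalar in (0, 1\].
#' @param combine "add" accumulates (`min(1, existing + weight * support)`);
#'   "max" supersedes (`max(existing, weight * support)`), which is
#'   idempotent and used by the measured-grid overlay.
#' @return The updated `voxflap_grid`.
#' @export
material_add <- function(grid, support, material, weight = 1,
                         combine = c("add", "max")) {
  stopifnot(inherits(grid, "voxflap_grid"))
  combine <- match.arg(combine)
  if (!material %in% names(grid$materials))
    stop_voxflap(sprintf(
      "material '%s' is not declared on this grid (declared: %s)",
      material, paste(names(grid$materials), collapse = ", ") %||% "none"),
      "voxflap_config_error")
  assert_that(identical(dim(support), dim(grid$shape)),
              "support field dimensions do not match the grid")
  assert_that(weight > 0 && weight <= 1, "weight must be in (0, 1]")
  sel <- which(support > 0 & grid$shape > 0)
  if (length(sel) == 0) return(grid)
  m <- grid$materials[[material]]
  new_val <- if (combine == "add") {
    pmin(1, m[sel] + weight * support[sel])
  } else {
    pmax(m[sel], weight * support[sel])
  }
  m[sel] <- new_val
  others <- setdiff(names(grid$materials), material)
  if (length(others)) {
    total <- new_val
    for (o in others) total <- total + grid$materials[[o]][sel]
    over <- which(total > 1)
    if (length(over)) {
      scl <- (1 - new_val[over]) / (total[over] - new_val[over])
      for (o in others) {
        ch <- grid$materials[[o]]
        ch[sel[over]] <- ch[sel[over]] * scl
        grid$materials[[o]] <- ch
      }
    }
  }
  grid$materials[[material]] <- m
  grid
}

#' Classify vessel voxels by muscle containment
#'
#' Splits the vessel occupancy into the intra-muscular part (vessel voxels
#' where the pre-subtraction muscle shape exceeds 0.5) and the extra-muscular
#' remainder. The two masks are disjoint and together cover the vessel
#' support exactly.
#'
#' @param vessels,muscle `voxflap_grid`s on the same spec; `muscle` is the
#'   muscle *before* vessel subtraction.
#' @return List of two [label_mask]s: `intra` and `extra`.
#' @export
classify_by_containment <- function(vessels, muscle) {
  stopifnot(inherits(vessels, "voxflap_grid"), inherits(muscle, "voxflap_grid"))
  if (!same_spec(vessels$spec, muscle$spec))
    stop_voxflap("vessel and muscle grids do not share a grid spec",
                 "voxflap_geometry_error")
  vs <- vessels$shape > 0.5
  ms <- muscle$shape > 0.5
  geo <- list(spacing = rep(vessels$spec$voxel_size, 3),
              origin = vessels$spec$origin)
  list(intra = label_mask(vs & ms, geo, structure = "vessels_intra"),
       extra = label_mask(vs & !ms, geo, structure = "vessels_extra"))
}

#' Volume of a grid channel
#'
#' Sum of the channel values times the voxel volume.
#'
#' @param grid A `voxflap_grid`.
#' @param channel "shape" or "material:<name>".
#' @return Volume in mm^3.
#' @export
measure_volume <- function(grid, channel = "shape") {
  stopifnot(inherits(grid, "voxflap_grid"))
  f <- grid_channel(grid, channel)
  sum(f) * grid$spec$voxel_size^3
}

grid_channel <- function(grid, channel) {
  if (channel == "shape") return(grid$shape)
  if (startsWith(channel, "material:")) {
    m <- sub("^material:", "", channel)
    if (m %in% names(grid$materials)) return(grid$materials[[m]])
  }
  stop_voxflap(sprintf("unknown channel '%s'", channel),
               "voxflap_config_error")
}

#' Write grid channels to NIfTI for inspection
#'
#' One file per channel: `<prefix>_shape.nii.gz` and
#' `<prefix>_material_<name>.nii.gz`.
#'
#' @param grid A `voxflap_grid`.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_grid_channels <- function(grid, prefix) {
  geo <- list(spacing = rep(grid$spec$voxel_size, 3), origin = grid$spec$origin)
  paths <- character(0)
  fake_vol <- function(arr) scalar_volume(arr, geo$spacing, geo$origin)
  p <- paste0(prefix, "_shape.nii.gz")
  write_volume(fake_vol(grid$shape), p)
  paths <- c(paths, p)
  for (m in names(grid$materials)) {
    p <- paste0(prefix, "_material_", m, ".nii.gz")
    write_volume(fake_vol(grid$materials[[m]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
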