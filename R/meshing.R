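#' Triangle mesh in world coordinates
#'
#' Vertices in mm, triangles as 1-based vertex index triples with consistent
#' outward winding. An empty mesh (0 vertices, 0 triangles) is permitted as
#' the degenerate result of splitting operations.
#'
#' @param vertices n x 3 numeric matrix of world points (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return A `voxflap_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0)
    assert_that(min(faces) >= 1 && max(faces) <= nrow(vertices),
                "face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "voxflap_mesh")
}

#' @export
print.voxflap_mesh <- function(x, ...) {
  cat(sprintf("<voxflap_mesh> %d vertices, %d triangles, signed volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Signed volume enclosed by a mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed, outward-oriented surface.
#'
#' @param mesh A [triangle_mesh].
#' @return Signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Watertightness and orientation report
#'
#' Counts open edges (used by exactly one triangle), non-manifold edges
#' (more than two), and flipped-winding pairs (an edge traversed twice in
#' the same direction). A mesh passes iff all three counts are zero and the
#' signed volume is positive. Report-only: no error is raised.
#'
#' @param mesh A [triangle_mesh].
#' @return List with `open_edges`, `nonmanifold_edges`, `flipped_pairs`,
#'   `signed_volume_mm3`, `n_vertices`, `n_triangles`, and `passes`.
#' @export
check_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "voxflap_mesh"))
  nf <- nrow(mesh$faces)
  if (nf == 0)
    return(list(open_edges = 0L, nonmanifold_edges = 0L, flipped_pairs = 0L,
                signed_volume_mm3 = 0, n_vertices = nrow(mesh$vertices),
                n_triangles = 0L, passes = FALSE))
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  nv <- nrow(mesh$vertices)
  key_u <- pmin(from, to) * (nv + 1) + pmax(from, to)
  cnt <- rle(sort(key_u))$lengths
  open_edges <- sum(cnt == 1L)
  nonmanifold <- sum(cnt > 2L)
  key_d <- from * (nv + 1) + to
  dup_dir <- sum(rle(sort(key_d))$lengths >= 2L)
  vol <- mesh_volume(mesh)
  list(open_edges = open_edges, nonmanifold_edges = nonmanifold,
       flipped_pairs = dup_dir, signed_volume_mm3 = vol,
       n_vertices = nv, n_triangles = nf,
       passes = open_edges == 0L && nonmanifold == 0L && dup_dir == 0L &&
                vol > 0)
}

#' Extract a watertight isosurface from a grid channel
#'
#' Marching tetrahedra (Kuhn 6-tetrahedron split of each lattice cube) on
#' the channel field, at `level` (default 0.5 = the midpoint between
#' material absent and full). The field is zero-padded by one virtual voxel
#' layer so support touching the grid border is capped; the tetrahedral
#' contour is unambiguous, so the surface is watertight by construction.
#' Optional Gaussian pre-smoothing (sigma in voxels) reduces the faceting
#' and volume-loss artifacts of extraction from binary data; it is off for
#' conservation-sensitive uses.
#'
#' @param grid A `voxflap_grid`.
#' @param channel "shape" or "material:<name>"; must have non-empty support.
#' @param level Iso level in (0, 1), default 0.5.
#' @param smooth_sigma Pre-extraction Gaussian sigma in voxels
#'   (default 0.5; 0 = off).
#' @return A [triangle_mesh] in world mm.
#' @export
extract_isosurface <- function(grid, channel = "shape", level = 0.5,
                               smooth_sigma = 0.5) {
  stopifnot(inherits(grid, "voxflap_grid"))
  f <- grid_channel(grid, channel)
  if (max(f) == 0)
    stop_voxflap(sprintf("channel '%s' has empty support", channel),
                 "voxflap_empty_surface")
  if (smooth_sigma > 0) f <- gauss_smooth_3d(f, smooth_sigma)
  if (max(f) <= level)
    stop_voxflap(sprintf(
      "channel '%s' has no values above level %g after smoothing",
      channel, level), "voxflap_empty_surface")
  res <- mt_isosurface_cpp(as.numeric(f), grid$spec$dims, grid$spec$origin,
                           rep(grid$spec$voxel_size, 3), level)
  triangle_mesh(res$vertices, res$faces)
}

# Isosurface of an arbitrary binary/real field sharing a grid spec.
field_isosurface <- function(field, spec, level = 0.5, smooth_sigma = 0) {
  if (smooth_sigma > 0) field <- gauss_smooth_3d(field, smooth_sigma)
  if (max(field) <= level) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  res <- mt_isosurface_cpp(as.numeric(field), spec$dims, spec$origin,
                           rep(spec$voxel_size, 3), level)
  triangle_mesh(res$vertices, res$faces)
}

#' Split a grid into material and remainder meshes
#'
#' Voxels inside the shape support whose material fraction exceeds
#' `threshold` are quantized to the material part; all others form the
#' remainder. Both parts are extracted as closed isosurfaces of their binary
#' supports (no smoothing, so the shared interface coincides exactly and the
#' voxel supports partition the shape support). The material field is
#' implicitly trimmed by the shape channel because material weight only
#' exists inside the shape.
#'
#' @param grid A `voxflap_grid`.
#' @param material Material channel name.
#' @param threshold Quantization threshold (default 0.5).
#' @return List with `mesh_mat`, `mesh_rest` ([triangle_mesh], possibly
#'   empty for a degenerate partition), and the binary `support_mat`,
#'   `support_rest` arrays.
#' @export
split_by_material <- function(grid, material, threshold = 0.5) {
  stopifnot(inherits(grid, "voxflap_grid"))
  mf <- grid_channel(grid, paste0("material:", material))
  s <- grid$shape > 0.5
  q <- s & (mf > threshold)
  r <- s & !q
  if (!any(q))
    stop_voxflap(sprintf("material '%s' has empty support inside the shape",
                         material), "voxflap_empty_surface")
  mesh_mat <- field_isosurface(array(as.numeric(q), dim(q)), grid$spec)
  mesh_rest <- field_isosurface(array(as.numeric(r), dim(r)), grid$spec)
  list(mesh_mat = mesh_mat, mesh_rest = mesh_rest,
       support_mat = q, support_rest = r)
}

#' Support strut specification
#'
#' A capsule (cylinder with hemispherical caps) between two world points,
#' used to support fragile vessels, thin muscle and the umbilicus in the
#' printed model.
#'
#' @param endpoints 2 x 3 matrix of distinct world points (mm).
#' @param radius Strut radius in mm (default 1.5).
#' @return A `voxflap_strut`.
#' @export
strut_spec <- function(endpoints, radius = 1.5) {
  endpoints <- matrix(as.numeric(endpoints), 2, 3, byrow = FALSE)
  assert_that(radius > 0, "strut radius must be > 0")
  if (sqrt(sum((endpoints[1, ] - endpoints[2, ])^2)) <= 1e-9)
    stop_voxflap("strut endpoints coincide (zero-length strut)",
                 "voxflap_geometry_error")
  structure(list(endpoints = endpoints, radius = radius),
            class = "voxflap_strut")
}

#' Rasterize a support strut onto a grid
#'
#' Voxelized capsule between the strut endpoints, intended for an additive
#' layer (composited with op `add` it can only grow the base occupancy).
#'
#' @param sspec A [strut_spec].
#' @param grid_spec A [grid_spec].
#' @return A `voxflap_grid` with binary shape.
#' @export
generate_strut <- function(sspec, grid_spec) {
  stopifnot(inherits(sspec, "voxflap_strut"),
            inherits(grid_spec, "voxflap_gridspec"))
  occ <- rasterize_capsules(grid_spec$dims, rep(grid_spec$voxel_size, 3),
                            grid_spec$origin,
                            list(list(p0 = sspec$endpoints[1, ],
                                      p1 = sspec$endpoints[2, ])),
                            sspec$radius)
  multichannel_grid(grid_spec, shape = array(as.numeric(occ), grid_spec$dims))
}

#' Write a mesh as binary STL
#'
#' Little-endian binary STL in mm with per-facet normals recomputed from the
#' winding. Non-watertight meshes are refused, with the [check_watertight()]
#' report attached to the error.
#'
#' @param mesh A [triangle_mesh].
#' @param path Output `.stl` path.
#' @param check Refuse non-watertight meshes (default TRUE).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, check = TRUE) {
  stopifnot(inherits(mesh, "voxflap_mesh"))
  if (check) {
    wt <- check_watertight(mesh)
    if (!wt$passes)
      stop_voxflap(sprintf(
        "refusing to write non-watertight mesh (%d open, %d non-manifold, %d flipped edges, volume %.3f)",
        wt$open_edges, wt$nonmanifold_edges, wt$flipped_pairs,
        wt$signed_volume_mm3), "voxflap_geometry_error", report = wt)
  }
  nf <- nrow(mesh$faces)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  # 50 bytes per facet: 12 float32 then a zero uint16 attribute
  floats <- t(cbind(n, a, b, c_))  # 12 x nf, column = one facet
  fraw <- writeBin(as.numeric(floats), raw(), size = 4, endian = "little")
  if (nf > 0) {
    block <- rbind(matrix(fraw, nrow = 48), matrix(as.raw(0), 2, nf))
  } else {
    block <- raw(0)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "voxflap binary STL (mm)"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  writeBin(as.vector(block), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Vertices are welded by exact float32 coordinate equality, which restores
#' shared vertices written by [write_stl()].
#'
#' @param path Binary STL path.
#' @return A [triangle_mesh].
#' @export
read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  assert_that(sz >= 84 + 50 * nf, "truncated binary STL",
              class = "voxflap_format_error")
  block <- readBin(con, "raw", 50 * nf)
  if (nf == 0) return(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  m <- matrix(block, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", n = 12 * nf, size = 4,
                    endian = "little")
  tri <- matrix(floats, nrow = 12)  # rows 4..12 = v0, v1, v2
  verts <- matrix(as.numeric(tri[4:12, ]), ncol = 3, byrow = TRUE)
  key <- paste(verts[, 1], verts[, 2], verts[, 3], sep = "/")
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(uverts, faces)
}
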