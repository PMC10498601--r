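# Isosurface extraction, material splitting, struts, STL and manifest.

test_that("isosurface of a binary sphere is watertight and volume-accurate", {
  g <- binary_sphere_grid(radius = 5, voxel = 0.5)
  analytic <- 4 / 3 * pi * 5^3
  m <- extract_isosurface(g, smooth_sigma = 0)
  wt <- check_watertight(m)
  expect_true(wt$passes)
  # tolerance pinned from a pre-build run (observed error ~0.6%)
  expect_lt(abs(wt$signed_volume_mm3 - analytic) / analytic, 0.02)
  # smoothing keeps the surface watertight too
  ms <- extract_isosurface(g, smooth_sigma = 0.5)
  expect_true(check_watertight(ms)$passes)
  expect_lt(abs(mesh_volume(ms) - analytic) / analytic, 0.02)
  # the default level is the material-gradient midpoint 0.5
  expect_equal(formals(extract_isosurface)$level, 0.5)
  m05 <- extract_isosurface(g, level = 0.5, smooth_sigma = 0)
  expect_identical(m$vertices, m05$vertices)
})

test_that("support touching the grid border is capped to a closed surface", {
  spec <- grid_spec(rbind(c(0, 0, 0), c(6, 6, 6)), voxel_size = 1,
                    padding = 0)
  g <- multichannel_grid(spec, shape = array(1, spec$dims))  # fills the grid
  m <- extract_isosurface(g, smooth_sigma = 0)
  wt <- check_watertight(m)
  expect_true(wt$passes)
  expect_gt(wt$signed_volume_mm3, 0)
  # empty channel is an error
  expect_error(extract_isosurface(multichannel_grid(spec)),
               class = "voxflap_empty_surface")
})

test_that("voxelizing an extracted surface recovers the support", {
  g <- binary_sphere_grid(radius = 4, voxel = 0.5)
  m <- extract_isosurface(g, smooth_sigma = 0)
  back <- voxelize_mesh(m, g$spec)
  # recovered support within a 1-voxel boundary shell of the original
  diff_idx <- which(back$shape != g$shape)
  expect_equal(length(diff_idx), 0)
})

test_that("material split partitions the shape into coincident closed parts", {
  set.seed(51)
  g <- binary_sphere_grid(radius = 5, voxel = 0.5)
  g <- multichannel_grid(g$spec, materials = "grid", shape = g$shape)
  ps <- plane_array_spec(anchor = c(0.3, -0.2, 0))
  g <- apply_grid_overlay(g, ps)
  split <- split_by_material(g, "grid")
  # voxel supports are disjoint and cover the shape support exactly
  expect_true(all(xor(split$support_mat, split$support_rest) ==
                    (g$shape > 0.5)))
  expect_equal(sum(split$support_mat & split$support_rest), 0)
  expect_true(check_watertight(split$mesh_mat)$passes)
  expect_true(check_watertight(split$mesh_rest)$passes)
  # voxelized split meshes are disjoint at the working resolution
  vm <- voxelize_mesh(split$mesh_mat, g$spec)
  vr <- voxelize_mesh(split$mesh_rest, g$spec)
  expect_equal(sum(vm$shape * vr$shape), 0)

  # degenerate partition: uniform material leaves an empty remainder
  g2 <- multichannel_grid(g$spec, materials = "grid", shape = g$shape)
  g2 <- material_add(g2, array(1, g$spec$dims), "grid", weight = 1)
  split2 <- split_by_material(g2, "grid")
  expect_equal(nrow(split2$mesh_rest$faces), 0)
  # empty material support is an error
  g3 <- multichannel_grid(g$spec, materials = "grid", shape = g$shape)
  expect_error(split_by_material(g3, "grid"),
               class = "voxflap_empty_surface")
})

test_that("struts are analytic capsules and only ever add volume", {
  st <- strut_spec(rbind(c(0, 0, 0), c(10, 0, 0)), radius = 1.5)
  spec <- grid_spec(rbind(c(-2, -2, -2), c(12, 2, 2)), voxel_size = 0.25,
                    padding = 1)
  g <- generate_strut(st, spec)
  analytic <- pi * 1.5^2 * 10 + 4 / 3 * pi * 1.5^3  # 84.82 mm^3
  expect_lt(abs(measure_volume(g) - analytic) / analytic, 0.03)
  m <- extract_isosurface(g, smooth_sigma = 0)
  expect_true(check_watertight(m)$passes)
  expect_lt(abs(mesh_volume(m) - analytic) / analytic, 0.03)

  # additive compositing with a strut never removes base occupancy
  set.seed(61)
  base <- array(as.numeric(runif(prod(spec$dims)) < 0.3), spec$dims)
  added <- composite(layer_stack(layer(base, "replace"),
                                 layer(g, "add")), spec)
  expect_true(all(added$shape >= base))

  expect_error(strut_spec(rbind(c(1, 1, 1), c(1, 1, 1))),
               class = "voxflap_geometry_error")
})

test_that("watertightness report counts defects and orientation", {
  expect_true(check_watertight(cube_mesh())$passes)
  # removing one triangle opens 3 edges
  broken <- cube_mesh()
  broken$faces <- broken$faces[-5, ]
  rep1 <- check_watertight(broken)
  expect_equal(rep1$open_edges, 3)
  expect_false(rep1$passes)
  # removing a whole quad face opens 4 edges
  broken2 <- cube_mesh()
  broken2$faces <- broken2$faces[-c(1, 2), ]
  expect_equal(check_watertight(broken2)$open_edges, 4)
  # an inside-out cube is flagged by negative signed volume
  flipped <- cube_mesh()
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  repf <- check_watertight(flipped)
  expect_lt(repf$signed_volume_mm3, 0)
  expect_false(repf$passes)
})

test_that("binary STL round-trips within float32 rounding", {
  m <- icosphere(5, 2)
  path <- tempfile(fileext = ".stl")
  write_stl(m, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(m$faces))
  expect_equal(nrow(back$vertices), nrow(m$vertices))
  # vertex sets agree to float32 precision
  ord <- function(v) v[order(round(v[, 1], 4), round(v[, 2], 4),
                             round(v[, 3], 4)), ]
  expect_equal(ord(back$vertices), ord(m$vertices), tolerance = 1e-6)
  expect_equal(mesh_volume(back), mesh_volume(m), tolerance = 1e-6)
  expect_true(check_watertight(back)$passes)
  unlink(path)

  # non-watertight meshes are refused with the report attached
  broken <- cube_mesh()
  broken$faces <- broken$faces[-1, ]
  err <- tryCatch(write_stl(broken, tempfile(fileext = ".stl")),
                  error = identity)
  expect_s3_class(err, "voxflap_geometry_error")
  expect_equal(err$report$open_edges, 3)
})

test_that("the default manifest matches the printed material palette", {
  pal <- default_part_materials()
  expect_equal(pal$muscle_remainder$opacity, "clear")
  expect_equal(unname(pal$grid_bands$mixture["cyan"]), 0.8)
  expect_equal(unname(pal$grid_bands$mixture["clear"]), 0.2)
  expect_equal(unname(pal$vessels_extra$mixture["magenta"]), 1.0)
  expect_equal(unname(pal$vessels_intra$mixture["magenta"]), 0.5)
  expect_equal(unname(pal$vessels_intra$mixture["cyan"]), 0.5)
  expect_identical(pal$umbilicus$mixture, pal$struts$mixture)

  m <- cube_mesh()
  part <- print_part("muscle_remainder", m, pal$muscle_remainder$mixture,
                     pal$muscle_remainder$opacity,
                     pal$muscle_remainder$finish)
  man <- print_manifest(list(part), provenance = list(config_hash = "abc"))
  path <- tempfile(fileext = ".json")
  write_manifest(man, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$parts[[1]]$opacity, "clear")
  expect_equal(js$parts[[1]]$mixture$clear, 1.0)
  expect_equal(js$provenance$config_hash, "abc")
  unlink(path)

  expect_error(print_part("x", m, c(cyan = 0.8, clear = 0.3)), "sum to 1")
  expect_error(print_manifest(list(part, part)), "unique")
})
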