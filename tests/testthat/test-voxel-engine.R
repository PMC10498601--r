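# Multi-channel grid, layer compositing, containment classification.

test_that("boolean compositing follows the subtract/add truth tables", {
  spec <- grid_spec(rbind(c(0, 0, 0), c(3, 1, 1)), voxel_size = 1,
                    padding = 0)
  mk <- function(v) array(as.numeric(v), spec$dims)
  base <- mk(c(1, 1, 0))
  top <- mk(c(1, 0, 1))
  sub <- composite(layer_stack(layer(base, "replace"),
                               layer(top, "subtract")), spec)
  expect_equal(as.vector(sub$shape), c(0, 1, 0))
  add <- composite(layer_stack(layer(base, "replace"),
                               layer(top, "add")), spec)
  expect_equal(as.vector(add$shape), c(1, 1, 1))
  # base layer must replace shape
  expect_error(layer_stack(layer(base, "add")), "base")
})

test_that("cube-minus-sphere matches an independent per-voxel oracle", {
  spec <- grid_spec(rbind(c(0, 0, 0), c(10, 10, 10)), voxel_size = 0.5,
                    padding = 0)
  d <- spec$dims
  ax <- lapply(1:3, function(a) spec$origin[a] + (seq_len(d[a]) - 1) * 0.5)
  cube <- array(1, d)
  ctr <- c(5, 5, 5)
  r2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
              (ax[[3]] - ctr[3])^2, "+")
  sphere <- array(as.numeric(r2 <= 16), d)
  got <- composite(layer_stack(layer(cube, "replace"),
                               layer(sphere, "subtract")), spec)
  # brute-force loop oracle over every voxel
  oracle <- array(0, d)
  for (i in seq_len(prod(d)))
    oracle[i] <- max(0, cube[i] - sphere[i])
  expect_identical(got$shape, oracle)
  expect_equal(measure_volume(got), sum(oracle) * 0.5^3)
  # every subtracted voxel is a void: the printed compositing contract
  expect_true(all(got$shape[sphere == 1] == 0))
})

test_that("subtraction conserves volume and is order-sensitive", {
  set.seed(21)
  for (rep in 1:5) {
    a <- random_binary_grid(12)
    b <- multichannel_grid(a$spec,
                           shape = array(as.numeric(runif(12^3) < 0.5),
                                         a$spec$dims))
    sub <- composite(layer_stack(layer(a$shape, "replace"),
                                 layer(b$shape, "subtract")), a$spec)
    inter <- a$shape * b$shape
    expect_identical(measure_volume(a),
                     sum(sub$shape + inter) * a$spec$voxel_size^3)
  }
  # A - B differs from B - A for asymmetric stacks
  spec <- grid_spec(rbind(c(0, 0, 0), c(2, 1, 1)), voxel_size = 1,
                    padding = 0)
  a <- array(c(1, 0), spec$dims)
  b <- array(c(1, 1), spec$dims)
  ab <- composite(layer_stack(layer(a, "replace"), layer(b, "subtract")),
                  spec)
  ba <- composite(layer_stack(layer(b, "replace"), layer(a, "subtract")),
                  spec)
  expect_false(identical(ab$shape, ba$shape))
})

test_that("material arithmetic recolors without touching morphology", {
  set.seed(31)
  g <- random_binary_grid(10)
  g <- multichannel_grid(g$spec, materials = c("grid", "vessel"),
                         shape = g$shape)
  shape_before <- g$shape
  sup <- array(runif(10^3), g$spec$dims)
  g <- material_add(g, sup, "grid", weight = 0.7)
  g <- material_add(g, array(1, g$spec$dims), "vessel", weight = 0.6)
  g <- material_add(g, sup, "grid", weight = 1, combine = "max")
  expect_identical(g$shape, shape_before)  # bit-identical shape channel
  msum <- g$materials$grid + g$materials$vessel
  expect_true(max(msum) <= 1 + 1e-6)
  expect_true(all(g$materials$grid[g$shape == 0] == 0))

  # full-weight add supersedes competing materials
  spec1 <- grid_spec(rbind(c(0, 0, 0), c(1, 1, 1)), voxel_size = 1,
                     padding = 0)
  h <- multichannel_grid(spec1, materials = c("A", "B"),
                         shape = array(1, spec1$dims))
  h <- material_add(h, array(1, spec1$dims), "A", weight = 1)
  h <- material_add(h, array(1, spec1$dims), "B", weight = 1)
  expect_equal(as.vector(h$materials$A), 0)
  expect_equal(as.vector(h$materials$B), 1)

  # support entirely outside the shape leaves the grid unchanged
  h2 <- multichannel_grid(spec1, materials = "A",
                          shape = array(0, spec1$dims))
  h3 <- material_add(h2, array(1, spec1$dims), "A")
  expect_identical(h3$materials$A, h2$materials$A)

  # undeclared material is a configuration error
  expect_error(material_add(h2, array(1, spec1$dims), "nope"),
               class = "voxflap_config_error")
})

test_that("containment classification partitions the vessel support", {
  # vessel tube crossing a muscle slab
  spec <- grid_spec(rbind(c(0, 0, 0), c(20, 20, 30)), voxel_size = 1,
                    padding = 0)
  d <- spec$dims
  ax <- lapply(1:3, function(a) spec$origin[a] + (seq_len(d[a]) - 1) * 1)
  slab <- array(rep(ax[[3]] >= 10 & ax[[3]] <= 20, each = d[1] * d[2]), d)
  lat <- outer((ax[[1]] - 10)^2, (ax[[2]] - 10)^2, "+")
  tube <- array(as.numeric(lat <= 9), d)  # vertical tube radius 3 everywhere
  vg <- multichannel_grid(spec, shape = tube)
  mg <- multichannel_grid(spec, shape = slab)
  cls <- classify_by_containment(vg, mg)
  # brute-force point-in-slab oracle on the tube voxels
  oracle_intra <- array(0L, d)
  for (i in seq_len(prod(d)))
    oracle_intra[i] <- as.integer(tube[i] > 0.5 && slab[i] > 0.5)
  expect_identical(cls$intra$data, oracle_intra)
  # partition: disjoint and covering
  expect_true(all(cls$intra$data + cls$extra$data == (tube > 0.5)))
  expect_equal(sum(cls$intra$data & cls$extra$data), 0)

  # degenerate containment cases
  empty <- multichannel_grid(spec)
  expect_equal(sum(classify_by_containment(vg, empty)$intra$data), 0)
  all_m <- multichannel_grid(spec, shape = array(1, d))
  expect_equal(sum(classify_by_containment(vg, all_m)$extra$data), 0)

  bad <- multichannel_grid(grid_spec(rbind(c(0, 0, 0), c(10, 10, 10)),
                                     voxel_size = 1, padding = 0))
  expect_error(classify_by_containment(vg, bad),
               class = "voxflap_geometry_error")
})

test_that("measure_volume is channel sum times voxel volume", {
  spec <- grid_spec(rbind(c(0, 0, 0), c(5, 5, 5)), voxel_size = 0.5,
                    padding = 0)
  shp <- array(0, spec$dims)
  shp[seq_len(1000)] <- 1
  g <- multichannel_grid(spec, shape = shp)
  expect_equal(measure_volume(g), 125)
  expect_equal(measure_volume(multichannel_grid(spec)), 0)
  expect_error(measure_volume(g, "material:missing"),
               class = "voxflap_config_error")
})

test_that("mask rasterization is exact on aligned grids", {
  geo <- scalar_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
  m <- array(0L, c(8, 8, 8))
  m[3:5, 2:6, 4] <- 1L
  mask <- label_mask(m, geo, "muscle")
  # identity at the same spacing
  g1 <- from_mask(mask, grid_spec_from_volume(geo))
  expect_identical(g1$shape, array(as.numeric(m), dim(m)))
  # each source voxel maps to an exact 2x2x2 block at half spacing
  g2 <- from_mask(mask, grid_spec_from_volume(geo, voxel_size = 0.5))
  expect_equal(sum(g2$shape), 8 * sum(m))
  blocks <- g2$shape[, , 7] + g2$shape[, , 8]  # the two children of slice 4
  expect_equal(sum(blocks), 2 * 4 * sum(m[, , 4]))
  # empty mask warns but yields a valid grid
  empty <- label_mask(array(0L, c(8, 8, 8)), geo)
  expect_warning(ge <- from_mask(empty, grid_spec_from_volume(geo)),
                 "empty")
  expect_equal(sum(ge$shape), 0)
})

test_that("mesh voxelization counts interior voxel centers", {
  spec <- grid_spec(rbind(c(0, 0, 0), c(10, 10, 10)), voxel_size = 1,
                    padding = 0)
  g <- voxelize_mesh(cube_mesh(10), spec)
  expect_equal(sum(g$shape), 1000)  # centers at 0.5 ... 9.5 on each axis

  sph <- icosphere(5, 3)
  spec2 <- grid_spec(rbind(rep(-5.5, 3), rep(5.5, 3)), voxel_size = 0.5,
                     padding = 0.5)
  gv <- voxelize_mesh(sph, spec2)
  analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(measure_volume(gv) - analytic) / analytic, 0.02)

  # a deleted face is reported as 3 open edges
  broken <- cube_mesh(10)
  broken$faces <- broken$faces[-1, ]
  err <- tryCatch(voxelize_mesh(broken, spec), error = identity)
  expect_s3_class(err, "voxflap_geometry_error")
  expect_match(conditionMessage(err), "3 open edges")
})
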