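#' Synthetic abdomen phantom specification
#'
#' Parameters of the seeded CT-angiography-like phantom: a curved rectus-
#' abdominis-like muscle slab spanning the volume, a contrast-filled vessel
#' tree (a trunk running inferior-superior beneath the slab with perforators
#' rising vertically through it), a cone-shaped umbilicus landmark anterior
#' to the slab, and fat background. Tissue HU are drawn uniformly inside the
#' printed segmentation windows (muscle within 180-230 HU, vessels within
#' 900-1100 HU), fat from a Gaussian with negative mean, so noise-free
#' thresholding recovers each structure exactly.
#'
#' @param dims Volume dimensions in voxels (default 128 x 128 x 96).
#' @param spacing Isotropic voxel spacing in mm (default 1).
#' @param slab_thickness Muscle slab thickness in mm (default 12).
#' @param slab_bulge Anterior bulge amplitude of the curved slab in mm
#'   (default 3).
#' @param slab_z0 Posterior slab offset in mm; default 42% of the z extent.
#' @param n_perforators Number of perforators (>= 1, default 3).
#' @param perforator_radius,trunk_radius Vessel radii in mm (defaults 2 and
#'   2.5); must be at least twice the voxel spacing.
#' @param tortuosity Lateral sinusoidal wobble amplitude of the trunk in mm
#'   (default 2).
#' @param umbilicus_radius,umbilicus_height Cone base radius / height in mm.
#' @param fat_mean,fat_sd Fat background HU distribution (default N(-75, 10)).
#' @param muscle_hu,vessel_hu,umbilicus_hu Uniform HU ranges per tissue.
#' @param noise_sd Optional Gaussian image noise sigma in HU, added last
#'   (default 0 = noise-free).
#' @param siea Also add a superficial (SIEA-like) vessel (default FALSE).
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @return A `voxflap_phantomspec`.
#' @export
phantom_spec <- function(dims = c(128, 128, 96), spacing = 1,
                         slab_thickness = 12, slab_bulge = 3, slab_z0 = NULL,
                         n_perforators = 3, perforator_radius = 2,
                         trunk_radius = 2.5, tortuosity = 2,
                         umbilicus_radius = 5, umbilicus_height = 8,
                         fat_mean = -75, fat_sd = 10,
                         muscle_hu = c(190, 220), vessel_hu = c(950, 1050),
                         umbilicus_hu = c(30, 50), noise_sd = 0,
                         siea = FALSE, seed = 42) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)[1]
  assert_that(length(dims) == 3 && all(dims >= 16),
              "dims must be three values >= 16")
  assert_that(spacing > 0, "spacing must be positive")
  assert_that(muscle_hu[1] >= 180 && muscle_hu[2] <= 230 &&
                muscle_hu[1] < muscle_hu[2],
              "muscle_hu must lie within the 180-230 HU window")
  assert_that(vessel_hu[1] >= 900 && vessel_hu[2] <= 1100 &&
                vessel_hu[1] < vessel_hu[2],
              "vessel_hu must lie within the 900-1100 HU window")
  assert_that(fat_mean < 0, "fat_mean must be negative (fat HU < 0)")
  assert_that(n_perforators >= 1, "need at least one perforator")
  if (min(perforator_radius, trunk_radius) < 2 * spacing)
    stop_voxflap(sprintf(
      "vessel radii (%g, %g mm) must be at least twice the voxel spacing (%g mm)",
      perforator_radius, trunk_radius, spacing), "voxflap_resolution_error")
  ex <- (dims - 1) * spacing
  slab_z0 <- slab_z0 %||% (0.42 * ex[3])
  spec <- list(dims = dims, spacing = spacing,
               slab_thickness = slab_thickness, slab_bulge = slab_bulge,
               slab_z0 = slab_z0, n_perforators = as.integer(n_perforators),
               perforator_radius = perforator_radius,
               trunk_radius = trunk_radius, tortuosity = tortuosity,
               umbilicus_radius = umbilicus_radius,
               umbilicus_height = umbilicus_height,
               fat_mean = fat_mean, fat_sd = fat_sd,
               muscle_hu = muscle_hu, vessel_hu = vessel_hu,
               umbilicus_hu = umbilicus_hu, noise_sd = noise_sd,
               siea = siea, seed = as.integer(seed))
  structure(spec, class = "voxflap_phantomspec")
}

# deterministic template geometry shared by rasterization, truth and the
# scripted repair; all positions in world mm with origin at voxel (1,1,1)
phantom_template <- function(spec) {
  ex <- (spec$dims - 1) * spec$spacing
  cx <- ex[1] / 2
  cy <- ex[2] / 2
  bulge <- function(x) spec$slab_bulge * (1 - ((x - cx) / cx)^2)
  z0 <- spec$slab_z0
  zt <- z0 + spec$slab_thickness
  trunk_z <- z0 - 10
  trunk_x <- function(y) cx + spec$tortuosity * sin(2 * pi * y / 50)

  # perforator sites: lateral offsets chosen on the flat central region of
  # the bulge so the anterior surface is locally level around each tunnel
  offs <- c(0, -0.25, 0.19, -0.12, 0.28, 0.08, -0.31)
  n <- spec$n_perforators
  xi <- cx + offs[(seq_len(n) - 1) %% length(offs) + 1] * cx
  yi <- seq(0.25, 0.7, length.out = n) * ex[2]
  perf_top <- zt + bulge(xi) + 5

  trunk_y <- seq(0.08 * ex[2], 0.85 * ex[2], by = 8)
  trunk_pts <- cbind(trunk_x(trunk_y), trunk_y, trunk_z)

  segs <- list()
  for (i in seq_len(nrow(trunk_pts) - 1))
    segs[[length(segs) + 1]] <- list(p0 = trunk_pts[i, ],
                                     p1 = trunk_pts[i + 1, ],
                                     r = spec$trunk_radius)
  for (i in seq_len(n)) {
    j0 <- c(trunk_x(yi[i]), yi[i], trunk_z)
    j1 <- c(xi[i], yi[i], trunk_z)
    segs[[length(segs) + 1]] <- list(p0 = j0, p1 = j1,
                                     r = spec$perforator_radius)
    segs[[length(segs) + 1]] <- list(p0 = j1,
                                     p1 = c(xi[i], yi[i], perf_top[i]),
                                     r = spec$perforator_radius)
  }

  umb_center <- c(cx, cy)
  umb_apex <- zt + spec$slab_bulge + 4
  umb_base <- umb_apex + spec$umbilicus_height

  siea_seg <- NULL
  if (spec$siea) {
    xs <- cx + 0.3 * cx
    zs <- zt + bulge(xs) + 6
    siea_seg <- list(p0 = c(xs, 0.1 * ex[2], zs),
                     p1 = c(xs, 0.55 * ex[2], zs),
                     r = spec$perforator_radius)
  }

  list(ex = ex, cx = cx, cy = cy, bulge = bulge, z0 = z0, zt = zt,
       trunk_z = trunk_z, perf_x = xi, perf_y = yi, perf_top = perf_top,
       vessel_segs = segs, umb_center = umb_center, umb_apex = umb_apex,
       umb_base = umb_base, siea_seg = siea_seg)
}

#' Generate the synthetic abdomen phantom
#'
#' Rasterizes the scripted anatomy template onto the voxel lattice, draws
#' per-tissue HU from the spec's distributions and (optionally) adds
#' Gaussian noise last. Deterministic given the seed: the same spec yields a
#' bit-identical volume and truth.
#'
#' @param spec A [phantom_spec].
#' @return List with `volume` (a [scalar_volume]) and `truth`, which holds
#'   per-structure [label_mask]s (`muscle`, `vessels`, `vessels_intra`,
#'   `vessels_extra`, `umbilicus`, optional `siea`), `exit_points` (one
#'   world point per perforator, on the anterior muscle surface),
#'   `umbilicus_centroid`, the scripted `repair_strokes` that fill the
#'   perforator tunnels in a thresholded muscle mask (the recorded stand-in
#'   for manual gap filling), and suggested `strut_endpoints`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "voxflap_phantomspec"))
  tpl <- phantom_template(spec)
  d <- spec$dims
  sp <- rep(spec$spacing, 3)
  org <- c(0, 0, 0)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spec$spacing)

  # curved slab: z - bulge(x) in [z0, z0 + thickness]; separable in (x, z)
  zb <- outer(-tpl$bulge(ax[[1]]), ax[[3]], "+")  # nx x nz of z - bulge(x)
  in_xz <- zb >= tpl$z0 & zb <= tpl$zt
  slab <- aperm(array(in_xz, c(d[1], d[3], d[2])), c(1, 3, 2))

  # vessels: capsule chain; rasterize per radius group
  vessels <- array(FALSE, d)
  segs <- tpl$vessel_segs
  if (!is.null(tpl$siea_seg)) segs <- c(segs, list(tpl$siea_seg))
  for (r in unique(vapply(segs, `[[`, numeric(1), "r"))) {
    sr <- Filter(function(s) s$r == r, segs)
    vessels <- vessels | rasterize_capsules(d, sp, org, sr, r)
  }
  siea_mask <- NULL
  if (!is.null(tpl$siea_seg))
    siea_mask <- rasterize_capsules(d, sp, org, list(tpl$siea_seg),
                                    tpl$siea_seg$r)

  # umbilicus: cone, apex pointing posteriorly toward the muscle
  umb <- array(FALSE, d)
  lat2 <- outer((ax[[1]] - tpl$umb_center[1])^2,
                (ax[[2]] - tpl$umb_center[2])^2, "+")
  kz <- which(ax[[3]] >= tpl$umb_apex & ax[[3]] <= tpl$umb_base)
  for (k in kz) {
    rad <- spec$umbilicus_radius *
      (ax[[3]][k] - tpl$umb_apex) / (tpl$umb_base - tpl$umb_apex)
    umb[, , k] <- lat2 <= rad^2
  }

  muscle <- slab & !vessels
  intra <- vessels & slab
  extra <- vessels & !slab

  n <- prod(d)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  hu <- rnorm(n, spec$fat_mean, spec$fat_sd)
  hu[umb] <- runif(sum(umb), spec$umbilicus_hu[1], spec$umbilicus_hu[2])
  hu[muscle] <- runif(sum(muscle), spec$muscle_hu[1], spec$muscle_hu[2])
  hu[vessels] <- runif(sum(vessels), spec$vessel_hu[1], spec$vessel_hu[2])
  if (spec$noise_sd > 0) hu <- hu + rnorm(n, 0, spec$noise_sd)
  vol <- scalar_volume(array(hu, d), spacing = sp, origin = org)

  exit_points <- cbind(tpl$perf_x, tpl$perf_y,
                       tpl$zt + tpl$bulge(tpl$perf_x))
  colnames(exit_points) <- c("x", "y", "z")

  umb_idx <- which(umb, arr.ind = TRUE)
  umb_centroid <- org + (colMeans(umb_idx) - 1) * spec$spacing

  truth <- list(
    muscle = label_mask(muscle, vol, "muscle"),
    vessels = label_mask(vessels, vol, "vessels"),
    vessels_intra = label_mask(intra, vol, "vessels_intra"),
    vessels_extra = label_mask(extra, vol, "vessels_extra"),
    umbilicus = label_mask(umb, vol, "umbilicus"),
    siea = if (!is.null(siea_mask)) label_mask(siea_mask, vol, "siea"),
    has_siea = spec$siea,
    exit_points = exit_points,
    umbilicus_centroid = as.numeric(umb_centroid),
    repair_strokes = phantom_repair_strokes(spec, tpl),
    strut_endpoints = list(rbind(
      c(tpl$cx, tpl$cy, tpl$zt + spec$slab_bulge - 2),
      c(tpl$cx, tpl$cy, tpl$umb_apex + 2))),
    spec = spec)
  list(volume = vol, truth = truth)
}

# Scripted fill strokes that restore the geometric slab through each
# perforator tunnel. The brush radius and axial placement are chosen so the
# swept capsule covers exactly the tunnel voxels inside the slab (and only
# slab voxels outside the tunnel): the filled muscle equals the geometric
# slab voxel-for-voxel wherever the anterior surface is locally level, which
# the perforator sites guarantee by construction.
phantom_repair_strokes <- function(spec, tpl) {
  sz <- spec$spacing
  rv <- spec$perforator_radius
  delta <- 0.4 * sz
  rb <- max(2.25 * rv, (rv^2 + delta^2) / (2 * delta))
  strokes <- list()
  for (i in seq_along(tpl$perf_x)) {
    b <- tpl$bulge(tpl$perf_x[i])
    h_top <- floor((tpl$zt + b) / sz) * sz
    z_bot <- ceiling((tpl$z0 + b) / sz) * sz
    z2 <- h_top + 0.75 * sz - rb
    z1 <- z_bot - 0.75 * sz + rb
    if (z1 >= z2)
      stop_voxflap(
        "slab too thin relative to the perforator radius for scripted repair",
        "voxflap_resolution_error")
    strokes[[i]] <- brush_stroke(
      "fill",
      rbind(c(tpl$perf_x[i], tpl$perf_y[i], z1),
            c(tpl$perf_x[i], tpl$perf_y[i], z2)),
      radius = rb)
  }
  strokes
}
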