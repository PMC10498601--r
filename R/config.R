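#' Default pipeline configuration
#'
#' Builds the single configuration object that drives the end-to-end
#' pipeline: per-structure segmentation windows (muscle 180-230 HU, vessels
#' 900-1100 HU, umbilicus 20-60 HU), scripted repair strokes, the measured
#' grid (1 cm spacing, 1 mm falloff, 100% strength, anchored on the
#' umbilicus), voxel-engine resolution, meshing options, struts, perforator
#' locations for the report, and the print-material palette.
#'
#' @param truth Optional phantom truth (from [make_phantom()]); supplies the
#'   scripted repair strokes, perforator points and strut endpoints.
#' @param voxel_size Engine voxel size in mm (default 0.5).
#' @param seed Seed recorded with the run.
#' @return A pipeline config list (see [validate_pipeline_config()]).
#' @export
default_pipeline_config <- function(truth = NULL, voxel_size = 0.5,
                                    seed = 1L) {
  strokes <- list()
  perfs <- list()
  struts <- list()
  if (!is.null(truth)) {
    strokes <- lapply(truth$repair_strokes, function(s)
      list(mode = s$mode, radius = s$radius,
           centers = lapply(seq_len(nrow(s$centers)),
                            function(i) as.numeric(s$centers[i, ]))))
    perfs <- lapply(seq_len(nrow(truth$exit_points)),
                    function(i) as.numeric(truth$exit_points[i, ]))
    struts <- lapply(truth$strut_endpoints, function(e)
      list(endpoints = list(as.numeric(e[1, ]), as.numeric(e[2, ])),
           radius = 1.5))
  }
  list(
    structures = list(
      muscle = list(hu_lo = 180, hu_hi = 230, smoothing_sigma = 0,
                    min_component_voxels = 0),
      vessels = list(hu_lo = 900, hu_hi = 1100, smoothing_sigma = 0,
                     min_component_voxels = 0),
      umbilicus = list(hu_lo = 20, hu_hi = 60, smoothing_sigma = 0,
                       min_component_voxels = 0)),
    repair = list(muscle = strokes, vessels = list()),
    grid = list(spacing_mm = 10, falloff_mm = 1, strength = 1,
                anchor = "auto:umbilicus",
                normals = list(c(1, 0, 0), c(0, 1, 0))),
    engine = list(voxel_size = voxel_size, padding = 2),
    mesh = list(iso_level = 0.5, material_threshold = 0.5,
                smooth_sigma = 0.5),
    struts = struts,
    perforators = perfs,
    materials = default_part_materials(),
    seed = as.integer(seed))
}

#' Validate a pipeline configuration
#'
#' Checks every stage's parameters before any stage runs; violations raise a
#' configuration error naming the offending field.
#'
#' @param config Pipeline config list.
#' @return `config`, invisibly, on success.
#' @export
validate_pipeline_config <- function(config) {
  fail <- function(field, why)
    stop_voxflap(sprintf("invalid config: %s %s", field, why),
                 "voxflap_config_error")
  need <- function(field, ok, why) if (!isTRUE(ok)) fail(field, why)

  need("structures", is.list(config$structures) &&
         length(config$structures) > 0, "must list at least one structure")
  for (nm in names(config$structures)) {
    s <- config$structures[[nm]]
    pre <- paste0("structures.", nm, ".")
    need(paste0(pre, "hu_lo"), is.numeric(s$hu_lo) && is.numeric(s$hu_hi) &&
           s$hu_lo < s$hu_hi, "hu_lo must be < hu_hi")
    need(paste0(pre, "smoothing_sigma"), (s$smoothing_sigma %||% 0) >= 0,
         "must be >= 0")
    need(paste0(pre, "min_component_voxels"),
         (s$min_component_voxels %||% 0) >= 0, "must be >= 0")
  }
  g <- config$grid
  need("grid.falloff_mm", g$falloff_mm > 0, "must be > 0")
  need("grid.spacing_mm", g$spacing_mm > 2 * g$falloff_mm,
       "must exceed 2 * falloff_mm")
  need("grid.strength", g$strength > 0 && g$strength <= 1,
       "must be in (0, 1]")
  need("grid.anchor", identical(g$anchor, "auto:umbilicus") ||
         (is.numeric(unlist(g$anchor)) && length(unlist(g$anchor)) == 3),
       "must be 'auto:umbilicus' or a world point")
  need("engine.voxel_size", config$engine$voxel_size > 0, "must be > 0")
  need("engine.padding", config$engine$padding >= 0, "must be >= 0")
  m <- config$mesh
  need("mesh.iso_level", m$iso_level > 0 && m$iso_level < 1,
       "must be in (0, 1)")
  need("mesh.material_threshold",
       m$material_threshold > 0 && m$material_threshold < 1,
       "must be in (0, 1)")
  need("mesh.smooth_sigma", m$smooth_sigma >= 0, "must be >= 0")
  for (i in seq_along(config$struts)) {
    st <- config$struts[[i]]
    pre <- sprintf("struts[%d].", i)
    ep <- st$endpoints
    need(paste0(pre, "endpoints"), length(ep) == 2 &&
           all(lengths(ep) == 3), "must be two world points")
    need(paste0(pre, "radius"), st$radius > 0, "must be > 0")
  }
  for (nm in names(config$repair))
    for (i in seq_along(config$repair[[nm]])) {
      s <- config$repair[[nm]][[i]]
      pre <- sprintf("repair.%s[%d].", nm, i)
      need(paste0(pre, "mode"), s$mode %in% c("fill", "erase"),
           "must be 'fill' or 'erase'")
      need(paste0(pre, "radius"), s$radius > 0, "must be > 0")
      need(paste0(pre, "centers"), length(s$centers) >= 1 &&
             all(lengths(s$centers) == 3), "must be world points")
    }
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return The config list ([read_pipeline_config()]) or `path`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config Pipeline config list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration for provenance
#'
#' MD5 of the canonical JSON serialization; embedded in the print manifest
#' so every exported model can be traced to the exact configuration.
#'
#' @param config Pipeline config list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
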