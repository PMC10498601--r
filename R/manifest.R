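#' Default print-material assignments
#'
#' The palette used for the printed model: clear muscle so the intramuscular
#' vessel course stays visible, an 80% cyan / 20% clear measured grid, 100%
#' magenta extra-muscular vessels, an equal magenta/cyan mix (purple) for
#' intra-muscular vessel segments, and one distinct opaque color (yellow)
#' shared by the umbilicus and the support struts. All parts default to a
#' glossy finish.
#'
#' @return Named list of per-part `mixture`, `opacity` and `finish`.
#' @export
default_part_materials <- function() {
  list(
    muscle_remainder = list(mixture = c(clear = 1.0), opacity = "clear",
                            finish = "glossy"),
    grid_bands = list(mixture = c(cyan = 0.8, clear = 0.2),
                      opacity = "opaque", finish = "glossy"),
    vessels_intra = list(mixture = c(magenta = 0.5, cyan = 0.5),
                         opacity = "opaque", finish = "glossy"),
    vessels_extra = list(mixture = c(magenta = 1.0), opacity = "opaque",
                         finish = "glossy"),
    umbilicus = list(mixture = c(yellow = 1.0), opacity = "opaque",
                     finish = "glossy"),
    struts = list(mixture = c(yellow = 1.0), opacity = "opaque",
                  finish = "glossy")
  )
}

#' Printable part: mesh plus material assignment
#'
#' @param name Unique part name.
#' @param mesh A [triangle_mesh].
#' @param mixture Named pigment fractions in \[0, 1\] summing to 1 (+- 1e-6).
#' @param opacity "clear", "translucent" or "opaque".
#' @param finish "glossy" or "matte".
#' @param stl STL filename recorded in the manifest.
#' @return A `voxflap_part`.
#' @export
print_part <- function(name, mesh, mixture, opacity = "opaque",
                       finish = "glossy", stl = paste0(name, ".stl")) {
  stopifnot(inherits(mesh, "voxflap_mesh"))
  mixture <- unlist(mixture)
  assert_that(!is.null(names(mixture)) && all(nzchar(names(mixture))),
              "mixture must be a named pigment -> fraction map")
  assert_that(all(mixture >= 0 & mixture <= 1) &&
                abs(sum(mixture) - 1) <= 1e-6,
              "mixture fractions must lie in [0,1] and sum to 1")
  opacity <- match.arg(opacity, c("clear", "translucent", "opaque"))
  finish <- match.arg(finish, c("glossy", "matte"))
  structure(list(name = name, mesh = mesh, mixture = mixture,
                 opacity = opacity, finish = finish, stl = stl),
            class = "voxflap_part")
}

#' Print manifest: the machine-readable twin of the print setup
#'
#' @param parts List of [print_part]s with unique names.
#' @param provenance List of provenance fields (config hash, tool version,
#'   timestamp); sensible defaults are filled in.
#' @return A `voxflap_manifest`.
#' @export
print_manifest <- function(parts, provenance = list()) {
  assert_that(all(vapply(parts, inherits, logical(1), "voxflap_part")),
              "parts must be print_part objects")
  nm <- vapply(parts, `[[`, character(1), "name")
  assert_that(!anyDuplicated(nm), "part names must be unique")
  names(parts) <- nm
  prov <- modifyList(list(
    tool = "voxflap",
    tool_version = as.character(packageVersion("voxflap")),
    config_hash = NA_character_,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), provenance)
  structure(list(parts = parts, provenance = prov),
            class = "voxflap_manifest")
}

#' @export
print.voxflap_manifest <- function(x, ...) {
  cat(sprintf("<voxflap_manifest> %d parts (config %s)\n", length(x$parts),
              x$provenance$config_hash))
  for (p in x$parts)
    cat(sprintf("  %-18s %8d tris  %-11s %-6s  %s\n", p$name,
                nrow(p$mesh$faces), p$opacity, p$finish,
                paste(sprintf("%s=%.2f", names(p$mixture), p$mixture),
                      collapse = " ")))
  invisible(x)
}

#' Write manifest JSON (and optionally the part STLs)
#'
#' The JSON lists, per part, the STL filename, pigment mixture, opacity and
#' finish, plus provenance (tool version, config hash, timestamp).
#'
#' @param manifest A [print_manifest].
#' @param path Output JSON path.
#' @param write_meshes Also write each part's STL next to the JSON.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, write_meshes = FALSE) {
  stopifnot(inherits(manifest, "voxflap_manifest"))
  dir <- dirname(path)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    parts = lapply(unname(manifest$parts), function(p) list(
      name = p$name, stl = p$stl, mixture = as.list(p$mixture),
      opacity = p$opacity, finish = p$finish,
      n_triangles = nrow(p$mesh$faces),
      volume_mm3 = mesh_volume(p$mesh))),
    provenance = manifest$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (write_meshes)
    for (p in manifest$parts) write_stl(p$mesh, file.path(dir, p$stl))
  invisible(path)
}
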