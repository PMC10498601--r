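#' Scalar CT-like volume
#'
#' A 3D array of Hounsfield-unit (HU) values with physical geometry: isotropic
#' or anisotropic voxel spacing in mm and the world position of the center of
#' voxel (1,1,1). World coordinates follow the voxel-center convention:
#' the center of voxel (i, j, k) is at `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing Numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin Numeric length-3, world position (mm) of the first voxel
#'   center.
#' @param axes Axis-convention label (informational), default "LPS"
#'   (x = patient left, y = posterior, z = superior).
#' @return A `voxflap_volume` object.
#' @export
scalar_volume <- function(data, spacing, origin = c(0, 0, 0), axes = "LPS") {
  assert_that(is.array(data) && length(dim(data)) == 3 && all(dim(data) > 0),
              "data must be a 3D array with positive dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  assert_that(is_point3(spacing) && all(spacing > 0),
              "spacing must be three strictly positive numbers (mm)")
  assert_that(is_point3(origin), "origin must be a finite world point (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 axes = axes),
            class = "voxflap_volume")
}

#' @export
print.voxflap_volume <- function(x, ...) {
  cat(sprintf(
    "<voxflap_volume> %s voxels, spacing %s mm, origin %s mm [%s]\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    paste(format(x$origin), collapse = ", "), x$axes))
  cat(sprintf("  HU range: [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxflap_volume <- function(x) dim(x$data)

#' Binary label mask for one anatomical structure
#'
#' Shares the exact geometry (spacing and origin) of its source volume and
#' holds only 0/1 values.
#'
#' @param data 3D array coercible to 0/1 (logical or numeric).
#' @param geometry A [scalar_volume], [label_mask], or list with `spacing`
#'   and `origin` supplying the shared geometry.
#' @param structure Structure name, e.g. "muscle", "vessels", "umbilicus".
#' @return A `voxflap_mask` object.
#' @export
label_mask <- function(data, geometry, structure = "other") {
  assert_that(is.array(data) && length(dim(data)) == 3,
              "mask data must be a 3D array")
  vals <- unique(as.vector(data))
  assert_that(all(vals %in% c(0, 1, TRUE, FALSE)),
              "mask values must be 0/1")
  d <- array(as.integer(data != 0), dim(data))
  structure(list(data = d, spacing = as.numeric(geometry$spacing),
                 origin = as.numeric(geometry$origin),
                 structure = structure),
            class = "voxflap_mask")
}

#' @export
print.voxflap_mask <- function(x, ...) {
  cat(sprintf("<voxflap_mask> '%s' %s voxels, %d foreground (%.2f%%)\n",
              x$structure, paste(dim(x$data), collapse = "x"),
              sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' @export
dim.voxflap_mask <- function(x) dim(x$data)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centers
#'
#' @param x A [scalar_volume] or [label_mask].
#' @param axis Axis 1, 2 or 3.
#' @return Numeric vector of center positions (mm) along `axis`.
#' @export
voxel_centers <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$data)[axis]) - 1) * x$spacing[axis]
}

#' Read a CT-like volume from NIfTI or a DICOM series
#'
#' NIfTI input (`.nii` / `.nii.gz`) must be a 3D scalar image with an
#' axis-aligned, positively oriented transform. DICOM input is a directory of
#' single-frame slices from one series: all slices must share dimensions,
#' pixel spacing and orientation, be uniformly spaced, and use an
#' axis-aligned orientation; the rescale slope/intercept is applied so the
#' returned values are HU.
#'
#' @param path File (NIfTI) or directory (DICOM series).
#' @param format "auto" (by path type), "nifti" or "dicom_series".
#' @return A [scalar_volume].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  assert_that(file.exists(path), sprintf("path does not exist: %s", path),
              class = "voxflap_format_error")
  switch(format,
         nifti = read_nifti_volume(path),
         dicom_series = read_dicom_series(path))
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3)
    stop_voxflap(sprintf("expected a 3D scalar image, got %dD", length(d)),
                 "voxflap_unsupported_input")
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4) || any(diag(rot) <= 0))
    stop_voxflap(
      "only axis-aligned, positively oriented NIfTI transforms are supported",
      "voxflap_unsupported_input")
  scalar_volume(array(as.numeric(img), d),
                spacing = diag(rot), origin = xf[1:3, 4])
}

#' Write a volume or mask to NIfTI
#'
#' The geometry (spacing and origin, voxel-center convention) is stored in
#' the sform/qform as an axis-aligned transform, so a write/read round trip
#' through [read_volume()] is exact.
#'
#' @param x A [scalar_volume] or [label_mask].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  xf <- rbind(cbind(diag(x$spacing), x$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(x$data)
  img <- RNifti::`pixdim<-`(img, x$spacing)
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume

#' Read a label mask from NIfTI
#'
#' @param path NIfTI path holding 0/1 data.
#' @param structure Structure name to attach.
#' @return A [label_mask].
#' @export
read_mask <- function(path, structure = "other") {
  v <- read_nifti_volume(path)
  label_mask(v$data != 0, v, structure = structure)
}
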