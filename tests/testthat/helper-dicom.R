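# Minimal explicit-VR little-endian DICOM slice writer for test fixtures.
# Pixel matrix layout matches the package reader: pixels[col, row], column
# index (x) varying fastest within a row.

write_test_dicom_slice <- function(path, pixels, position,
                                   orientation = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(1, 1),
                                   slope = 1, intercept = 0) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  pad_even <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  elem <- function(group, el, vr, value_raw) {
    hdr <- c(u16(group), u16(el), charToRaw(vr))
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      c(hdr, as.raw(c(0, 0)),
        writeBin(length(value_raw), raw(), size = 4, endian = "little"),
        value_raw)
    } else {
      c(hdr, u16(length(value_raw)), value_raw)
    }
  }
  str_elem <- function(group, el, vr, s) elem(group, el, vr,
                                              charToRaw(pad_even(s)))
  ds <- function(v) paste(format(v, trim = TRUE, scientific = FALSE),
                          collapse = "\\")

  cols <- nrow(pixels)  # x
  rows <- ncol(pixels)  # y
  px_raw <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                     endian = "little")

  meta <- c(
    str_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    str_elem(0x0002, 0x0003, "UI", "1.2.3.4.5.6.7"),
    str_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  body <- c(
    str_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    str_elem(0x0020, 0x0032, "DS", ds(position)),
    str_elem(0x0020, 0x0037, "DS", ds(orientation)),
    elem(0x0028, 0x0010, "US", u16(rows)),
    elem(0x0028, 0x0011, "US", u16(cols)),
    str_elem(0x0028, 0x0030, "DS", ds(rev(pixel_spacing))),
    elem(0x0028, 0x0100, "US", u16(16)),
    elem(0x0028, 0x0101, "US", u16(16)),
    elem(0x0028, 0x0103, "US", u16(1)),
    str_elem(0x0028, 0x1052, "DS", ds(intercept)),
    str_elem(0x0028, 0x1053, "DS", ds(slope)),
    elem(0x7fe0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

write_test_dicom_series <- function(dir, volume_data, spacing = c(1, 1, 1),
                                    origin = c(0, 0, 0), slope = 1,
                                    intercept = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume_data)
  for (k in seq_len(d[3])) {
    stored <- round((volume_data[, , k] - intercept) / slope)
    write_test_dicom_slice(
      file.path(dir, sprintf("slice_%03d.dcm", k)), stored,
      position = c(origin[1], origin[2], origin[3] + (k - 1) * spacing[3]),
      pixel_spacing = spacing[1:2], slope = slope, intercept = intercept)
  }
  invisible(dir)
}
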