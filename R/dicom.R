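# Minimal DICOM reader for scalar CT series.
#
# Supports single-frame, uncompressed slices in Explicit or Implicit VR
# Little Endian transfer syntax with 8/16-bit integer pixel data -- the shape
# of an ordinary axial CT export. Sequences with undefined length and
# compressed transfer syntaxes are rejected as unsupported input. This is
# intake plumbing, not a general DICOM implementation.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# VRs carrying a 2-byte reserved field and 4-byte length in explicit VR
DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

parse_dicom_file <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n)
  if (n < 132 || rawToChar(raw[129:132]) != "DICM")
    stop_voxflap(sprintf("not a DICOM part-10 file: %s", path),
                 "voxflap_format_error")
  pos <- 133L
  ts <- TS_EXPLICIT_LE
  elems <- new.env(parent = emptyenv())

  read_element <- function(pos, explicit) {
    group <- dcm_u16(raw, pos)
    elem <- dcm_u16(raw, pos + 2L)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% DCM_LONG_VRS) {
        len <- dcm_u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- dcm_u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295)
      stop_voxflap(
        sprintf("undefined-length element (%04x,%04x) unsupported: %s",
                group, elem, path), "voxflap_unsupported_input")
    list(group = group, elem = elem, vr = vr, len = len,
         start = pos + hdr, next_pos = pos + hdr + as.integer(len))
  }

  get_ascii <- function(el) {
    if (el$len == 0) return("")
    b <- raw[el$start:(el$start + el$len - 1L)]
    trimws(rawToChar(b[b != as.raw(0)]))  # UI values are NUL-padded
  }
  get_ds <- function(el) as.numeric(strsplit(get_ascii(el), "\\\\")[[1]])
  get_us <- function(el) dcm_u16(raw, el$start)

  # file meta group (0002): always explicit VR little endian
  while (pos <= n - 8L) {
    el <- read_element(pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$elem == 16L) ts <- get_ascii(el)  # TransferSyntaxUID
    pos <- el$next_pos
  }
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
    stop_voxflap(sprintf("unsupported transfer syntax %s: %s", ts, path),
                 "voxflap_unsupported_input")
  explicit <- ts == TS_EXPLICIT_LE

  out <- list(rows = NULL, cols = NULL, pixel_spacing = NULL,
              position = NULL, orientation = NULL,
              slope = 1, intercept = 0, bits = 16L, signed = FALSE,
              pixel_raw = NULL, frames = 1L)
  while (pos <= n - 8L) {
    el <- read_element(pos, explicit)
    key <- sprintf("%04x%04x", el$group, el$elem)
    switch(key,
      "00200032" = { out$position <- get_ds(el) },
      "00200037" = { out$orientation <- get_ds(el) },
      "00280008" = { out$frames <- as.integer(get_ascii(el)) },
      "00280010" = { out$rows <- get_us(el) },
      "00280011" = { out$cols <- get_us(el) },
      "00280030" = { out$pixel_spacing <- get_ds(el) },
      "00280100" = { out$bits <- get_us(el) },
      "00280103" = { out$signed <- get_us(el) == 1L },
      "00281052" = { out$intercept <- get_ds(el)[1] },
      "00281053" = { out$slope <- get_ds(el)[1] },
      "7fe00010" = {
        out$pixel_raw <- raw[el$start:(el$start + el$len - 1L)]
      },
      NULL)
    pos <- el$next_pos
  }
  for (f in c("rows", "cols", "pixel_spacing", "position", "orientation",
              "pixel_raw"))
    if (is.null(out[[f]]))
      stop_voxflap(sprintf("missing required DICOM field %s in %s", f, path),
                   "voxflap_format_error")
  if (!is.null(out$frames) && out$frames > 1L)
    stop_voxflap(sprintf("multi-frame DICOM unsupported: %s", path),
                 "voxflap_unsupported_input")
  if (!out$bits %in% c(8L, 16L))
    stop_voxflap(sprintf("unsupported BitsAllocated %d: %s", out$bits, path),
                 "voxflap_unsupported_input")
  out
}

#' @rdname read_volume
#' @param dir Directory holding the slices of one DICOM series.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  assert_that(length(files) > 0, sprintf("no files in DICOM directory %s", dir),
              class = "voxflap_format_error")
  slices <- lapply(files, parse_dicom_file)

  ref <- slices[[1]]
  for (s in slices) {
    if (s$rows != ref$rows || s$cols != ref$cols)
      stop_voxflap("heterogeneous slice dimensions in series",
                   "voxflap_format_error")
    if (max(abs(s$pixel_spacing - ref$pixel_spacing)) > 1e-6)
      stop_voxflap("heterogeneous pixel spacing in series",
                   "voxflap_format_error")
    if (max(abs(s$orientation - ref$orientation)) > 1e-4)
      stop_voxflap("inconsistent slice orientation in series",
                   "voxflap_format_error")
  }
  if (max(abs(ref$orientation - c(1, 0, 0, 0, 1, 0))) > 1e-4)
    stop_voxflap("only axis-aligned slice orientation (1,0,0 / 0,1,0) is supported",
                 "voxflap_unsupported_input")

  zs <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  nz <- length(slices)
  if (nz > 1) {
    dz <- diff(zs)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3)
      stop_voxflap("slices are not uniformly spaced along the series axis",
                   "voxflap_format_error")
    sz <- mean(dz)
  } else {
    sz <- 1
  }
  xy0 <- slices[[1]]$position[1:2]
  for (s in slices)
    if (max(abs(s$position[1:2] - xy0)) > 1e-3)
      stop_voxflap("slices are sheared (in-plane positions differ)",
                   "voxflap_format_error")

  rows <- ref$rows
  cols <- ref$cols
  data <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    stored <- readBin(s$pixel_raw, "integer", n = rows * cols,
                      size = s$bits / 8L, signed = s$signed,
                      endian = "little")
    # DICOM pixel data is row-major: first Rows entries... actually first row
    # spans the columns, so column index varies fastest.
    data[, , k] <- matrix(s$slope * stored + s$intercept, nrow = cols)
  }
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  spacing <- c(ref$pixel_spacing[2], ref$pixel_spacing[1], sz)
  scalar_volume(data, spacing = spacing,
                origin = c(xy0[1], xy0[2], zs[1]))
}
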