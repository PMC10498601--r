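# Volume intake, Hounsfield-range segmentation, ROI sampling, brush edits.

test_that("NIfTI write/read round trip preserves data and geometry", {
  vol <- scalar_volume(array(rnorm(8 * 7 * 6, 0, 100), c(8, 7, 6)),
                       spacing = c(0.8, 1, 1.25), origin = c(-4, 3, 10))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, format = "nifti")
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  unlink(path)
})

test_that("volume and mask constructors enforce their invariants", {
  expect_error(scalar_volume(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(scalar_volume(matrix(0, 4, 4), spacing = c(1, 1, 1)), "3D")
  vol <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(label_mask(array(2, c(4, 4, 4)), vol), "0/1")
  expect_error(segmentation_params(230, 180), "less than")
})

test_that("threshold_segment equals the inclusive per-voxel predicate", {
  set.seed(11)
  vol <- scalar_volume(array(runif(10^3, -200, 1300), c(10, 10, 10)),
                       spacing = c(1, 1, 1))
  for (rng in list(c(180, 230), c(900, 1100), c(-100, 0))) {
    got <- threshold_segment(vol, segmentation_params(rng[1], rng[2]))
    # independent oracle: explicit per-voxel loop
    oracle <- array(0L, dim(vol$data))
    for (i in seq_along(vol$data))
      oracle[i] <- as.integer(vol$data[i] >= rng[1] & vol$data[i] <= rng[2])
    expect_identical(got$data, oracle)
  }
  # printed muscle window is inclusive at both ends
  vol2 <- scalar_volume(array(c(-80, 205, 950, 1200, 180, 230, 179.9, 230.1),
                              c(8, 1, 1)), spacing = c(1, 1, 1))
  m <- threshold_segment(vol2, segmentation_params(180, 230))
  expect_identical(as.vector(m$data), c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
})

test_that("small-component filter removes islands and is idempotent", {
  d <- array(0, c(12, 6, 6))
  d[2:6, 3, 3] <- 1    # 5-voxel blob
  d[10:11, 3, 3] <- 1  # 2-voxel island
  vol <- scalar_volume(d * 200, spacing = c(1, 1, 1))
  p <- segmentation_params(150, 250, min_component_voxels = 3)
  m <- threshold_segment(vol, p)
  expect_equal(sum(m$data), 5)
  expect_equal(sum(m$data[10:11, 3, 3]), 0)
  # re-applying the same size filter changes nothing
  vol2 <- scalar_volume(m$data * 200, spacing = c(1, 1, 1))
  m2 <- threshold_segment(vol2, p)
  expect_identical(m2$data, m$data)
  # all-zero segmentation is valid but warns
  expect_warning(threshold_segment(vol, segmentation_params(500, 600)),
                 "empty")
})

test_that("reference-range sampling reproduces the printed vessel window", {
  vol <- scalar_volume(array(1000, c(20, 20, 20)), spacing = c(1, 1, 1))
  res <- sample_reference_range(vol, roi_center = c(10, 10, 10),
                                roi_radius = 5)
  expect_equal(res$mean_hu, 1000)
  expect_equal(res$params$hu_lo, 900)
  expect_equal(res$params$hu_hi, 1100)

  vol0 <- scalar_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
  res0 <- sample_reference_range(vol0, c(5, 5, 5), 3, half_width = 50)
  expect_equal(c(res0$params$hu_lo, res0$params$hu_hi), c(-50, 50))

  expect_error(sample_reference_range(vol, c(500, 500, 500), 5),
               class = "voxflap_empty_roi")
})

test_that("brush strokes bridge gaps, erase totally, and are monotone", {
  geo <- scalar_volume(array(0, c(20, 7, 7)), spacing = c(1, 1, 1))
  tube <- array(0L, c(20, 7, 7))
  tube[c(2:8, 11:18), 4, 4] <- 1L  # 2-voxel gap at x = 9:10
  mask <- label_mask(tube, geo, "vessels")
  lab <- label_components_cpp(as.integer(mask$data), dim(mask$data), 6L)
  expect_equal(max(lab), 2L)
  filled <- apply_brush(mask, brush_stroke("fill",
                                           rbind(c(7, 3, 3), c(10, 3, 3)),
                                           radius = 1.8))
  lab2 <- label_components_cpp(as.integer(filled$data), dim(filled$data), 6L)
  expect_equal(max(lab2), 1L)  # 6-connected along the tube axis
  # fill is monotone non-decreasing, erase non-increasing
  expect_true(all(filled$data >= mask$data))
  erased <- apply_brush(filled, brush_stroke("erase", c(10, 3, 3), 50))
  expect_equal(sum(erased$data), 0)
  expect_true(all(erased$data <= filled$data))
  # fill then identical erase over previously empty support restores the mask
  st_fill <- brush_stroke("fill", c(16, 1, 1), 1.2)
  st_erase <- brush_stroke("erase", c(16, 1, 1), 1.2)
  roundtrip <- apply_brush(apply_brush(mask, st_fill), st_erase)
  expect_identical(roundtrip$data, mask$data)
})

test_that("DICOM series reading applies rescale and checks consistency", {
  # stored value 1224 with intercept -1024 is 200 HU
  dir <- tempfile("dcm")
  dir.create(dir)
  px <- matrix(1224L, 6, 5)
  for (k in 1:2)
    write_test_dicom_slice(file.path(dir, sprintf("s%d.dcm", k)), px,
                           position = c(-10, 5, (k - 1) * 2.5),
                           pixel_spacing = c(0.75, 0.5),
                           slope = 1, intercept = -1024)
  vol <- read_volume(dir, format = "dicom_series")
  expect_equal(dim(vol$data), c(6L, 5L, 2L))
  expect_true(all(vol$data == 200))
  expect_equal(vol$spacing, c(0.75, 0.5, 2.5))
  expect_equal(vol$origin, c(-10, 5, 0))

  # inconsistent orientation across slices is a format error
  write_test_dicom_slice(file.path(dir, "s3.dcm"), px,
                         position = c(-10, 5, 5),
                         orientation = c(0, 1, 0, 1, 0, 0),
                         pixel_spacing = c(0.75, 0.5),
                         slope = 1, intercept = -1024)
  expect_error(read_volume(dir, format = "dicom_series"),
               class = "voxflap_format_error")
  unlink(dir, recursive = TRUE)
})

test_that("DICOM reader agrees with an independent writer (pydicom)", {
  dir <- tempfile("pydcm")
  dir.create(dir)
  script <- sprintf('
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
for k in range(3):
    ds = Dataset()
    ds.SOPClassUID = "1.2.840.10008.5.1.4.1.1.2"
    ds.SOPInstanceUID = generate_uid()
    ds.Rows, ds.Columns = 4, 5
    ds.PixelSpacing = [1.5, 0.5]      # row, col
    ds.ImagePositionPatient = [1.0, 2.0, 3.0 + 2.0 * k]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleSlope = 2.0; ds.RescaleIntercept = -1024.0
    arr = (np.arange(20, dtype=np.int16) + 100 * k).reshape(4, 5)
    ds.PixelData = arr.tobytes()
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = ds.SOPClassUID
    meta.MediaStorageSOPInstanceUID = ds.SOPInstanceUID
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta = meta
    ds.save_as("%s/py_%%02d.dcm" %% k, enforce_file_format=True)
', dir)
  pyfile <- tempfile(fileext = ".py")
  writeLines(script, pyfile)
  status <- system2("python", pyfile, stdout = TRUE, stderr = TRUE)
  expect_length(list.files(dir), 3)
  vol <- read_volume(dir, format = "dicom_series")
  expect_equal(dim(vol$data), c(5L, 4L, 3L))
  expect_equal(vol$spacing, c(0.5, 1.5, 2))
  expect_equal(vol$origin, c(1, 2, 3))
  # arr.reshape(4,5) is row-major: row r, col c holds 5*r + c
  expected_slice1 <- 2 * outer(0:4, 0:3, function(c_, r) 5 * r + c_) - 1024
  expect_equal(vol$data[, , 1], expected_slice1)
  # slice 3 stores values offset by 200, scaled by the rescale slope of 2
  expect_equal(vol$data[, , 3], expected_slice1 + 400)
  unlink(dir, recursive = TRUE)
})

test_that("segmentation of the noisy phantom stays above the pinned Dice", {
  # thresholds pinned from a pre-build oracle run at sigma = 20 HU
  ph <- small_phantom(seed = 3, noise_sd = 20)
  pm <- segmentation_params(180, 230, smoothing_sigma = 1,
                            min_component_voxels = 27)
  pv <- segmentation_params(900, 1100, smoothing_sigma = 1,
                            min_component_voxels = 27)
  expect_gt(dice_coefficient(threshold_segment(ph$volume, pm),
                             ph$truth$muscle), 0.95)
  expect_gt(dice_coefficient(threshold_segment(ph$volume, pv),
                             ph$truth$vessels), 0.89)
})
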