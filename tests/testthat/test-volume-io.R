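test_that("raw volumes round-trip bit-exactly with sidecar metadata", {
  dir <- withr::local_tempdir()
  set.seed(1)
  v <- GrayVolume(array(as.numeric(sample(0:65535, 16^3, TRUE)),
                        c(16, 16, 16)), 100)
  p <- file.path(dir, "vol.json")
  writeVolume(v, p, dtype = "uint16")
  r <- readVolume(p)
  expect_identical(volData(r), volData(v))
  expect_identical(voxelSize(r), 100)
})

test_that("raw reader reports missing metadata keys and size mismatches", {
  dir <- withr::local_tempdir()
  meta <- file.path(dir, "vol.json")
  jsonlite::write_json(list(dims = c(4, 4, 4), dtype = "uint16"),
                       meta, auto_unbox = TRUE)
  expect_error(readVolume(meta), "voxel_size_um")
  jsonlite::write_json(list(dims = c(4, 4, 4), dtype = "uint16",
                            voxel_size_um = 50, data_file = "vol.raw"),
                       meta, auto_unbox = TRUE)
  writeBin(integer(10), file.path(dir, "vol.raw"), size = 2)
  expect_error(readVolume(meta), "size mismatch")
})

test_that("MHD round-trips floats and preserves the 175 um voxel size", {
  dir <- withr::local_tempdir()
  set.seed(2)
  v <- GrayVolume(array(runif(10^3), c(10, 10, 10)), 175)
  p <- file.path(dir, "vol.mhd")
  writeVolume(v, p, dtype = "float64")
  r <- readVolume(p)
  expect_equal(volData(r), volData(v))
  expect_equal(voxelSize(r), 175)
  # float32 loses precision but keeps geometry
  writeVolume(v, p, dtype = "float32")
  r32 <- readVolume(p)
  expect_equal(volData(r32), volData(v), tolerance = 1e-6)
})

test_that("TIFF stacks read slice-per-page with sidecar voxel size", {
  dir <- withr::local_tempdir()
  v <- GrayVolume(array(as.numeric(sample(0:65535, 5 * 8 * 8, TRUE)),
                        c(5, 8, 8)), 87.7)
  p <- file.path(dir, "stack.tif")
  writeVolume(v, p)
  r <- readVolume(p)
  expect_identical(dim(r), c(5L, 8L, 8L))
  expect_identical(volData(r), volData(v))
  expect_equal(voxelSize(r), 87.7)
})

test_that("binning averages blocks, drops partials and scales voxel size", {
  v <- GrayVolume(array(c(0, 0, 0, 0, 8, 8, 8, 8), c(2, 2, 2)), 87.7)
  b <- binVolume(v, 2)
  expect_identical(dim(b), c(1L, 1L, 1L))
  expect_equal(volData(b)[1, 1, 1], 4)
  expect_equal(voxelSize(b), 175.4)

  cv <- GrayVolume(array(7, c(6, 6, 6)), 100)
  expect_true(all(volData(binVolume(cv, 2)) == 7))

  # partial blocks dropped; mean-pooling conserves the cropped sum
  set.seed(3)
  w <- GrayVolume(array(runif(7 * 9 * 5), c(7, 9, 5)), 50)
  b2 <- binVolume(w, 2)
  expect_identical(dim(b2), c(3L, 4L, 2L))
  expect_equal(sum(volData(b2)) * 8, sum(volData(w)[1:6, 1:8, 1:4]))
  expect_error(binVolume(w, 0), "positive integer")
})

test_that("gray-to-attenuation is affine, invertible and monotone", {
  v <- GrayVolume(array(c(0, 100, 65535, 5), c(1, 2, 2)), 87.7)
  expect_equal(volData(grayToAttenuation(v)), volData(v))  # identity
  cal <- AttenuationCalibration(slope = 0.24 / 65535, intercept = 0)
  a <- grayToAttenuation(v, cal)
  expect_equal(volData(a)[1, 2, 2], 0.24 * 5 / 65535)
  expect_equal(max(volData(a)), 0.24)  # gray 65535 maps to the window top
  cal2 <- AttenuationCalibration(slope = 1, intercept = 0.05)
  expect_equal(volData(grayToAttenuation(v, cal2))[1, 1, 1], 0.05)
  # invertible
  back <- attenuationToGray(a, cal)
  expect_equal(volData(back), volData(v), tolerance = 1e-12)
  # strictly monotone for slope > 0
  g <- sort(runif(10, 0, 1000))
  m <- grayToAttenuation(GrayVolume(array(g, c(10, 1, 1)), 1), cal)
  expect_true(all(diff(as.vector(volData(m))) > 0))
  expect_error(AttenuationCalibration(slope = -1), "slope")
})
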