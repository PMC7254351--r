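test_that("raw binary volumes round-trip bitwise", {
  vol <- randomVolume(c(4L, 3L, 2L), seed = 1, dzUm = 2.5, dxUm = 10,
                      dyUm = 12, surfaceIndex = 1L)
  f <- tempfile(fileext = ".raw")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_identical(volData(back), volData(vol))
  expect_identical(voxelPitch(back), voxelPitch(vol))
  expect_identical(surfaceIndex(back), 1L)
})

test_that("TIFF stacks round-trip at the stored precision", {
  # values exactly representable in float32 round-trip bitwise
  set.seed(2)
  a <- array(sample(0:255, 24, replace = TRUE) / 255, c(4L, 3L, 2L))
  a[1, 1, 1] <- 1                      # pin data_max at 1
  vol <- OctaVolume(a, 4, 16, 16)
  f <- tempfile(fileext = ".tif")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_identical(dim(back), c(4L, 3L, 2L))
  expect_equal(volData(back), a, tolerance = 1e-7)
  # amplitudes above 1 survive through the recorded data_max
  vol2 <- OctaVolume(a * 37.5, 4, 16, 16)
  f2 <- tempfile(fileext = ".tif")
  writeVolume(vol2, f2)
  expect_equal(volData(readVolume(f2)), volData(vol2),
               tolerance = 1e-6)
})

test_that("a 4-page TIFF of 3x2 slices reads as nz=4, nx=3, ny=2", {
  vol <- OctaVolume(array(seq(0, 1, length.out = 24), c(4L, 3L, 2L)),
                    4, 16, 16)
  f <- tempfile(fileext = ".tif")
  writeVolume(vol, f)
  expect_identical(dim(readVolume(f)), c(4L, 3L, 2L))
  # one bright voxel stays at its page and position
  a <- array(0, c(4L, 3L, 2L)); a[3, 2, 1] <- 1
  f2 <- tempfile(fileext = ".tif")
  writeVolume(OctaVolume(a, 4, 16, 16), f2)
  b <- volData(readVolume(f2))
  expect_identical(which(b == max(b)),
                   which(a == 1))
})

test_that("axis order in the sidecar normalizes the cube to (z,x,y)", {
  set.seed(5)
  a <- array(runif(2 * 3 * 4), c(2L, 3L, 4L))     # (z, x, y)
  fz <- tempfile(fileext = ".raw")
  writeBin(as.vector(a), fz, size = 8L, endian = "little")
  jsonlite::write_json(
    list(dtype = "float64", shape = c(2, 3, 4), axis_order = "zxy",
         dz_um = 4, dx_um = 16, dy_um = 16),
    paste0(fz, ".json"), auto_unbox = TRUE)
  # the same cube stored (y, x, z)
  fy <- tempfile(fileext = ".raw")
  writeBin(as.vector(aperm(a, c(3, 2, 1))), fy, size = 8L,
           endian = "little")
  jsonlite::write_json(
    list(dtype = "float64", shape = c(4, 3, 2), axis_order = "yxz",
         dz_um = 4, dx_um = 16, dy_um = 16),
    paste0(fy, ".json"), auto_unbox = TRUE)
  expect_identical(volData(readVolume(fz)), a)
  expect_identical(volData(readVolume(fy)), a)
})

test_that("inconsistent or invalid stored volumes are rejected", {
  f <- tempfile(fileext = ".raw")
  writeBin(runif(100), f, size = 8L, endian = "little")
  jsonlite::write_json(
    list(dtype = "float64", shape = c(8, 4, 4), axis_order = "zxy",
         dz_um = 4, dx_um = 16, dy_um = 16),
    paste0(f, ".json"), auto_unbox = TRUE)
  expect_error(readVolume(f), "declares shape 8x4x4")

  neg <- tempfile(fileext = ".raw")
  v <- rep(1, 8); v[5] <- -0.25      # (z=1, x=2, y=1) in a 4x2x1 cube
  writeBin(v, neg, size = 8L, endian = "little")
  jsonlite::write_json(
    list(dtype = "float64", shape = c(4, 2, 1), axis_order = "zxy",
         dz_um = 4, dx_um = 16, dy_um = 16),
    paste0(neg, ".json"), auto_unbox = TRUE)
  expect_error(readVolume(neg), "negative voxel at \\(z=1, x=2, y=1\\)")

  nan <- tempfile(fileext = ".raw")
  v <- rep(1, 8); v[1] <- NaN
  writeBin(v, nan, size = 8L, endian = "little")
  jsonlite::write_json(
    list(dtype = "float64", shape = c(4, 2, 1), axis_order = "zxy",
         dz_um = 4, dx_um = 16, dy_um = 16),
    paste0(nan, ".json"), auto_unbox = TRUE)
  expect_error(readVolume(nan), "NaN voxel at \\(z=1, x=1, y=1\\)")

  expect_error(readVolume(tempfile()), "not found")
})

test_that("angiograms rescale linearly onto the 16-bit range", {
  img <- Angiogram(matrix(c(0, 1, 2, 3), 2, 2), c(440, 460))
  f <- tempfile(fileext = ".tif")
  writeAngiogram(img, f)
  pix <- round(tiff::readTIFF(f) * 65535)
  expect_identical(sort(as.integer(pix)), c(0L, 21845L, 43690L, 65535L))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$depth_range_um, c(440, 460))
  # round trip preserves the argmax location
  expect_identical(which.max(pix), which.max(angioData(img)))
  # constant image: all zeros plus a warning, not an error
  f2 <- tempfile(fileext = ".tif")
  expect_warning(writeAngiogram(Angiogram(matrix(5, 2, 2), c(0, 10)),
                                f2),
                 "constant")
  expect_true(all(tiff::readTIFF(f2) == 0))
})
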