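test_that("pot detection recovers radius and center of a rasterized annulus", {
  # inner radius 17 mm at 1 mm voxels (34 mm inner diameter pot)
  v <- annulusVolume(n = 48, nz = 6, rInVox = 17, wallVox = 4)
  pot <- detectPot(v, c(0.3, 0.7), wallThicknessMm = 4)
  expect_equal(mean(pot@innerRadiusMm), 17, tolerance = 1 / 17)
  expect_true(all(pot@fitted))

  off <- annulusVolume(n = 48, nz = 6, rInVox = 15, wallVox = 4,
                       centerOff = c(3, -3))
  pot2 <- detectPot(off, c(0.3, 0.7), wallThicknessMm = 4)
  c0 <- (48 + 1) / 2
  expect_lt(max(abs(pot2@centerYx[, 1] - (c0 + 3))), 1)
  expect_lt(max(abs(pot2@centerYx[, 2] - (c0 - 3))), 1)

  empty <- GrayVolume(array(0.1, c(4, 20, 20)), 1000)
  expect_error(detectPot(empty, c(0.3, 0.7), 2), "no pot detected")
})

test_that("pot removal strips wall and margin but preserves the interior", {
  v <- annulusVolume(n = 48, nz = 6, rInVox = 17, wallVox = 4)
  pot <- detectPot(v, c(0.3, 0.7), wallThicknessMm = 4)

  # margin 0: interior untouched
  r0 <- removePot(v, pot, soilMarginMm = 0.5)
  c0 <- (48 + 1) / 2
  jj <- matrix(seq_len(48), 48, 48)
  kk <- matrix(seq_len(48), 48, 48, byrow = TRUE)
  inside <- sqrt((jj - c0)^2 + (kk - c0)^2) < 15
  for (z in 1:6)
    expect_equal(volData(r0)[z, , ][inside], volData(v)[z, , ][inside])
  # wall zeroed
  wall <- sqrt((jj - c0)^2 + (kk - c0)^2) >= 17.5
  expect_true(all(volData(r0)[1, , ][wall] == 0))

  # margin 1 mm on a 17 mm pot: retained disc radius 16 mm +- 1 voxel
  r1 <- removePot(v, pot, soilMarginMm = 1)
  kept <- volData(r1)[3, , ] != 0
  area <- sum(kept)
  expect_equal(area, pi * 16^2, tolerance = 2 * 2 * pi * 16 / (pi * 16^2))

  expect_error(removePot(v, pot, soilMarginMm = 30), "margin")
})

test_that("attenuation windowing zeroes outside values and is idempotent", {
  const <- GrayVolume(array(0.30, c(6, 6, 6)), 1000)
  expect_true(all(volData(attenuationWindow(const, 0.11, 0.24)) == 0))

  set.seed(4)
  v <- GrayVolume(array(runif(6^3, 0, 0.6), c(6, 6, 6)), 1000)
  w <- attenuationWindow(v, -Inf, Inf)
  expect_equal(volData(w), volData(v))

  two <- GrayVolume(array(c(0.15, 0.5), c(6, 6, 6)), 1000)
  tw <- attenuationWindow(two, 0.11, 0.24)
  expect_true(all(volData(tw) %in% c(0, 0.15)))
  expect_equal(sum(volData(tw) == 0.15), sum(volData(two) == 0.15))

  w1 <- attenuationWindow(v, 0.11, 0.24)
  expect_identical(volData(attenuationWindow(w1, 0.11, 0.24)), volData(w1))
  expect_error(attenuationWindow(v, 0.3, 0.2), "aMin")
})

test_that("soil surface map follows flat soil and depressions", {
  d <- c(30, 20, 20)
  arr <- array(0.01, d)
  arr[12:30, , ] <- 0.18
  s <- detectSoilSurface(GrayVolume(arr, 1000), aMin = 0.11)
  expect_true(all(s@topDepth == 12))

  # 3-slice-deep central depression
  arr2 <- arr
  arr2[12:14, 8:12, 8:12] <- 0.01
  s2 <- detectSoilSurface(GrayVolume(arr2, 1000), aMin = 0.11)
  expect_true(all(s2@topDepth[8:12, 8:12] == 15))
  expect_true(all(s2@topDepth[1:5, ] == 12))

  expect_error(detectSoilSurface(GrayVolume(array(0, d), 1000), aMin = 0.11),
               "no soil")
})

test_that("the entry point lands on a dark rod piercing the surface", {
  set.seed(9)
  d <- c(40, 30, 30)
  arr <- array(0.01, d)
  arr[10:40, , ] <- 0.18 + rnorm(31 * 30 * 30, 0, 0.004)
  # vertical dark rod entering at (y=14, x=21)
  for (i in 10:35)
    for (j in 12:16) for (k in 19:23)
      if ((j - 14)^2 + (k - 21)^2 <= 4) arr[i, j, k] <- 0.15
  # the pipeline windows before surface detection; air drops to the sentinel
  win <- attenuationWindow(GrayVolume(arr, 1000), 0.11, 0.24)
  s <- detectSoilSurface(win, aMin = 0.11)
  expect_lt(abs(s@entryPoint[2] - 14), 1.5)
  expect_lt(abs(s@entryPoint[3] - 21), 1.5)
  expect_lt(abs(s@entryPoint[1] - 10), 2.5)
})

test_that("pot and surface models serialize to JSON", {
  v <- annulusVolume(n = 32, nz = 4, rInVox = 12, wallVox = 4)
  pot <- detectPot(v, c(0.3, 0.7), 4)
  f <- withr::local_tempfile(fileext = ".json")
  writeQcJson(pot, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$type, "PotModel")
  expect_equal(back$wall_thickness_mm, 4)
})
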