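flatSurface <- function(dims, slice) {
  new("SoilSurface", topDepth = matrix(slice, dims[2], dims[3]),
      entryPoint = c(slice, dims[2] / 2, dims[3] / 2),
      meanDepthSlices = slice)
}

test_that("root volume is voxel count times cubic voxel volume", {
  arr <- array(TRUE, c(10, 10, 10))  # 1000 voxels at 100 um
  expect_equal(rootVolume(RootMask(arr, 100)), 1.0)
  expect_equal(rootVolume(RootMask(array(FALSE, c(5, 5, 5)), 100)), 0)

  # rasterized cylinder r = 1 mm, h = 10 mm at 50 um voxels
  d <- c(220, 50, 50)
  cyl <- solidCylinder(d, center = c(25, 25), radius = 20, from = 11,
                       to = 210)
  expect_equal(rootVolume(RootMask(cyl, 50)), pi * 10, tolerance = 0.02)
})

test_that("depth quantiles interpolate the cumulative biomass profile", {
  d <- c(110, 20, 20)
  surface <- flatSurface(d, 10)
  # uniform rod spanning 0-100 mm below the surface (1 mm voxels)
  rod <- array(FALSE, d)
  rod[10:109, 10, 10] <- TRUE
  prof <- depthProfile(RootMask(rod, 1000), surface)
  expect_equal(quantileDepth(prof, 0.5), 50, tolerance = 1.5)
  expect_error(quantileDepth(prof, 1.2), "q must")

  # all mass in one slice at 40 mm
  one <- array(FALSE, d)
  one[50, 5:15, 5:15] <- TRUE
  p1 <- depthProfile(RootMask(one, 1000), surface)
  for (q in c(0.25, 0.5, 0.9))
    expect_equal(quantileDepth(p1, q), 40, tolerance = 1)

  # two equal blocks at 10 mm and 90 mm
  two <- array(FALSE, d)
  two[20, 5:10, 5:10] <- TRUE
  two[100, 5:10, 5:10] <- TRUE
  p2 <- depthProfile(RootMask(two, 1000), surface)
  expect_equal(quantileDepth(p2, 0.25), 10, tolerance = 1)
  expect_equal(quantileDepth(p2, 0.75), 90, tolerance = 1)
  # monotone in q
  qs <- vapply(c(0.25, 0.5, 0.75, 0.9), quantileDepth, 1.0,
               profile = p2)
  expect_true(all(diff(qs) >= 0))
})

test_that("form fraction is 100% for a solid cube and errors when flat", {
  cube <- RootMask(array(TRUE, c(8, 8, 8)), 1000)
  expect_equal(formFraction(cube), 100, tolerance = 1e-9)

  plate <- array(FALSE, c(6, 10, 10)); plate[3, , ] <- TRUE
  expect_error(formFraction(RootMask(plate, 1000)), "coplanar")

  # thin rod in a wide volume: F equals the analytic rod/hull ratio
  d <- c(52, 40, 40)
  rod <- solidCylinder(d, center = c(20, 20), radius = 2.5, from = 2,
                       to = 51)
  f <- formFraction(RootMask(rod, 1000))
  vr <- sum(rod)
  # independent oracle: the rod hull is (2D hull of disc voxel corners) x
  # height; polygon area by the shoelace formula
  jj <- which(rod[2, , ] , arr.ind = TRUE)
  corners <- do.call(rbind, lapply(list(c(-.5,-.5), c(-.5,.5), c(.5,-.5),
                                        c(.5,.5)),
                                   function(o) sweep(jj, 2, o, "+")))
  ch <- grDevices::chull(corners)
  poly <- corners[ch, ]
  nn <- nrow(poly)
  area <- abs(sum(poly[, 1] * poly[c(2:nn, 1), 2] -
                    poly[c(2:nn, 1), 1] * poly[, 2])) / 2
  expect_equal(f, 100 * vr / (50 * area), tolerance = 0.01)

  # a mask equal to its own hull rasterized approaches 100% from below;
  # the corner-expanded hull circumscribes the voxel ball, so the loss is
  # about (1 + 0.5/r)^-3 plus faceting (~8% at r = 19)
  ball <- array(FALSE, c(41, 41, 41))
  for (i in 1:41) for (j in 1:41) for (k in 1:41)
    if ((i - 21)^2 + (j - 21)^2 + (k - 21)^2 <= 19^2) ball[i, j, k] <- TRUE
  fb <- formFraction(RootMask(ball, 1000))
  expect_gte(fb, 88)
  expect_lte(fb, 100)

  # invariant under axis permutation
  rodP <- aperm(rod, c(3, 1, 2))
  expect_equal(formFraction(RootMask(rodP, 1000)), f, tolerance = 1e-6)
})

test_that("hull-face root angles span a dome and vanish on a plate", {
  # dome: spherical cap rising toward the surface (apex up)
  d <- c(34, 61, 61)
  arr <- array(FALSE, d)
  for (i in 1:34) for (j in 1:61) for (k in 1:61) {
    r2 <- (i - 30)^2 + (j - 31)^2 + (k - 31)^2
    if (r2 <= 28^2 && r2 >= 25^2 && i <= 30) arr[i, j, k] <- TRUE
  }
  a <- rootAngles(RootMask(arr, 1000))
  expect_lt(a["thetaMin"], 8)
  expect_gt(a["thetaMax"], 80)
  expect_true(a["thetaMin"] <= a["thetaMean"] &&
                a["thetaMean"] <= a["thetaMax"])

  # flat plate (1 voxel thick): all top faces horizontal
  plate <- array(FALSE, c(6, 15, 15)); plate[3, 3:13, 3:13] <- TRUE
  ap <- rootAngles(RootMask(plate, 1000))
  expect_lt(ap["thetaMax"], 1e-6)

  # narrow vertical cone, apex at the top, half-angle ~10 degrees
  dc <- c(60, 45, 45)
  cone <- array(FALSE, dc)
  for (i in 3:55) {
    r <- max(0.8, (i - 3) * tan(10 * pi / 180))
    jj <- matrix(seq_len(45), 45, 45)
    kk <- matrix(seq_len(45), 45, 45, byrow = TRUE)
    cone[i, , ] <- (jj - 23)^2 + (kk - 23)^2 <= r^2
  }
  ac <- rootAngles(RootMask(cone, 1000))
  expect_equal(unname(ac["thetaMean"]), 80, tolerance = 3 / 80)
})

test_that("densities combine gray and attenuation as documented", {
  d <- c(12, 12, 12)
  mask <- array(FALSE, d); mask[4:8, 4:8, 4:8] <- TRUE
  interior <- array(TRUE, d)
  # identical gray for root and soil: relation exactly 100%
  g <- GrayVolume(array(1000, d), 500)
  a <- GrayVolume(array(0.2, d), 500)
  dens <- rootDensities(g, a, RootMask(mask, 500), interior, radiusMm = 1)
  expect_equal(dens$earthRootRelationPct, 100)

  # soil gray 1.15x root gray: relation ~ 115%
  g2arr <- array(1150, d); g2arr[mask] <- 1000
  dens2 <- rootDensities(GrayVolume(g2arr, 500), a, RootMask(mask, 500),
                         interior, radiusMm = 1)
  expect_equal(dens2$earthRootRelationPct, 115, tolerance = 1e-6)

  # halo: soil density raised only within 1 mm of roots
  g3 <- array(1000, d)
  e2 <- array(rootCT:::cpp_edt_sq(as.vector(!mask), d, FALSE), d)
  halo <- !mask & e2 <= 4   # within 2 voxels = 1 mm at 500 um
  g3[halo] <- 2000
  dens3 <- rootDensities(GrayVolume(g3, 500), a, RootMask(mask, 500),
                         interior, radiusMm = 1)
  expect_gt(dens3$soilDensityAroundRoots, dens3$meanSoilDensity)

  expect_error(rootDensities(g, a, RootMask(array(FALSE, d), 500),
                             interior), "empty")
})

test_that("volume is additive over disjoint masks", {
  a <- array(FALSE, c(10, 10, 10)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[7:9, , ] <- TRUE
  va <- rootVolume(RootMask(a, 200))
  vb <- rootVolume(RootMask(b, 200))
  expect_equal(rootVolume(RootMask(a | b, 200)), va + vb)
})
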