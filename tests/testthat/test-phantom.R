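test_that("tree generation is deterministic and respects branching rules", {
  spec <- phantomSpec(seed = 21L)
  t1 <- generateRootTree(spec)
  t2 <- generateRootTree(spec)
  expect_identical(rlang::hash(t1), rlang::hash(t2))

  # branch probability 0: a single unbranched axis with one tip
  s0 <- phantomSpec(seed = 3L, branchProbability = 0)
  tr0 <- generateRootTree(s0)
  expect_length(tr0$branches, 1)
  expect_equal(sum(vapply(tr0$branches, `[[`, TRUE, "isTip")), 1)

  # full binary branching to depth 3: 8 tips
  s8 <- phantomSpec(seed = 3L, branchProbability = 1,
                    branchingDepth = 3L)
  tr8 <- generateRootTree(s8)
  expect_equal(sum(vapply(tr8$branches, `[[`, TRUE, "isTip")), 8)

  # impossible geometry errors
  expect_error(generateRootTree(phantomSpec(potInnerDiameterMm = 3,
                                            diameterStartVox = 6)),
               "outside the pot")
})

test_that("rasterization records truth before degradation", {
  spec <- phantomSpec(seed = 4L, branchProbability = 0, noiseSd = 0,
                      blurSigmaVox = 0, soilSd = 0, stoneDensity = 0)
  ph <- rasterizePhantom(generateRootTree(spec), spec)
  # no degradation, uniform soil: thresholding recovers the mask exactly
  arr <- volData(ph$volume)
  got <- arr < 0.165 & arr > 0.1
  tm <- volData(ph$truth@mask)
  # interior voxels recovered exactly; boundary voxels carry coverage mix
  core <- tm & array(rootCT:::cpp_edt_sq(as.vector(tm), dim(tm), TRUE),
                     dim(tm)) > 1
  expect_true(all(got[core]))
  expect_lt(sum(got & !tm) / sum(tm), 0.35)  # only the partial-volume rim

  # single unbranched tube: truth volume close to the analytic tube volume
  vmm <- voxelSize(ph$volume) / 1000
  rs <- lapply(ph$truth@polylines, function(p)
    rootCT:::resamplePolyline(p, attr(p, "diameterVox"), 0.25))
  analytic <- sum(vapply(rs, function(r) {
    step <- r$length / (nrow(r$points) - 1)
    sum(pi * (r$diameter * vmm / 2)^2) * step
  }, 1.0))
  expect_equal(ph$truth@vRootMm3, analytic, tolerance = 0.05)
  expect_equal(ph$truth@lengthMm,
               sum(vapply(rs, `[[`, 1.0, "length")))
})

test_that("storage roots render thick and internally homogeneous", {
  spec <- phantomSpec(seed = 6L, potInnerDiameterMm = 56, voxelSizeUm = 500,
                      nStorageRoots = 1L, storageDiameterVox = 45,
                      branchingDepth = 1L, potDepthMm = 36,
                      soilMean = 0.26, soilSd = 0.012)
  ph <- rasterizePhantom(generateRootTree(spec), spec)
  tm <- volData(ph$truth@mask)
  e2 <- array(rootCT:::cpp_edt_sq(as.vector(tm), dim(tm), TRUE), dim(tm))
  # a 45-voxel-diameter structure is present
  expect_gt(2 * sqrt(max(e2)), 40)
  # its deep interior is more homogeneous than soil
  core <- tm & e2 > 64
  arr <- volData(ph$volume)
  soil <- !tm & arr > 0.2
  expect_lt(stats::sd(arr[core]), stats::sd(arr[soil]))
})

test_that("a zero growth rate reproduces identical time steps", {
  spec <- phantomSpec(seed = 8L, potDepthMm = 20, branchingDepth = 1L)
  ser <- phantomTimeSeries(spec, nSteps = 3, growthRateMm3PerDay = 0)
  expect_length(ser, 3)
  expect_identical(volData(ser[[1]]$volume), volData(ser[[3]]$volume))
  expect_identical(ser[[1]]$truth@vRootMm3, ser[[3]]$truth@vRootMm3)
})

test_that("storage bulking recovers the configured volumetric growth rate", {
  # one storage capsule: the crown region where several capsules would
  # merge has no closed-form volume, and the generator targets the rate
  # analytically
  spec <- phantomSpec(seed = 9L, potInnerDiameterMm = 70, voxelSizeUm = 700,
                      potDepthMm = 40, nStorageRoots = 1L,
                      storageDiameterVox = 24, branchingDepth = 1L,
                      soilMean = 0.26, soilSd = 0.012)
  rate <- 500
  ser <- phantomTimeSeries(spec, nSteps = 8, growthRateMm3PerDay = rate,
                           daysPerStep = 3)
  days <- vapply(ser, `[[`, 1.0, "day")
  vols <- vapply(ser, function(s) s$truth@vRootMm3, 1.0)
  expect_true(all(diff(vols) > 0))
  slope <- stats::coef(stats::lm(vols ~ days))[2]
  expect_equal(unname(slope), rate, tolerance = 0.05)
  # soil identical across steps: compare a far-corner region
  a1 <- volData(ser[[1]]$volume)[1:10, 1:10, 1:10]
  a8 <- volData(ser[[8]]$volume)[1:10, 1:10, 1:10]
  expect_equal(a1, a8)
})
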