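respVol <- function(arr, branch, scales = c(1, 3)) {
  new("ResponseVolume", data = arr, voxelSizeUm = 500, branch = branch,
      scales = scales)
}

test_that("merge thresholds select exactly the right voxels", {
  d <- c(20, 20, 20)
  set.seed(5)
  win <- GrayVolume(array(runif(prod(d), 0.11, 0.24), d), 500)
  vess <- respVol(array(runif(prod(d), 0, 1000), d), "vesselness")
  varr <- respVol(array(runif(prod(d), 0, 5000), d), "variance")

  # theta1 = Inf-like, theta2 -> variance <= 0 impossible: empty mask
  m0 <- mergeResponses(vess, varr, win, 1e12, 1e-12,
                       thicknessTest = FALSE)
  expect_equal(sum(volData(m0)), 0)

  # membership oracle with the bean small-pot thresholds
  m <- mergeResponses(vess, varr, win, 400, 2500, thicknessTest = FALSE)
  want <- (volData(vess) >= 400) |
    (volData(win) != 0 & volData(varr) <= 2500)
  expect_identical(volData(m), want)

  bad <- GrayVolume(array(0.2, c(5, 5, 5)), 500)
  expect_error(mergeResponses(vess, varr, bad, 400, 2500), "geometry")
})

test_that("thin tubes pass the vesselness branch, thick homogeneous
           cylinders the variance branch, and the union holds both", {
  d <- c(30, 60, 60)
  thin <- paintSegments(d, list(list(c(3, 15, 15), c(28, 15, 15))), 2)
  thick <- solidCylinder(d, center = c(42, 42), radius = 20, from = 3,
                         to = 28)
  win <- GrayVolume(array(0.15, d) * (thin | thick), 500)
  vessArr <- array(0, d); vessArr[thin] <- 900       # only the tube fires
  varArr <- array(5000, d); varArr[thick] <- 10      # only the cylinder calm
  vess <- respVol(vessArr, "vesselness", scales = c(1, 2.5))
  varr <- respVol(varArr, "variance", 3)
  m <- mergeResponses(vess, varr, win, 500, 100, maxDiameterVox = 5)
  expect_true(all(volData(m)[thin]))
  expect_true(all(volData(m)[thick]))
  # the thin tube does not get in through the variance branch
  mVar <- mergeResponses(vess, varr, win, 1e12, 5000, maxDiameterVox = 5)
  expect_false(any(volData(mVar)[thin]))
  expect_true(all(volData(mVar)[thick]))
})

test_that("merge is monotone in both thresholds", {
  set.seed(6)
  d <- c(16, 16, 16)
  win <- GrayVolume(array(runif(prod(d), 0.11, 0.24), d), 500)
  vess <- respVol(array(runif(prod(d), 0, 1000), d), "vesselness")
  varr <- respVol(array(runif(prod(d), 0, 5000), d), "variance")
  base <- sum(volData(mergeResponses(vess, varr, win, 300, 2000,
                                     thicknessTest = FALSE)))
  up1 <- sum(volData(mergeResponses(vess, varr, win, 600, 2000,
                                    thicknessTest = FALSE)))
  dn2 <- sum(volData(mergeResponses(vess, varr, win, 300, 500,
                                    thicknessTest = FALSE)))
  expect_lte(up1, base)
  expect_lte(dn2, base)
})

test_that("binary median filter matches a brute-force majority vote", {
  m1 <- RootMask(array(c(TRUE, rep(FALSE, 124)), c(5, 5, 5)), 500)
  expect_identical(volData(medianFilterMask(m1, 1)), volData(m1))
  # isolated voxel removed by kernel 3
  expect_equal(sum(volData(medianFilterMask(m1, 3))), 0)
  expect_error(medianFilterMask(m1, 2), "odd")

  set.seed(8)
  d <- c(32, 32, 32)
  arr <- array(runif(prod(d)) < 0.4, d)
  got <- volData(medianFilterMask(RootMask(arr, 500), 3))
  pad <- array(FALSE, d + 2)
  pad[2:33, 2:33, 2:33] <- arr
  ora <- array(FALSE, d)
  for (i in 1:32) for (j in 1:32) for (k in 1:32)
    ora[i, j, k] <- sum(pad[i:(i + 2), j:(j + 2), k:(k + 2)]) > 13
  expect_identical(got, ora)

  # solid ball: kernel 3 changes at most a surface shell
  ball <- array(FALSE, c(13, 13, 13))
  for (i in 1:13) for (j in 1:13) for (k in 1:13)
    if ((i - 7)^2 + (j - 7)^2 + (k - 7)^2 <= 25) ball[i, j, k] <- TRUE
  got2 <- volData(medianFilterMask(RootMask(ball, 500), 3))
  expect_lte(sum(xor(got2, ball)), 4 * pi * 5^2)  # one surface shell
})

test_that("size filter removes components below V_min exactly", {
  d <- c(30, 30, 30)
  arr <- array(FALSE, d)
  arr[2:6, 2:4, 2:4] <- TRUE          # 45 voxels
  arr[15:29, 10:29, 10:29] <- TRUE    # 6000 voxels
  m <- RootMask(arr, 100)             # 0.001 mm^3 per voxel

  expect_identical(volData(sizeFilter(m, 0)), arr)   # V_min = 0: identity

  # 50-ish voxel component = 0.045 mm^3, big = 6 mm^3; V_min = 1
  f <- sizeFilter(m, 1)
  expect_false(any(volData(f)[2:6, 2:4, 2:4]))
  expect_true(all(volData(f)[15:29, 10:29, 10:29]))

  # cassava preset: 5 mm^3 at 175 um -> components under ~933 voxels drop
  expect_equal(ceiling(5 / 0.175^3), 933)  # components under 933 voxels
  d2 <- c(25, 50, 30)
  arr2 <- array(FALSE, d2)
  arr2[1:20, 1:15, 1:3] <- TRUE        # 900 voxels < 933
  arr2[1:21, 20:35, 10:12] <- TRUE     # 1008 voxels > 933
  f2 <- sizeFilter(RootMask(arr2, 175), 5)
  expect_false(any(volData(f2)[1:20, 1:15, 1:3]))
  expect_true(all(volData(f2)[1:21, 20:35, 10:12]))

  # every surviving component is >= V_min
  set.seed(10)
  noise <- RootMask(array(runif(20^3) < 0.2, c(20, 20, 20)), 400)
  fs <- sizeFilter(noise, 0.5)
  lab <- array(rootCT:::cpp_label3d(as.vector(volData(fs)), dim(volData(fs)),
                                    26L), dim(volData(fs)))
  if (any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    sizes <- sizes[sizes > 0]
    expect_true(all(sizes * 0.4^3 >= 0.5))
  }
})

test_that("segmentation is deterministic: same volume and P, same mask", {
  spec <- phantomSpec(seed = 41L, potDepthMm = 18, branchingDepth = 1L)
  ph <- rasterizePhantom(generateRootTree(spec), spec)
  params <- presetParameters("phantom")
  s1 <- segmentVolume(ph$volume, params, potWallRange = c(0.3, 0.7))
  s2 <- segmentVolume(ph$volume, params, potWallRange = c(0.3, 0.7))
  expect_identical(rlang::hash(volData(s1$mask)),
                   rlang::hash(volData(s2$mask)))
  expect_identical(s1$mask@provenance, parameterHash(params))
})

test_that("parameter sets round-trip through YAML with published names", {
  p <- presetParameters("cassava")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeParameterSet(p, f)
  cfg <- yaml::read_yaml(f)
  expect_equal(cfg$attenuation_range, c(0.08, 0.2))
  expect_equal(cfg$D_root, c(1, 1.5, 2, 3))
  expect_equal(cfg$theta1, 60)
  expect_equal(cfg$theta2, 65000)
  expect_equal(cfg$V_min, 5)
  back <- readParameterSet(f)
  expect_equal(parameterHash(back), parameterHash(p))
})
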