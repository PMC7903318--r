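# The Hessian/vesselness branch and the local-variance branch are checked
# against independent oracles built from plain R indexing (refConv1) and
# dense eigensolvers.

test_that("Hessian eigenvalues match a finite-difference + eigen() oracle", {
  set.seed(42)
  n <- 21
  vol <- refConv1(refConv1(refConv1(array(rnorm(n^3), c(n, n, n)),
                                    refGaussKernel(2), 1),
                           refGaussKernel(2), 2), refGaussKernel(2), 3)
  sigma <- 1.5
  he <- hessianEigenvalues(vol, sigma)

  # oracle: same mathematical definition, independent machinery
  k <- refGaussKernel(sigma)
  s <- refConv1(refConv1(refConv1(vol, k, 1), k, 2), k, 3)
  sh <- function(a, axis, off) {
    L <- dim(a)[axis]
    src <- seq_len(L) + off
    src <- ifelse(src < 1, 1 - src, src)
    src <- ifelse(src > L, 2 * L + 1 - src, src)
    switch(axis, a[src, , , drop = FALSE], a[, src, , drop = FALSE],
           a[, , src, drop = FALSE])
  }
  g <- sigma^2
  hxx <- g * (sh(s, 1, 1) - 2 * s + sh(s, 1, -1))
  hyy <- g * (sh(s, 2, 1) - 2 * s + sh(s, 2, -1))
  hzz <- g * (sh(s, 3, 1) - 2 * s + sh(s, 3, -1))
  hxy <- g * (sh(sh(s, 1, 1), 2, 1) - sh(sh(s, 1, 1), 2, -1) -
                sh(sh(s, 1, -1), 2, 1) + sh(sh(s, 1, -1), 2, -1)) / 4
  hxz <- g * (sh(sh(s, 1, 1), 3, 1) - sh(sh(s, 1, 1), 3, -1) -
                sh(sh(s, 1, -1), 3, 1) + sh(sh(s, 1, -1), 3, -1)) / 4
  hyz <- g * (sh(sh(s, 2, 1), 3, 1) - sh(sh(s, 2, 1), 3, -1) -
                sh(sh(s, 2, -1), 3, 1) + sh(sh(s, 2, -1), 3, -1)) / 4
  ev <- matrix(0, n^3, 3)
  for (v in seq_len(n^3)) {
    H <- matrix(c(hxx[v], hxy[v], hxz[v],
                  hxy[v], hyy[v], hyz[v],
                  hxz[v], hyz[v], hzz[v]), 3, 3)
    e <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    ev[v, ] <- e[order(abs(e))]
  }
  mine <- cbind(as.vector(he@lambda1), as.vector(he@lambda2),
                as.vector(he@lambda3))
  expect_lt(max(abs(mine - ev)) / max(abs(ev)), 1e-6)
})

test_that("constant volumes give zero Hessian, vesselness and variance", {
  v <- GrayVolume(array(5, c(11, 11, 11)), 100)
  he <- hessianEigenvalues(v, 1.2)
  expect_equal(max(abs(he@lambda3)), 0)
  r <- frangiVesselness(v, c(2, 4), polarity = "bright")
  expect_equal(max(volData(r)), 0)
  lv <- localVariance(v, 2)
  expect_equal(max(volData(lv)), 0)
})

test_that("a bright Gaussian tube satisfies the tube eigenvalue condition", {
  v <- gaussianTube(n = 41, a = 2)
  he <- hessianEigenvalues(v, 2)
  mid <- 21
  l1 <- he@lambda1[mid, mid, mid]
  l2 <- he@lambda2[mid, mid, mid]
  l3 <- he@lambda3[mid, mid, mid]
  expect_lt(abs(l1), 0.05 * abs(l3))  # lambda1 ~ 0
  expect_lt(l2, 0)                    # strongly negative pair
  expect_lt(l3, 0)
  expect_equal(l2, l3, tolerance = 1e-6)
})

test_that("vesselness argmax over the shipped scale list is sigma = D/2", {
  scales <- c(2, 2.5, 3, 3.5, 4, 5, 6)  # diameter list
  mid <- 21
  for (D in c(2, 4, 6)) {
    v <- gaussianTube(n = 41, a = D / 2)
    resp <- vapply(scales, function(s)
      volData(frangiVesselness(v, s, c = 0.05,
                               polarity = "bright"))[mid, mid, mid], 1.0)
    expect_equal(scales[which.max(resp)], D)
  }
})

test_that("a blob is suppressed relative to a tube of equal peak", {
  mid <- 21
  tube <- frangiVesselness(gaussianTube(n = 41, a = 2), 4,
                           polarity = "bright")
  blob <- frangiVesselness(gaussianBlob(n = 41, a = 2), 4,
                           polarity = "bright")
  expect_gt(volData(tube)[mid, mid, mid],
            3 * volData(blob)[mid, mid, mid])
})

test_that("vesselness is shift-invariant and zero on background voxels", {
  v <- gaussianTube(n = 31, a = 2)
  r1 <- frangiVesselness(v, 4, c = 0.05, polarity = "bright")
  shifted <- GrayVolume(volData(v) + 3, voxelSize(v))
  r2 <- frangiVesselness(shifted, 4, c = 0.05, polarity = "bright")
  expect_equal(volData(r1), volData(r2), tolerance = 1e-8)

  # translation invariance along the tube axis, away from borders
  mid <- 16
  axisResp <- volData(r1)[8:24, mid, mid]
  expect_lt(diff(range(axisResp)) / max(axisResp), 0.02)

  # background sentinel
  w <- volData(v)
  w[, 1:3, ] <- 0
  rz <- frangiVesselness(GrayVolume(w, 100), 4, polarity = "bright")
  expect_true(all(volData(rz)[, 1:3, ] == 0))
  expect_error(frangiVesselness(v, numeric(0)), "non-empty")
})

test_that("local variance equals the explicit Gaussian-weighted variance", {
  set.seed(7)
  n <- 15
  arr <- array(runif(n^3), c(n, n, n))
  lam <- 2
  lv <- localVariance(GrayVolume(arr, 100), lam)
  k <- refGaussKernel(lam)
  r <- (length(k) - 1) / 2
  refl <- function(i, L) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > L, 2 * L + 1 - i, i)
  }
  w3 <- outer(outer(k, k), k)
  ora <- array(0, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) for (kk in seq_len(n)) {
    block <- arr[refl(i + (-r:r), n), refl(j + (-r:r), n),
                 refl(kk + (-r:r), n)]
    m <- sum(w3 * block)
    ora[i, j, kk] <- sum(w3 * block^2) - m^2
  }
  expect_lt(max(abs(volData(lv) - ora)) / max(ora), 1e-6)
})

test_that("local variance of white noise approaches the noise variance", {
  set.seed(11)
  s <- 0.7
  big <- array(rnorm(40^3, 5, s), c(40, 40, 40))
  lv <- localVariance(GrayVolume(big, 100), 4)
  inner <- volData(lv)[10:30, 10:30, 10:30]
  expect_equal(mean(inner), s^2, tolerance = 0.05)
  # clipped at zero, zero on background
  big[1:3, , ] <- 0
  lv2 <- localVariance(GrayVolume(big, 100), 4)
  expect_true(all(volData(lv2) >= 0))
  expect_true(all(volData(lv2)[1:3, , ] == 0))
  expect_error(localVariance(GrayVolume(big, 100), 0), "lambdaScale")
})
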