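# Shared fixture builders: analytic volumes with known geometry, built in
# code at test time.

# Gaussian tube along axis 1: I = exp(-(dy^2 + dz^2) / (2 a^2)), a = D/2
gaussianTube <- function(n = 41, a = 2, voxel = 100) {
  c0 <- (n + 1) / 2
  g <- array(0, c(n, n, n))
  for (j in seq_len(n))
    g[, j, ] <- matrix(exp(-((j - c0)^2 + (seq_len(n) - c0)^2) / (2 * a^2)),
                       1, n, byrow = TRUE)[rep(1, n), ]
  GrayVolume(g, voxel)
}

# isotropic Gaussian blob of the same peak height
gaussianBlob <- function(n = 41, a = 2, voxel = 100) {
  c0 <- (n + 1) / 2
  g <- array(0, c(n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n))
    g[i, j, ] <- exp(-((i - c0)^2 + (j - c0)^2 +
                         (seq_len(n) - c0)^2) / (2 * a^2))
  GrayVolume(g, voxel)
}

# solid tube segments (union of spheres along straight segments)
paintSegments <- function(dims, segments, radius) {
  arr <- array(FALSE, dims)
  for (s in segments) {
    p0 <- s[[1]]; p1 <- s[[2]]
    len <- sqrt(sum((p1 - p0)^2))
    for (t in seq(0, 1, length.out = max(2, ceiling(len * 4)))) {
      ctr <- p0 + t * (p1 - p0)
      lo <- pmax(1, floor(ctr - radius - 1))
      hi <- pmin(dims, ceiling(ctr + radius + 1))
      for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3])
        if ((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= radius^2)
          arr[i, j, k] <- TRUE
    }
  }
  arr
}

# solid cylinder along axis 1
solidCylinder <- function(dims, center = c(dims[2], dims[3]) / 2, radius,
                          from, to) {
  arr <- array(FALSE, dims)
  jj <- matrix(seq_len(dims[2]), dims[2], dims[3])
  kk <- matrix(seq_len(dims[3]), dims[2], dims[3], byrow = TRUE)
  disc <- (jj - center[1])^2 + (kk - center[2])^2 <= radius^2
  for (i in from:to) arr[i, , ] <- disc
  arr
}

# annulus (pot wall) volume: wall value inside [rIn, rOut], soil inside
annulusVolume <- function(n = 64, nz = 8, rInVox, wallVox = 5,
                          wallValue = 0.5, soilValue = 0.18, voxel = 1000,
                          centerOff = c(0, 0)) {
  arr <- array(0.02, c(nz, n, n))
  c0 <- (n + 1) / 2
  jj <- matrix(seq_len(n), n, n)
  kk <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((jj - c0 - centerOff[1])^2 + (kk - c0 - centerOff[2])^2)
  sl <- matrix(0.02, n, n)
  sl[r < rInVox + wallVox] <- wallValue
  sl[r < rInVox] <- soilValue
  for (z in seq_len(nz)) arr[z, , ] <- sl
  GrayVolume(arr, voxel)
}

# dense 1-voxel-wide polyline rasterization (voxel chain between nodes)
paintChain <- function(dims, pts) {
  arr <- array(FALSE, dims)
  for (r in seq_len(nrow(pts) - 1)) {
    p0 <- pts[r, ]; p1 <- pts[r + 1, ]
    nst <- max(2, 2 * max(abs(p1 - p0)) + 1)
    for (t in seq(0, 1, length.out = nst)) {
      v <- round(p0 + t * (p1 - p0))
      arr[v[1], v[2], v[3]] <- TRUE
    }
  }
  arr
}

# reference separable convolution with half-sample symmetric reflection,
# independent of the package machinery (pure R indexing)
refConv1 <- function(a, k, axis) {
  d <- dim(a)
  half <- (length(k) - 1) / 2
  L <- d[axis]
  res <- array(0, d)
  for (t in seq_along(k)) {
    off <- t - half - 1
    src <- seq_len(L) + off
    src <- ifelse(src < 1, 1 - src, src)
    src <- ifelse(src > L, 2 * L + 1 - src, src)
    res <- res + k[t] * switch(axis, a[src, , , drop = FALSE],
                               a[, src, , drop = FALSE],
                               a[, , src, drop = FALSE])
  }
  res
}

refGaussKernel <- function(s) {
  r <- ceiling(4 * s)
  x <- -r:r
  g <- exp(-x^2 / (2 * s^2))
  g / sum(g)
}

smallPhantomSpec <- function(seed, ...) phantomSpec(seed = seed, ...)
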