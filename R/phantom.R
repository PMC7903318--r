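#' Construct a PhantomSpec
#'
#' Defaults describe a bean-like small pot (inner diameter 34 mm) scanned at
#' 400 um cubic voxels, with roots at attenuation 0.15 embedded in textured
#' soil at mean 0.18 so the shipped bean attenuation window (0.11, 0.24)
#' applies unchanged. Storage roots are off by default; enable them for
#' cassava-like phantoms.
#'
#' @param potInnerDiameterMm,wallThicknessMm,potDepthMm,headspaceMm pot
#'   geometry (soil depth below the flat surface; air headspace above).
#' @param voxelSizeUm cubic voxel size.
#' @param soilMean,soilSd,soilCorrelationVox soil attenuation texture.
#' @param stoneDensity expected stones/pores per 1000 mm^3 of soil.
#' @param rootAttenuation,wallAttenuation material attenuations.
#' @param branchingDepth,branchProbability,insertionAngleRangeDeg,
#'   diameterStartVox,diameterEndVox,tortuosity,segmentLengthMm fine-root
#'   tree statistics.
#' @param nStorageRoots,storageDiameterVox storage-root capsules.
#' @param noiseSd,blurSigmaVox image degradation.
#' @param seed integer seed fixing all randomness.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(potInnerDiameterMm = 34, wallThicknessMm = 2,
                        potDepthMm = 32, headspaceMm = 4,
                        voxelSizeUm = 400, soilMean = 0.18, soilSd = 0.004,
                        soilCorrelationVox = 4, stoneDensity = 0.2,
                        noiseSd = 0.006, blurSigmaVox = 0.6,
                        rootAttenuation = 0.15, wallAttenuation = 0.5,
                        branchingDepth = 3L, branchProbability = 0.8,
                        insertionAngleRangeDeg = c(25, 60),
                        diameterStartVox = 5, diameterEndVox = 3,
                        tortuosity = 0.05, segmentLengthMm = 8,
                        nStorageRoots = 0L, storageDiameterVox = 45,
                        seed = 1L) {
  new("PhantomSpec", potInnerDiameterMm = potInnerDiameterMm,
      wallThicknessMm = wallThicknessMm, potDepthMm = potDepthMm,
      headspaceMm = headspaceMm, voxelSizeUm = voxelSizeUm,
      soilMean = soilMean, soilSd = soilSd,
      soilCorrelationVox = soilCorrelationVox, stoneDensity = stoneDensity,
      rootAttenuation = rootAttenuation, wallAttenuation = wallAttenuation,
      branchingDepth = as.integer(branchingDepth),
      branchProbability = branchProbability,
      insertionAngleRangeDeg = insertionAngleRangeDeg,
      diameterStartVox = diameterStartVox, diameterEndVox = diameterEndVox,
      tortuosity = tortuosity, segmentLengthMm = segmentLengthMm,
      nStorageRoots = as.integer(nStorageRoots),
      storageDiameterVox = storageDiameterVox, noiseSd = noiseSd,
      blurSigmaVox = blurSigmaVox, seed = as.integer(seed))
}

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

phantomDims <- function(spec) {
  vmm <- spec@voxelSizeUm / 1000
  wide <- spec@potInnerDiameterMm + 2 * spec@wallThicknessMm + 3
  c(ceiling((spec@headspaceMm + spec@potDepthMm) / vmm),
    ceiling(wide / vmm), ceiling(wide / vmm))
}

unitv <- function(v) v / sqrt(sum(v^2))

#' Generate a random root-system centerline tree
#'
#' Recursive branching polylines growing downward from the entry point at
#' the soil surface. At the end of each segment a branch either splits into
#' two laterals (probability \code{branchProbability}, insertion angles
#' drawn from \code{insertionAngleRangeDeg}) or continues; after
#' \code{branchingDepth} splitting opportunities every path terminates in a
#' tip. Diameters taper linearly with tree level. All points stay inside
#' the retained pot cylinder; growth that cannot stay inside stops at the
#' wall margin.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed seed (default \code{spec@seed}).
#' @return an object of class \code{RootTree}: branch polylines in mm
#'   (depth, y, x), per-point diameters (voxels), parentage, tips, storage
#'   flags.
#' @export
generateRootTree <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  vmm <- spec@voxelSizeUm / 1000
  dims <- phantomDims(spec)
  center <- c(dims[2], dims[3]) / 2 * vmm
  z0 <- spec@headspaceMm
  rIn <- spec@potInnerDiameterMm / 2
  maxLevel <- spec@branchingDepth
  dMaxMm <- spec@diameterStartVox * vmm
  if (rIn - dMaxMm / 2 - 1 <= 0)
    stop("spec forces roots outside the pot: pot too small for the ",
         "root diameter")

  withSeed(seed, {
    stepMm <- max(vmm, 0.4)
    branches <- list()
    # occupied space of already-grown branches, for collision avoidance:
    # independent roots must never fuse, or the ground-truth tip count
    # would not be the topological tip count of the rasterized mask
    cloudPts <- matrix(0, 0, 3)
    cloudRad <- numeric(0)       # tube radius in mm
    cloudStorage <- logical(0)   # rows belonging to storage capsules
    collides <- function(p, radMm, ignoreNear, ignoreStorage = FALSE) {
      if (nrow(cloudPts) == 0) return(FALSE)
      d2 <- (cloudPts[, 1] - p[1])^2 + (cloudPts[, 2] - p[2])^2 +
        (cloudPts[, 3] - p[3])^2
      # surface separation must exceed the segmentation's boundary
      # uncertainty (~1 voxel each side) for truth tips to stay
      # topologically recoverable from a detected mask
      sep <- (cloudRad + radMm + 4.5 * vmm)^2
      near <- (cloudPts[, 1] - ignoreNear[1])^2 +
        (cloudPts[, 2] - ignoreNear[2])^2 +
        (cloudPts[, 3] - ignoreNear[3])^2 < (4 * radMm + 2)^2
      if (ignoreStorage) near <- near | cloudStorage
      any(d2 < sep & !near)
    }
    grow <- function(pt, dir, level, parent, startLevel) {
      poly <- matrix(pt, 1, 3)
      dia <- diaAtLevel(spec, startLevel)
      lev <- level
      start0 <- pt
      alive <- TRUE
      repeat {
        nSteps <- max(3L, round(spec@segmentLengthMm / stepMm))
        for (s in seq_len(nSteps)) {
          perp <- stats::rnorm(3) * spec@tortuosity
          dir <- unitv(dir + perp + c(0.06, 0, 0))  # gravitropic bias
          nxt <- pt + dir * stepMm
          rad <- sqrt(sum((nxt[2:3] - center)^2))
          # stay clear of the soil margin the pipeline strips with the pot
          # (2x wall thickness), or ground truth would contain root the
          # segmentation is never shown
          margin <- rIn - diaAtLevel(spec, lev + 1) * vmm / 2 -
            2 * spec@wallThicknessMm - 1
          if (rad > margin) {  # reflect horizontal component inward
            rhat <- unitv(nxt[2:3] - center)
            dh <- dir[2:3] - 2 * sum(dir[2:3] * rhat) * rhat
            dir <- unitv(c(max(dir[1], 0.2), dh))
            nxt <- pt + dir * stepMm
          }
          if (nxt[1] > z0 + spec@potDepthMm - 1) { alive <- FALSE; break }
          rMm <- diaInterp(spec, lev, s / nSteps) * vmm / 2
          # the stem passes between/through the storage capsules that
          # attach to it, so it does not collide with them
          isStem <- is.na(parent)
          if (collides(nxt, rMm, start0, ignoreStorage = isStem)) {
            deflected <- FALSE
            for (try in 1:4) {  # steer away, steeper downward
              cand <- unitv(dir + c(0.5 * try, 0, 0) +
                              stats::rnorm(3) * 0.2)
              nxt2 <- pt + cand * stepMm
              if (nxt2[1] > z0 + spec@potDepthMm - 1) break
              if (!collides(nxt2, rMm, start0, ignoreStorage = isStem)) {
                dir <- cand; nxt <- nxt2; deflected <- TRUE; break
              }
            }
            if (!deflected) { alive <- FALSE; break }  # stop: becomes a tip
          }
          pt <- nxt
          poly <- rbind(poly, pt)
          dia <- c(dia, diaInterp(spec, lev, s / nSteps))
        }
        lev <- lev + 1
        if (!alive || lev > maxLevel ||
            stats::runif(1) < spec@branchProbability) break
      }
      # collision-stopped stubs shorter than half a segment are discarded:
      # they would be indistinguishable from skeleton spurs
      if (!is.na(parent) &&
          nrow(poly) < ceiling(0.75 * spec@segmentLengthMm / stepMm))
        return(FALSE)
      idx <- length(branches) + 1
      branches[[idx]] <<- list(points = poly, diameterVox = dia,
                               parent = parent, level = startLevel,
                               isTip = TRUE, storage = FALSE)
      cloudPts <<- rbind(cloudPts, poly)
      cloudRad <<- c(cloudRad, dia * vmm / 2)
      cloudStorage <<- c(cloudStorage, rep(FALSE, nrow(poly)))
      if (alive && lev <= maxLevel) {
        # siblings leave on opposite azimuths so their tubes diverge
        az0 <- stats::runif(1, 0, 2 * pi)
        survived <- FALSE
        for (child in 1:2) {
          ang <- stats::runif(1, spec@insertionAngleRangeDeg[1],
                              spec@insertionAngleRangeDeg[2]) * pi / 180
          az <- az0 + (child - 1) * pi + stats::rnorm(1, 0, 0.3)
          cd <- branchDirection(dir, ang, az)
          survived <- grow(pt, cd, lev, idx, lev) || survived
        }
        if (survived) branches[[idx]]$isTip <<- FALSE
      }
      TRUE
    }
    entry <- c(z0, center[1], center[2])

    if (spec@nStorageRoots > 0) {
      radMm <- spec@storageDiameterVox * vmm / 2
      len <- min(spec@potDepthMm * 0.55,
                 (rIn - radMm - 2 * spec@wallThicknessMm - 1) /
                   sin(pi / 5))
      if (len <= radMm)
        stop("spec forces roots outside the pot: storage roots too ",
             "thick for the pot")
      for (s in seq_len(spec@nStorageRoots)) {
        az <- 2 * pi * (s - 1) / spec@nStorageRoots + stats::runif(1, 0, 0.5)
        polar <- pi / 5  # ~36 deg from vertical
        dir <- unitv(c(cos(polar), sin(polar) * sin(az),
                       sin(polar) * cos(az)))
        start <- entry + c(radMm * 0.8 + 0.5, 0, 0)
        npts <- 24
        ts <- seq(0, 1, length.out = npts)
        pts <- t(vapply(ts, function(tt) start + dir * (len * tt),
                        numeric(3)))
        branches[[length(branches) + 1]] <-
          list(points = pts,
               diameterVox = rep(spec@storageDiameterVox, npts),
               parent = NA_integer_, level = 0L, isTip = TRUE,
               storage = TRUE)
        # fine roots steer clear with headroom for radial bulking, so a
        # growth series does not swallow fine-root volume
        cloudPts <- rbind(cloudPts, pts)
        cloudRad <- c(cloudRad, rep(radMm * 1.6, npts))
        cloudStorage <- c(cloudStorage, rep(TRUE, npts))
      }
    }
    grow(entry, c(1, 0, 0), 0L, NA_integer_, 0L)
    structure(list(branches = branches, entryMm = entry,
                   surfaceMm = z0, centerMm = center, dims = dims,
                   voxelSizeUm = spec@voxelSizeUm),
              class = "RootTree")
  })
}

diaAtLevel <- function(spec, level) {
  f <- min(1, level / (spec@branchingDepth + 1))
  spec@diameterStartVox + (spec@diameterEndVox - spec@diameterStartVox) * f
}

diaInterp <- function(spec, level, frac) {
  a <- diaAtLevel(spec, level)
  b <- diaAtLevel(spec, level + 1)
  a + (b - a) * frac
}

# rotate dir by angle ang toward a perpendicular direction chosen by azimuth
branchDirection <- function(dir, ang, az) {
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitv(cross3(dir, ref))
  v <- cross3(dir, u)
  unitv(dir * cos(ang) + (u * cos(az) + v * sin(az)) * sin(ang))
}

#' Rasterize a root tree into a synthetic CT volume with ground truth
#'
#' Roots are painted as tubes with per-point diameter (smooth half-voxel
#' edge profile standing in for partial-volume coverage), soil as a
#' correlated Gaussian random field, stones and pores as random ellipsoids
#' outside the attenuation window, and the pot as a dense annulus. A global
#' Gaussian blur and additive noise degrade the image after the truth mask
#' is recorded.
#'
#' @param tree a \code{RootTree} from \code{\link{generateRootTree}}.
#' @param spec the \linkS4class{PhantomSpec}.
#' @return list with \code{volume} (a \linkS4class{GrayVolume}) and
#'   \code{truth} (a \linkS4class{PhantomTruth}).
#' @export
rasterizePhantom <- function(tree, spec) {
  stopifnot(inherits(tree, "RootTree"), is(spec, "PhantomSpec"))
  dims <- tree$dims
  vmm <- spec@voxelSizeUm / 1000
  n <- prod(dims)
  withSeed(spec@seed + 1000L, {
    # soil: correlated Gaussian random field
    fld <- array(stats::rnorm(n), dims)
    if (spec@soilCorrelationVox > 0) {
      fld <- gaussianFilter3d(fld, spec@soilCorrelationVox)
      fld <- fld / stats::sd(fld)
    }
    soil <- spec@soilMean + spec@soilSd * fld

    # region geometry
    center <- tree$centerMm
    jg <- matrix(seq_len(dims[2]) - 0.5, dims[2], dims[3]) * vmm
    kg <- matrix(seq_len(dims[3]) - 0.5, dims[2], dims[3],
                 byrow = TRUE) * vmm
    rGrid <- sqrt((jg - center[1])^2 + (kg - center[2])^2)
    rIn <- spec@potInnerDiameterMm / 2
    surfSlice <- floor(spec@headspaceMm / vmm) + 1
    air <- 0.02
    inPot <- rGrid < rIn
    inWall <- rGrid >= rIn & rGrid < rIn + spec@wallThicknessMm
    vol <- array(air, dims)
    for (z in seq_len(dims[1])) {
      sl <- matrix(air, dims[2], dims[3])
      if (z >= surfSlice) sl[inPot] <- soil[z, , ][inPot]
      sl[inWall] <- spec@wallAttenuation
      vol[z, , ] <- sl
    }

    # stones and pores (ellipsoids outside the attenuation window)
    soilVol <- pi * rIn^2 * spec@potDepthMm
    nStones <- stats::rpois(1, spec@stoneDensity * soilVol / 1000)
    rootPts <- do.call(rbind, lapply(tree$branches, `[[`, "points"))
    rootRadMm <- unlist(lapply(tree$branches, `[[`, "diameterVox")) *
      vmm / 2
    for (s in seq_len(nStones)) {
      az <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * (rIn - 2)
      cMm <- c(stats::runif(1, spec@headspaceMm + 2,
                            spec@headspaceMm + spec@potDepthMm - 2),
               center[1] + rr * sin(az), center[2] + rr * cos(az))
      semi <- stats::runif(3, 0.5, 2)  # voxels
      val <- if (stats::runif(1) < 0.5) 0.45 else 0.03
      # stones and pores keep clear of the root system so their rim
      # artifacts stay disconnected from the tree (removable by V_min);
      # all random draws happen before this check so the RNG stream -- and
      # with it the soil of a growth series -- does not depend on the tree
      d2r <- (rootPts[, 1] - cMm[1])^2 + (rootPts[, 2] - cMm[2])^2 +
        (rootPts[, 3] - cMm[3])^2
      if (any(d2r < (rootRadMm + 4 * vmm)^2)) next
      cV <- cMm / vmm + 0.5
      lo <- pmax(1, floor(cV - semi - 1)); hi <- pmin(dims, ceiling(cV + semi + 1))
      for (z in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (x in lo[3]:hi[3]) {
        q <- ((z - cV[1]) / semi[1])^2 + ((y - cV[2]) / semi[2])^2 +
          ((x - cV[3]) / semi[3])^2
        if (q <= 1 && z >= surfSlice && rGrid[y, x] < rIn - 0.5)
          vol[z, y, x] <- val
      }
    }

    # roots: coverage via dense sphere chains
    cov <- numeric(n)
    lengthMm <- 0
    for (b in tree$branches) {
      rs <- resamplePolyline(b$points, b$diameterVox, 0.5 * vmm)
      lengthMm <- lengthMm + rs$length
      ptsVox <- rs$points / vmm + 0.5 - 1  # 0-based voxel coords
      cov <- cpp_paint_tube(cov, dims, ptsVox, rs$diameter / 2)
    }
    covArr <- array(cov, dims)
    mask <- covArr >= 0.5
    vol <- vol * (1 - covArr) + spec@rootAttenuation * covArr

    if (spec@blurSigmaVox > 0) vol <- gaussianFilter3d(vol, spec@blurSigmaVox)
    if (spec@noiseSd > 0) vol <- vol + array(stats::rnorm(n, 0, spec@noiseSd),
                                             dims)

    nTips <- sum(vapply(tree$branches, `[[`, TRUE, "isTip"))
    truth <- new("PhantomTruth",
                 mask = RootMask(mask, spec@voxelSizeUm),
                 polylines = lapply(tree$branches, function(b) {
                   p <- b$points
                   attr(p, "diameterVox") <- b$diameterVox
                   p
                 }),
                 vRootMm3 = sum(mask) * vmm^3,
                 lengthMm = as.numeric(lengthMm),
                 nTips = as.integer(nTips),
                 entryPoint = tree$entryMm / vmm + 0.5,
                 surfaceSlice = surfSlice)
    list(volume = GrayVolume(vol, spec@voxelSizeUm), truth = truth)
  })
}

# resample a polyline to ~even spacing; returns points (mm), per-point
# diameters (voxels) and the arc length
resamplePolyline <- function(points, diameters, spacingMm) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0)
    return(list(points = points[1, , drop = FALSE],
                diameter = diameters[1], length = 0))
  ts <- seq(0, total, by = spacingMm)
  if (ts[length(ts)] < total) ts <- c(ts, total)
  out <- vapply(1:3, function(d) stats::approx(s, points[, d], ts)$y,
                numeric(length(ts)))
  dia <- stats::approx(s, diameters, ts)$y
  list(points = matrix(out, ncol = 3), diameter = dia, length = total)
}

# analytic tube volume of a (resampled) branch prefix
analyticTreeVolume <- function(tree, vmm, fineFraction = 1,
                               storageRadiusMm = NULL) {
  tot <- 0
  for (b in tree$branches) {
    rs <- resamplePolyline(b$points, b$diameterVox, 0.25)
    if (b$storage) {
      r <- if (is.null(storageRadiusMm)) rs$diameter[1] * vmm / 2 else
        storageRadiusMm
      tot <- tot + pi * r^2 * rs$length + 4 / 3 * pi * r^3
    } else {
      L <- rs$length * fineFraction
      keep <- seq_len(max(2, ceiling(nrow(rs$points) * fineFraction)))
      rMm <- rs$diameter[keep] * vmm / 2
      step <- rs$length / (nrow(rs$points) - 1)
      tot <- tot + sum(pi * rMm^2) * step
    }
  }
  tot
}

# tree with fine roots truncated to a prefix fraction and storage roots at
# a given radius
scaleTree <- function(tree, fineFraction, storageRadiusMm, vmm) {
  tree$branches <- lapply(tree$branches, function(b) {
    if (b$storage) {
      if (!is.null(storageRadiusMm))
        b$diameterVox <- rep(2 * storageRadiusMm / vmm,
                             length(b$diameterVox))
      return(b)
    }
    npt <- nrow(b$points)
    keep <- min(npt, max(2, ceiling(npt * fineFraction)))
    b$points <- b$points[seq_len(keep), , drop = FALSE]
    b$diameterVox <- b$diameterVox[seq_len(keep)]
    b
  })
  tree
}

#' Generate a monotone-growing phantom time series
#'
#' Emulates a storage-root bulking experiment: fine roots elongate and the
#' storage roots bulk radially so that the analytic total root volume grows
#' at \code{growthRateMm3PerDay}. The soil field is generated from the same
#' seed at every step, so only the roots change. A rate of zero returns
#' identical steps.
#'
#' @param spec a \linkS4class{PhantomSpec} with \code{nStorageRoots >= 1}
#'   (unless the rate is 0).
#' @param nSteps number of time steps (>= 2).
#' @param growthRateMm3PerDay volumetric bulking rate.
#' @param daysPerStep days between consecutive steps.
#' @param seed seed (default \code{spec@seed}).
#' @return list of \code{nSteps} elements, each with \code{volume},
#'   \code{truth} and \code{day}.
#' @export
phantomTimeSeries <- function(spec, nSteps, growthRateMm3PerDay,
                              daysPerStep = 3, seed = spec@seed) {
  if (nSteps < 2) stop("nSteps must be >= 2")
  tree <- generateRootTree(spec, seed)
  vmm <- spec@voxelSizeUm / 1000
  if (growthRateMm3PerDay == 0) {
    one <- rasterizePhantom(tree, spec)
    return(lapply(seq_len(nSteps) - 1, function(t)
      c(one, list(day = t * daysPerStep))))
  }
  if (spec@nStorageRoots < 1)
    stop("a positive growth rate requires storage roots (bulking)")
  r0 <- spec@storageDiameterVox * vmm / 2
  g <- seq(0.6, 1, length.out = nSteps)
  v0 <- analyticTreeVolume(tree, vmm, g[1], r0)
  lapply(seq_len(nSteps), function(step) {
    day <- (step - 1) * daysPerStep
    target <- v0 + growthRateMm3PerDay * day
    rT <- if (step == 1) r0 else
      stats::uniroot(function(r)
        analyticTreeVolume(tree, vmm, g[step], r) - target,
        lower = r0 / 2, upper = r0 * 6, tol = 1e-8)$root
    treeT <- scaleTree(tree, g[step], rT, vmm)
    out <- rasterizePhantom(treeT, spec)
    out$day <- day
    out
  })
}
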