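#' Total root volume
#'
#' Root voxel count times the cubic voxel volume.
#'
#' @param mask a \linkS4class{RootMask}.
#' @return volume in mm^3.
#' @examples
#' m <- RootMask(array(rep(c(TRUE, FALSE), 500), c(10, 10, 10)), 100)
#' rootVolume(m)
#' @export
rootVolume <- function(mask) {
  stopifnot(is(mask, "RootMask"))
  sum(mask@data) * (mask@voxelSizeUm / 1000)^3
}

# logical array marking voxels at or below the local soil surface
belowSurface <- function(dims, surface) {
  if (is.null(surface)) return(NULL)
  below <- array(FALSE, dims)
  td <- surface@topDepth
  for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      t0 <- td[j, k]
      if (!is.na(t0) && t0 <= dims[1]) below[t0:dims[1], j, k] <- TRUE
    }
  below
}

#' Root-volume depth profile
#'
#' Per-slice root volume below the soil surface and its cumulative
#' distribution over depth, measured from the mean soil-surface depth.
#' With \code{weightVol} the profile is weighted by the per-voxel values of
#' that volume (density-weighted biomass variant); the default weights every
#' voxel equally (volume-based biomass, the primary definition).
#'
#' @param mask a \linkS4class{RootMask}.
#' @param surface a \linkS4class{SoilSurface}.
#' @param weightVol optional \linkS4class{GrayVolume} of per-voxel weights.
#' @return an object of class \code{DepthProfile}: slice depths (mm below
#'   the mean surface), per-slice volumes (mm^3) and cumulative fractions.
#' @export
depthProfile <- function(mask, surface, weightVol = NULL) {
  stopifnot(is(mask, "RootMask"), is(surface, "SoilSurface"))
  d <- dim(mask@data)
  vmm <- mask@voxelSizeUm / 1000
  below <- belowSurface(d, surface)
  sel <- mask@data & below
  if (!any(sel)) stop("mask is empty below the soil surface")
  w <- if (is.null(weightVol)) array(1, d) else weightVol@data
  perSlice <- vapply(seq_len(d[1]), function(z) sum(w[z, , ][sel[z, , ]]),
                     1.0)
  volumes <- vapply(seq_len(d[1]), function(z) sum(sel[z, , ]), 1.0) * vmm^3
  z0 <- surface@meanDepthSlices
  structure(list(sliceIndex = seq_len(d[1]),
                 depthMm = (seq_len(d[1]) - z0) * vmm,
                 volumeMm3 = volumes,
                 weight = perSlice,
                 cumFraction = cumsum(perSlice) / sum(perSlice),
                 voxelMm = vmm),
            class = "DepthProfile")
}

#' Biomass quantile depth
#'
#' First depth at which the cumulative root-volume fraction reaches
#' \code{q}, interpolated linearly within the slice, in mm below the mean
#' soil surface.
#'
#' @param profile a \code{DepthProfile} from \code{\link{depthProfile}}.
#' @param q quantile level in (0, 1).
#' @return depth in mm.
#' @export
quantileDepth <- function(profile, q) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  cum <- profile$cumFraction
  i <- which(cum >= q)[1]
  prev <- if (i > 1) cum[i - 1] else 0
  lower <- profile$depthMm[i] - profile$voxelMm / 2
  lower + profile$voxelMm * (q - prev) / (cum[i] - prev)
}

#' Form fraction of the root system
#'
#' Root volume below the soil-air interface divided by the volume of the 3D
#' convex hull of the root system, in percent. A compact root ball
#' approaches 100%; a sparse architecture spanning the pot is small.
#'
#' @param mask a \linkS4class{RootMask}.
#' @param surface optional \linkS4class{SoilSurface}; if given, only voxels
#'   below the surface enter volume and hull.
#' @return form fraction in percent (0-100).
#' @export
formFraction <- function(mask, surface = NULL) {
  stopifnot(is(mask, "RootMask"))
  below <- belowSurface(dim(mask@data), surface)
  arr <- if (is.null(below)) mask@data else mask@data & below
  vox <- which(arr, arr.ind = TRUE)
  if (nrow(vox) < 4 ||
      qr(sweep(vox, 2, colMeans(vox)))$rank < 3)
    stop("degenerate (coplanar) mask: the form fraction needs at least 4 ",
         "non-coplanar root voxels; check the segmentation")
  nVox <- nrow(vox)
  hull <- convexHull3d(maskHullPoints(mask, below))
  100 * nVox * (mask@voxelSizeUm / 1000)^3 / hull$volume
}

#' Root angles from the convex-hull top faces
#'
#' Top faces are hull faces whose outward normal has a negative
#' depth-component (facing the soil surface). Each face angle is the
#' dihedral angle between the face plane and the horizontal soil plane, in
#' [0, 90] degrees; the mean is area-weighted over top faces.
#'
#' @param mask a \linkS4class{RootMask}.
#' @param surface optional \linkS4class{SoilSurface} restricting the hull to
#'   below-surface voxels.
#' @return named numeric: \code{thetaMin}, \code{thetaMax}, \code{thetaMean}
#'   (degrees).
#' @export
rootAngles <- function(mask, surface = NULL) {
  stopifnot(is(mask, "RootMask"))
  below <- belowSurface(dim(mask@data), surface)
  hull <- convexHull3d(maskHullPoints(mask, below))
  top <- which(hull$normals[, 1] < -1e-9)
  if (!length(top)) stop("hull has no top faces")
  theta <- acos(pmin(1, abs(hull$normals[top, 1]))) * 180 / pi
  w <- hull$areas[top]
  c(thetaMin = min(theta), thetaMax = max(theta),
    thetaMean = sum(theta * w) / sum(w))
}

#' Gray-value densities of roots and surrounding soil
#'
#' Per-voxel density is the product of the gray value and the correlated
#' attenuation coefficient. Root density averages over mask voxels, soil
#' density over pot-interior non-root voxels, and the soil density around
#' roots over the non-root voxels within \code{radiusMm} of the mask.
#'
#' @param gray \linkS4class{GrayVolume} in gray values.
#' @param atten \linkS4class{GrayVolume} in attenuation units.
#' @param mask a \linkS4class{RootMask}.
#' @param interior logical array marking the retained pot interior.
#' @param radiusMm halo radius around roots (default 1 mm).
#' @return named list: \code{meanRootDensity}, \code{sdRootDensity},
#'   \code{meanSoilDensity}, \code{sdSoilDensity},
#'   \code{earthRootRelationPct} (100 * soil / root),
#'   \code{soilDensityAroundRoots}.
#' @export
rootDensities <- function(gray, atten, mask, interior, radiusMm = 1) {
  stopifnot(is(gray, "GrayVolume"), is(atten, "GrayVolume"),
            is(mask, "RootMask"))
  if (radiusMm <= 0) stop("radiusMm must be > 0")
  d <- dim(mask@data)
  if (!identical(dim(gray@data), d) || !identical(dim(atten@data), d))
    stop("geometry mismatch")
  dens <- gray@data * atten@data
  rootSel <- mask@data & interior
  soilSel <- interior & !mask@data
  if (!any(rootSel)) stop("empty root mask")
  if (!any(soilSel)) stop("no soil voxels in the pot interior")
  rv <- dens[rootSel]; sv <- dens[soilSel]
  rVox <- radiusMm / (mask@voxelSizeUm / 1000)
  edt2 <- array(cpp_edt_sq(as.vector(!mask@data), d, FALSE), d)
  halo <- soilSel & edt2 <= rVox^2
  list(meanRootDensity = mean(rv), sdRootDensity = stats::sd(rv),
       meanSoilDensity = mean(sv), sdSoilDensity = stats::sd(sv),
       earthRootRelationPct = 100 * mean(sv) / mean(rv),
       soilDensityAroundRoots = if (any(halo)) mean(dens[halo]) else
         NA_real_)
}

#' Compute the full trait report
#'
#' Derives every global feature from the segmented mask, the root graph and
#' the gray/attenuation volumes: total root volume, graph root length
#' (voxel-count convention, Euclidean variant alongside), biomass depth
#' quantiles (25/50/75/90%), form fraction, hull root angles, densities and
#' tip count.
#'
#' @param mask a \linkS4class{RootMask}.
#' @param graph a \linkS4class{RootGraph}.
#' @param surface a \linkS4class{SoilSurface}.
#' @param gray,atten optional volumes for the density block.
#' @param interior optional pot-interior logical array.
#' @param radiusMm halo radius for the soil-around-roots density.
#' @return a \linkS4class{TraitReport}.
#' @export
computeTraits <- function(mask, graph, surface, gray = NULL, atten = NULL,
                          interior = NULL, radiusMm = 1) {
  prof <- depthProfile(mask, surface)
  ang <- tryCatch(rootAngles(mask, surface),
                  error = function(e) c(thetaMin = NA_real_,
                                        thetaMax = NA_real_,
                                        thetaMean = NA_real_))
  ff <- tryCatch(formFraction(mask, surface),
                 error = function(e) NA_real_)
  dens <- if (!is.null(gray) && !is.null(atten) && !is.null(interior)) {
    rootDensities(gray, atten, mask, interior, radiusMm)
  } else {
    list(meanRootDensity = NA_real_, sdRootDensity = NA_real_,
         meanSoilDensity = NA_real_, sdSoilDensity = NA_real_,
         earthRootRelationPct = NA_real_,
         soilDensityAroundRoots = NA_real_)
  }
  values <- c(list(
    vRootMm3 = rootVolume(mask),
    lRootMm = graphLength(graph, "voxel"),
    lRootEuclidMm = graphLength(graph, "euclidean"),
    depthQ25Mm = quantileDepth(prof, 0.25),
    depthQ50Mm = quantileDepth(prof, 0.50),
    depthQ75Mm = quantileDepth(prof, 0.75),
    depthQ90Mm = quantileDepth(prof, 0.90),
    formFractionPct = ff,
    thetaMinDeg = unname(ang["thetaMin"]),
    thetaMaxDeg = unname(ang["thetaMax"]),
    thetaMeanDeg = unname(ang["thetaMean"])),
    dens,
    list(nTips = countTips(graph),
         nExtraComponents = graph@extraComponents))
  new("TraitReport", values = values)
}
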