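#' @useDynLib rootCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' GrayVolume: a 3D scalar CT volume with cubic voxels
#'
#' Container for a reconstructed X-ray CT volume (or any derived scalar
#' volume). The array is indexed \code{[depth, y, x]}: axis 1 is the depth
#' axis, slice index 1 is the top of the pot and indices increase downward.
#' Voxels are cubic with edge length \code{voxelSizeUm} micrometres.
#'
#' @slot data 3D numeric array.
#' @slot voxelSizeUm positive scalar, cubic voxel edge length in micrometres.
#' @export
setClass("GrayVolume",
  representation(data = "array", voxelSizeUm = "numeric"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be a 3D array")
    if (any(dim(d) < 1L)) return("all three dimensions must be >= 1")
    if (length(object@voxelSizeUm) != 1L || !is.finite(object@voxelSizeUm) ||
        object@voxelSizeUm <= 0)
      return("voxelSizeUm must be a positive finite scalar")
    if (anyNA(d) || any(!is.finite(d))) return("data must be finite")
    TRUE
  }
)

#' Construct a GrayVolume
#'
#' @param data 3D numeric array, axis 1 = depth (downward).
#' @param voxelSizeUm cubic voxel edge length in micrometres.
#' @return A \linkS4class{GrayVolume}.
#' @examples
#' v <- GrayVolume(array(0, c(4, 4, 4)), voxelSizeUm = 100)
#' voxelSize(v)
#' @export
GrayVolume <- function(data, voxelSizeUm) {
  new("GrayVolume", data = data, voxelSizeUm = as.numeric(voxelSizeUm))
}

#' ResponseVolume: the output of one detection branch
#'
#' A \linkS4class{GrayVolume} carrying the non-negative per-voxel response of
#' either the multiscale vesselness branch or the local-variance branch,
#' together with the scales that produced it.
#'
#' @slot branch "vesselness" or "variance".
#' @slot scales numeric vector of scales (voxels) used.
#' @export
setClass("ResponseVolume",
  contains = "GrayVolume",
  representation(branch = "character", scales = "numeric"),
  validity = function(object) {
    if (!object@branch %in% c("vesselness", "variance"))
      return("branch must be 'vesselness' or 'variance'")
    if (any(object@data < 0)) return("response data must be non-negative")
    TRUE
  }
)

#' RootMask: a binary root segmentation
#'
#' Binary volume marking root voxels, sharing the geometry of its source
#' volume. \code{provenance} records a hash of the parameter set that
#' produced the mask so batch runs can assert the one-parameter-set contract.
#'
#' @slot data 3D logical array.
#' @slot voxelSizeUm voxel edge length in micrometres.
#' @slot provenance character, parameter-set hash ("" if unknown).
#' @export
setClass("RootMask",
  representation(data = "array", voxelSizeUm = "numeric",
                 provenance = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (!is.logical(object@data)) return("mask data must be logical")
    if (anyNA(object@data)) return("mask data must not contain NA")
    if (object@voxelSizeUm <= 0) return("voxelSizeUm must be positive")
    TRUE
  }
)

#' Construct a RootMask
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param voxelSizeUm voxel edge length in micrometres.
#' @param provenance optional parameter-set hash.
#' @return A \linkS4class{RootMask}.
#' @export
RootMask <- function(data, voxelSizeUm, provenance = "") {
  if (!is.logical(data)) {
    stopifnot(all(data %in% c(0, 1)))
    data <- array(data > 0, dim = dim(data))
  }
  new("RootMask", data = data, voxelSizeUm = as.numeric(voxelSizeUm),
      provenance = provenance)
}

#' AttenuationCalibration: affine map from gray values to attenuation
#'
#' Linear calibration \eqn{A = slope \cdot g + intercept} between detector
#' gray values and attenuation coefficients.
#'
#' @slot slope attenuation per gray-value unit, > 0.
#' @slot intercept attenuation at gray value 0.
#' @export
setClass("AttenuationCalibration",
  representation(slope = "numeric", intercept = "numeric"),
  validity = function(object) {
    if (object@slope <= 0) return("slope must be > 0")
    TRUE
  }
)

#' @rdname AttenuationCalibration-class
#' @param slope attenuation per gray-value unit (> 0).
#' @param intercept attenuation at gray value 0.
#' @return An \linkS4class{AttenuationCalibration}.
#' @examples
#' AttenuationCalibration(slope = 0.24 / 65535, intercept = 0)
#' @export
AttenuationCalibration <- function(slope = 1, intercept = 0) {
  new("AttenuationCalibration", slope = as.numeric(slope),
      intercept = as.numeric(intercept))
}

#' ParameterSet: the single tuning object P of the segmentation pipeline
#'
#' Holds every tunable of the segmentation, kept constant across a time
#' series: the attenuation window (\code{aMin}, \code{aMax}), the list of
#' target root diameters \code{dRoot} (voxels) driving the vesselness scales,
#' the two fusion thresholds \code{theta1} (vesselness, gray-value scale) and
#' \code{theta2} (local variance, gray-value scale), the minimum component
#' volume \code{vMinMm3} (mm^3) and post-processing options.
#'
#' @slot aMin,aMax attenuation window bounds (aMin < aMax).
#' @slot dRoot numeric vector of root diameters in voxels.
#' @slot theta1 vesselness threshold (lower bound), gray-value scale.
#' @slot theta2 local-variance threshold (upper bound = homogeneity),
#'   gray-value scale.
#' @slot vMinMm3 minimum connected-component volume in mm^3.
#' @slot medianKernel odd integer kernel of the optional binary median
#'   filter; 1 disables it.
#' @slot polarity "dark" (roots attenuate less than soil, the default for
#'   water-filled roots in mineral soil) or "bright".
#' @slot connectivity 6, 18 or 26 for component labelling.
#' @slot responseScale factor mapping the native [0,1] vesselness onto the
#'   gray-value scale of \code{theta1} (default 65535).
#' @slot frangiC structure-norm constant c of the vesselness filter; NA
#'   adapts it per volume (half the maximal Hessian norm), a fixed value
#'   keeps responses comparable across a batch (one-parameter-set
#'   contract).
#' @slot varianceScale Gaussian scale lambda (voxels) of the variance branch;
#'   NA means max(dRoot).
#' @slot varianceDilateVox dilation (voxels) recovering the high-variance
#'   partial-volume rim of storage roots after the thickness test; NA means
#'   1.5x the variance scale, 0 disables.
#' @slot thicknessTest logical; require homogeneity components to be thicker
#'   than max(dRoot) (distance-transform test) before the variance branch may
#'   contribute.
#' @export
setClass("ParameterSet",
  representation(aMin = "numeric", aMax = "numeric", dRoot = "numeric",
                 theta1 = "numeric", theta2 = "numeric", vMinMm3 = "numeric",
                 medianKernel = "integer", polarity = "character",
                 connectivity = "integer", responseScale = "numeric",
                 frangiC = "numeric",
                 varianceScale = "numeric", varianceDilateVox = "numeric",
                 thicknessTest = "logical"),
  validity = function(object) {
    if (object@aMin >= object@aMax) return("aMin must be < aMax")
    if (length(object@dRoot) < 1L || any(object@dRoot <= 0))
      return("dRoot must be a non-empty list of positive diameters")
    if (object@theta1 <= 0) return("theta1 must be > 0")
    if (object@theta2 <= 0) return("theta2 must be > 0")
    if (object@vMinMm3 < 0) return("vMinMm3 must be >= 0")
    if (object@medianKernel < 1L || object@medianKernel %% 2L == 0L)
      return("medianKernel must be an odd integer >= 1")
    if (!object@polarity %in% c("dark", "bright"))
      return("polarity must be 'dark' or 'bright'")
    if (!object@connectivity %in% c(6L, 18L, 26L))
      return("connectivity must be 6, 18 or 26")
    TRUE
  }
)

#' @rdname ParameterSet-class
#' @param aMin,aMax attenuation window.
#' @param dRoot root-diameter list in voxels.
#' @param theta1,theta2 fusion thresholds.
#' @param vMinMm3 minimum component volume (mm^3).
#' @param medianKernel odd integer, 1 = off.
#' @param polarity "dark" or "bright".
#' @param connectivity 6, 18 or 26.
#' @param responseScale vesselness gray-value scaling.
#' @param frangiC fixed vesselness structure-norm constant (NA = adaptive).
#' @param varianceScale variance-branch Gaussian scale in voxels
#'   (NA = max(dRoot)).
#' @param varianceDilateVox rim-recovery dilation in voxels (NA = auto).
#' @param thicknessTest enable the minimum-thickness support test of the
#'   variance branch.
#' @return A \linkS4class{ParameterSet}.
#' @examples
#' p <- ParameterSet(aMin = 0.11, aMax = 0.24,
#'                   dRoot = c(2, 2.5, 3, 3.5, 4, 5, 6),
#'                   theta1 = 400, theta2 = 2500, vMinMm3 = 1)
#' @export
ParameterSet <- function(aMin, aMax, dRoot, theta1, theta2, vMinMm3 = 0,
                         medianKernel = 1L, polarity = "dark",
                         connectivity = 26L, responseScale = 65535,
                         frangiC = NA_real_, varianceScale = NA_real_,
                         varianceDilateVox = 0, thicknessTest = TRUE) {
  new("ParameterSet", aMin = as.numeric(aMin), aMax = as.numeric(aMax),
      dRoot = as.numeric(dRoot), theta1 = as.numeric(theta1),
      theta2 = as.numeric(theta2), vMinMm3 = as.numeric(vMinMm3),
      medianKernel = as.integer(medianKernel), polarity = polarity,
      connectivity = as.integer(connectivity),
      responseScale = as.numeric(responseScale),
      frangiC = as.numeric(frangiC),
      varianceScale = as.numeric(varianceScale),
      varianceDilateVox = as.numeric(varianceDilateVox),
      thicknessTest = isTRUE(thicknessTest))
}

#' PotModel: per-slice circular model of the pot inner wall
#'
#' @slot centerYx matrix (nSlices x 2) of per-slice circle centers in voxel
#'   coordinates (axes 2 and 3).
#' @slot innerRadiusMm per-slice inner-wall radius in mm.
#' @slot wallThicknessMm pot wall thickness in mm.
#' @slot wallAttenuationRange length-2 numeric, attenuation range of the
#'   wall material.
#' @slot fitted logical per slice: TRUE where a ring was detected (others
#'   inherit the nearest fitted slice).
#' @export
setClass("PotModel",
  representation(centerYx = "matrix", innerRadiusMm = "numeric",
                 wallThicknessMm = "numeric",
                 wallAttenuationRange = "numeric", fitted = "logical"),
  validity = function(object) {
    if (any(object@innerRadiusMm <= 0)) return("inner radii must be > 0")
    if (object@wallThicknessMm <= 0) return("wall thickness must be > 0")
    TRUE
  }
)

#' SoilSurface: the soil-air interface and the root entry point
#'
#' @slot topDepth matrix (axis2 x axis3) of the first depth slice containing
#'   soil at each horizontal position (NA outside the pot).
#' @slot entryPoint numeric length-3 voxel coordinate (depth, y, x) where the
#'   stem meets the soil.
#' @slot meanDepthSlices mean soil-surface depth in slice units, used as the
#'   depth origin of the trait report.
#' @export
setClass("SoilSurface",
  representation(topDepth = "matrix", entryPoint = "numeric",
                 meanDepthSlices = "numeric"))

#' Skeleton: 1-voxel-wide curve skeleton of a root mask
#'
#' @slot voxels integer matrix (n x 3) of voxel coordinates (depth, y, x).
#' @slot dims integer length-3 dims of the source volume.
#' @slot voxelSizeUm voxel edge length in micrometres.
#' @export
setClass("Skeleton",
  representation(voxels = "matrix", dims = "integer",
                 voxelSizeUm = "numeric"))

#' RootGraph: directed junction/endpoint graph over the skeleton
#'
#' Nodes sit at skeleton voxels with other than two neighbours (endpoints and
#' junctions) plus the entry voxel; edges are the 26-connected voxel chains
#' between nodes, directed away from the entry.
#'
#' @slot nodes data.frame with columns id, type ("entry", "branch", "tip"),
#'   i, j, k (voxel coordinates).
#' @slot edges list of edges; each edge is a list with fields \code{from},
#'   \code{to} (node ids), \code{polyline} (matrix of voxel coordinates from
#'   tail to head) and \code{lengthMm} (Euclidean polyline length).
#' @slot voxelSizeUm voxel edge length in micrometres.
#' @slot entryNode id of the entry node.
#' @slot extraComponents number of skeleton components not connected to the
#'   entry (excluded from the graph, reported for QC).
#' @export
setClass("RootGraph",
  representation(nodes = "data.frame", edges = "list",
                 voxelSizeUm = "numeric", entryNode = "integer",
                 extraComponents = "integer"))

#' TraitReport: global root-system feature vector
#'
#' All trait values computed from one segmented volume: total root volume,
#' graph-based root length, biomass depth quantiles, convex-hull form
#' fraction, hull-face root angles, gray-value densities and tip count.
#'
#' @slot values named list of trait values (see \code{\link{computeTraits}}).
#' @export
setClass("TraitReport", representation(values = "list"),
  validity = function(object) {
    f <- object@values$formFractionPct
    if (!is.null(f) && is.finite(f) && (f < 0 || f > 100))
      return("form fraction must lie in [0, 100] %")
    TRUE
  }
)

#' PhantomSpec: parameters of the synthetic root-phantom generator
#'
#' Describes a synthetic pot: geometry, soil texture, fine-root tree
#' statistics, optional thick storage roots, and image degradation. The
#' defaults emulate the imaging conditions the pipeline is designed for:
#' roots at attenuation 0.15 against soil at mean 0.18 so the shipped bean
#' window (0.11, 0.24) applies unchanged.
#'
#' @slot potInnerDiameterMm,wallThicknessMm pot geometry.
#' @slot potDepthMm soil column depth below the surface.
#' @slot headspaceMm air gap above the soil surface.
#' @slot voxelSizeUm cubic voxel size.
#' @slot soilMean,soilSd,soilCorrelationVox soil attenuation texture: mean,
#'   standard deviation and Gaussian correlation length (voxels).
#' @slot stoneDensity expected stones+pores per 1000 mm^3 of soil.
#' @slot rootAttenuation attenuation inside roots.
#' @slot wallAttenuation attenuation of the pot wall.
#' @slot branchingDepth,branchProbability recursion depth and per-node
#'   probability of binary branching of the fine-root tree.
#' @slot insertionAngleRangeDeg length-2 range of lateral insertion angles.
#' @slot diameterStartVox,diameterEndVox taper of fine-root diameters.
#' @slot tortuosity per-step angular jitter (radians, sd).
#' @slot segmentLengthMm length of one branch segment.
#' @slot nStorageRoots,storageDiameterVox storage-root count and diameter.
#' @slot noiseSd additive Gaussian noise sd (attenuation units).
#' @slot blurSigmaVox global Gaussian blur (partial-volume) sigma.
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("PhantomSpec",
  representation(potInnerDiameterMm = "numeric", wallThicknessMm = "numeric",
                 potDepthMm = "numeric", headspaceMm = "numeric",
                 voxelSizeUm = "numeric", soilMean = "numeric",
                 soilSd = "numeric", soilCorrelationVox = "numeric",
                 stoneDensity = "numeric", rootAttenuation = "numeric",
                 wallAttenuation = "numeric", branchingDepth = "integer",
                 branchProbability = "numeric",
                 insertionAngleRangeDeg = "numeric",
                 diameterStartVox = "numeric", diameterEndVox = "numeric",
                 tortuosity = "numeric", segmentLengthMm = "numeric",
                 nStorageRoots = "integer", storageDiameterVox = "numeric",
                 noiseSd = "numeric", blurSigmaVox = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@diameterStartVox <= 0 || object@diameterEndVox <= 0)
      return("diameters must be > 0")
    if (object@potInnerDiameterMm <= 0) return("pot diameter must be > 0")
    TRUE
  }
)

#' PhantomTruth: ground truth of a rasterized phantom
#'
#' @slot mask \linkS4class{RootMask} of the true root voxels (before blur
#'   and noise).
#' @slot polylines list of matrices (mm coordinates, depth/y/x) with
#'   attribute "diameterVox" per point.
#' @slot vRootMm3 true root volume (mask voxel count x voxel volume).
#' @slot lengthMm true centerline arc length.
#' @slot nTips true tip count (tree leaves).
#' @slot entryPoint voxel coordinate of the stem entry.
#' @slot surfaceSlice depth slice of the flat soil surface.
#' @export
setClass("PhantomTruth",
  representation(mask = "RootMask", polylines = "list", vRootMm3 = "numeric",
                 lengthMm = "numeric", nTips = "integer",
                 entryPoint = "numeric", surfaceSlice = "numeric"))
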