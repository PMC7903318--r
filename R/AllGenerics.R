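#' Accessors for volume-like objects
#'
#' \code{volData} returns the raw array of a volume, mask or response;
#' \code{voxelSize} returns the cubic voxel edge length in micrometres.
#'
#' @param x a \linkS4class{GrayVolume}, \linkS4class{RootMask},
#'   \linkS4class{ResponseVolume} or \linkS4class{Skeleton}.
#' @return \code{volData}: the underlying array; \code{voxelSize}: a numeric
#'   scalar in micrometres.
#' @examples
#' v <- GrayVolume(array(1, c(3, 3, 3)), 87.7)
#' dim(volData(v)); voxelSize(v)
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname volData
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volData
#' @export
setMethod("volData", "GrayVolume", function(x) x@data)

#' @rdname volData
#' @export
setMethod("volData", "RootMask", function(x) x@data)

#' @rdname volData
#' @export
setMethod("voxelSize", "GrayVolume", function(x) x@voxelSizeUm)

#' @rdname volData
#' @export
setMethod("voxelSize", "RootMask", function(x) x@voxelSizeUm)

#' @rdname volData
#' @export
setMethod("voxelSize", "Skeleton", function(x) x@voxelSizeUm)

#' @describeIn GrayVolume-class dimensions of the volume array.
#' @param x a GrayVolume.
#' @export
setMethod("dim", "GrayVolume", function(x) dim(x@data))

#' @describeIn RootMask-class dimensions of the mask array.
#' @param x a RootMask.
#' @export
setMethod("dim", "RootMask", function(x) dim(x@data))

setMethod("show", "GrayVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d, voxel %.6g um, range [%.6g, %.6g]\n",
              class(object), d[1], d[2], d[3], object@voxelSizeUm,
              min(object@data), max(object@data)))
})

setMethod("show", "ResponseVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ResponseVolume (%s) %d x %d x %d, scales: %s\n",
              object@branch, d[1], d[2], d[3],
              paste(signif(object@scales, 4), collapse = ", ")))
})

setMethod("show", "RootMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("RootMask %d x %d x %d, voxel %.6g um, %d root voxels\n",
              d[1], d[2], d[3], object@voxelSizeUm, sum(object@data)))
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet\n")
  cat(sprintf("  attenuation window : (%g, %g)\n", object@aMin, object@aMax))
  cat(sprintf("  D_root (voxels)    : %s\n",
              paste(object@dRoot, collapse = ", ")))
  cat(sprintf("  theta1 / theta2    : %g / %g\n", object@theta1,
              object@theta2))
  cat(sprintf("  V_min (mm^3)       : %g\n", object@vMinMm3))
  cat(sprintf("  median kernel      : %d, polarity: %s, connectivity: %d\n",
              object@medianKernel, object@polarity, object@connectivity))
})

setMethod("show", "RootGraph", function(object) {
  types <- table(object@nodes$type)
  cat(sprintf("RootGraph: %d nodes (%s), %d edges\n",
              nrow(object@nodes),
              paste(sprintf("%s=%d", names(types), as.integer(types)),
                    collapse = ", "),
              length(object@edges)))
})

setMethod("show", "TraitReport", function(object) {
  v <- object@values
  cat("TraitReport\n")
  cat(sprintf("  V_root  : %.2f mm^3\n", v$vRootMm3))
  cat(sprintf("  L_root  : %.2f mm (euclid %.2f mm)\n", v$lRootMm,
              v$lRootEuclidMm))
  cat(sprintf("  quantile depths (mm): 25%%=%.1f 50%%=%.1f 75%%=%.1f 90%%=%.1f\n",
              v$depthQ25Mm, v$depthQ50Mm, v$depthQ75Mm, v$depthQ90Mm))
  cat(sprintf("  F       : %.2f %%\n", v$formFractionPct))
  cat(sprintf("  angles  : min %.1f / mean %.1f / max %.1f deg\n",
              v$thetaMinDeg, v$thetaMeanDeg, v$thetaMaxDeg))
  cat(sprintf("  density : root %.1f +/- %.1f, soil %.1f +/- %.1f, relation %.1f %%\n",
              v$meanRootDensity, v$sdRootDensity, v$meanSoilDensity,
              v$sdSoilDensity, v$earthRootRelationPct))
  cat(sprintf("  tips    : %d\n", v$nTips))
})

#' Flatten a TraitReport to a one-row data.frame
#'
#' @param x a \linkS4class{TraitReport}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return one-row \code{data.frame} with one column per trait.
#' @export
as.data.frame.TraitReport <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  as.data.frame(x@values, stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.TraitReport
#' @param object a TraitReport.
#' @export
traitValues <- function(object) object@values
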