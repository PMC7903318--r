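#' Fuse the vesselness and variance branches into one root mask
#'
#' A voxel is root if either branch admits it:
#' \itemize{
#'   \item fine-root branch: vesselness response >= \code{theta1};
#'   \item storage-root branch: the voxel is inside the attenuation window,
#'     its local variance is <= \code{theta2} (homogeneity), and it belongs
#'     to a homogeneity component whose minimum thickness exceeds
#'     \code{maxDiameterVox} (distance-transform test) so that fine soil
#'     homogeneity cannot leak in.
#' }
#'
#' @param vesselness \linkS4class{ResponseVolume}, branch "vesselness".
#' @param variance \linkS4class{ResponseVolume}, branch "variance".
#' @param windowed the attenuation-windowed \linkS4class{GrayVolume}
#'   (background sentinel 0).
#' @param theta1 vesselness threshold (lower bound).
#' @param theta2 variance threshold (upper bound).
#' @param maxDiameterVox thickness requirement of the storage branch in
#'   voxels; defaults to twice the largest vesselness scale, i.e.
#'   \code{max(dRoot)}.
#' @param thicknessTest set FALSE to disable the thickness support test.
#' @param connectivity labelling connectivity for the thickness test.
#' @param dilateVox after the thickness test, grow the surviving
#'   homogeneity components by this many voxels (restricted to the
#'   attenuation window). The rim of a storage root carries the
#'   partial-volume ramp between root and soil and therefore high local
#'   variance; dilation recovers it. 0 disables.
#' @param provenance optional parameter hash stored in the mask.
#' @return a \linkS4class{RootMask}.
#' @export
mergeResponses <- function(vesselness, variance, windowed, theta1, theta2,
                           maxDiameterVox = 2 * max(vesselness@scales),
                           thicknessTest = TRUE, connectivity = 26L,
                           dilateVox = 0, provenance = "") {
  stopifnot(is(vesselness, "ResponseVolume"), is(variance, "ResponseVolume"),
            is(windowed, "GrayVolume"))
  d <- dim(windowed@data)
  if (!identical(d, dim(vesselness@data)) ||
      !identical(d, dim(variance@data)))
    stop("geometry mismatch between responses and windowed volume")
  fine <- vesselness@data >= theta1
  cand <- windowed@data != 0 & variance@data <= theta2
  if (thicknessTest && any(cand)) {
    lab <- cpp_label3d(as.vector(cand), d, as.integer(connectivity))
    edt2 <- cpp_edt_sq(as.vector(cand), d, TRUE)
    maxEdt2 <- tapply(edt2[lab > 0], lab[lab > 0], max)
    thick <- as.integer(names(maxEdt2))[2 * sqrt(maxEdt2) > maxDiameterVox]
    cand <- array(lab %in% thick, d)
  }
  if (dilateVox > 0 && any(cand)) {
    dist2 <- cpp_edt_sq(as.vector(!cand), d, FALSE)
    cand <- array(dist2 <= dilateVox^2, d) & windowed@data != 0
  }
  RootMask(fine | cand, voxelSizeUm = windowed@voxelSizeUm,
           provenance = provenance)
}

#' Binary volumetric median filter (majority vote)
#'
#' @param mask a \linkS4class{RootMask}.
#' @param kernel odd integer edge of the cubic neighbourhood; 1 is the
#'   identity. Voxels outside the volume count as background.
#' @return the filtered \linkS4class{RootMask}.
#' @export
medianFilterMask <- function(mask, kernel) {
  stopifnot(is(mask, "RootMask"))
  if (kernel < 1 || kernel %% 2 == 0) stop("kernel must be an odd integer")
  if (kernel == 1) return(mask)
  d <- dim(mask@data)
  counts <- cpp_boxsum(as.numeric(mask@data), d, as.integer(kernel))
  RootMask(array(counts > kernel^3 / 2, d), voxelSizeUm = mask@voxelSizeUm,
           provenance = mask@provenance)
}

#' Remove connected components smaller than a minimum volume
#'
#' Component volume is voxel count times the cubic voxel volume; components
#' below \code{vMinMm3} are dropped.
#'
#' @param mask a \linkS4class{RootMask}.
#' @param vMinMm3 minimum component volume in mm^3 (0 = identity).
#' @param connectivity 6, 18 or 26 (default).
#' @return the filtered \linkS4class{RootMask}.
#' @export
sizeFilter <- function(mask, vMinMm3, connectivity = 26L) {
  stopifnot(is(mask, "RootMask"), vMinMm3 >= 0)
  if (vMinMm3 == 0 || !any(mask@data)) return(mask)
  d <- dim(mask@data)
  lab <- cpp_label3d(as.vector(mask@data), d, as.integer(connectivity))
  voxMm3 <- (mask@voxelSizeUm / 1000)^3
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * voxMm3 >= vMinMm3)
  RootMask(array(lab %in% keep, d), voxelSizeUm = mask@voxelSizeUm,
           provenance = mask@provenance)
}

#' Shipped parameter presets
#'
#' Returns one of the published parameter sets (\code{"bean_small_pot"},
#' \code{"bean_medium_pot"}, \code{"cassava"}) or the \code{"phantom"}
#' preset calibrated once for the synthetic phantom generator shipped with
#' the package. Thresholds of the published presets are stated on the
#' 16-bit gray-value scale of the original acquisitions; the phantom preset
#' is stated on the attenuation scale the generator produces.
#'
#' @param name preset name.
#' @return a \linkS4class{ParameterSet}.
#' @examples
#' presetParameters("cassava")
#' @export
presetParameters <- function(name = c("bean_small_pot", "bean_medium_pot",
                                      "cassava", "phantom",
                                      "phantom_storage")) {
  name <- match.arg(name)
  switch(name,
    bean_small_pot = ParameterSet(
      aMin = 0.11, aMax = 0.24, dRoot = c(2, 2.5, 3, 3.5, 4, 5, 6),
      theta1 = 400, theta2 = 2500, vMinMm3 = 1, medianKernel = 3L,
      polarity = "dark"),
    bean_medium_pot = ParameterSet(
      aMin = 0.11, aMax = 0.24, dRoot = c(2, 2.5, 3, 3.5, 4, 5, 6),
      theta1 = 600, theta2 = 2000, vMinMm3 = 1.6, medianKernel = 3L,
      polarity = "dark"),
    cassava = ParameterSet(
      aMin = 0.08, aMax = 0.2, dRoot = c(1, 1.5, 2, 3),
      theta1 = 60, theta2 = 65000, vMinMm3 = 5, medianKernel = 1L,
      polarity = "dark"),
    phantom = ParameterSet(
      aMin = 0.11, aMax = 0.24, dRoot = c(2.5, 3, 4, 5, 6),
      theta1 = 8000, theta2 = 1e-6, vMinMm3 = 20,
      medianKernel = 1L, polarity = "dark", frangiC = 0.006,
      varianceScale = 3, varianceDilateVox = 0),
    phantom_storage = ParameterSet(
      aMin = 0.11, aMax = 0.24, dRoot = c(2.5, 3, 4, 5, 6),
      theta1 = 8000, theta2 = 1e-3, vMinMm3 = 20,
      medianKernel = 1L, polarity = "dark", frangiC = 0.006,
      varianceScale = 3, varianceDilateVox = NA_real_))
}

#' Read or write a ParameterSet as YAML/JSON config
#'
#' The config uses the published field names: \code{attenuation_range},
#' \code{D_root}, \code{theta1}, \code{theta2}, \code{V_min},
#' \code{median_kernel}, \code{polarity}.
#'
#' @param path config path (.yaml/.yml or .json).
#' @return \code{readParameterSet}: a \linkS4class{ParameterSet}.
#' @export
readParameterSet <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
    yaml::read_yaml(path) else jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
  for (key in c("attenuation_range", "D_root", "theta1", "theta2", "V_min"))
    if (is.null(cfg[[key]])) stop("config is missing key '", key, "'")
  ParameterSet(aMin = cfg$attenuation_range[[1]],
               aMax = cfg$attenuation_range[[2]],
               dRoot = unlist(cfg$D_root),
               theta1 = cfg$theta1, theta2 = cfg$theta2,
               vMinMm3 = cfg$V_min,
               medianKernel = cfg$median_kernel %||% 1L,
               polarity = cfg$polarity %||% "dark",
               connectivity = cfg$connectivity %||% 26L,
               responseScale = cfg$response_scale %||% 65535,
               frangiC = cfg$frangi_c %||% NA_real_,
               varianceScale = cfg$variance_scale %||% NA_real_,
               varianceDilateVox = cfg$variance_dilate %||% 0,
               thicknessTest = cfg$thickness_test %||% TRUE)
}

#' @rdname readParameterSet
#' @param params a \linkS4class{ParameterSet}.
#' @return \code{writeParameterSet}: \code{invisible(path)}.
#' @export
writeParameterSet <- function(params, path) {
  cfg <- list(attenuation_range = c(params@aMin, params@aMax),
              D_root = params@dRoot, theta1 = params@theta1,
              theta2 = params@theta2, V_min = params@vMinMm3,
              median_kernel = params@medianKernel,
              polarity = params@polarity,
              connectivity = params@connectivity,
              response_scale = params@responseScale,
              frangi_c = params@frangiC,
              variance_scale = params@varianceScale,
              variance_dilate = params@varianceDilateVox,
              thickness_test = params@thicknessTest)
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
    yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hash of a ParameterSet
#'
#' Stable hash recording which parameter set produced a mask; identical
#' across a batch by the one-parameter-set contract.
#'
#' @param params a \linkS4class{ParameterSet}.
#' @return character hash.
#' @export
parameterHash <- function(params) {
  slots <- lapply(slotNames(params), function(s) slot(params, s))
  names(slots) <- slotNames(params)
  rlang::hash(slots)
}
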