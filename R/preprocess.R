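#' Detect the pot wall as a per-slice circle model
#'
#' The pot wall is found per depth slice by thresholding the attenuation
#' volume to the wall material range and fitting a circle to the inner wall
#' boundary (innermost wall voxel per angular bin, algebraic least-squares
#' fit). Slices without a detectable ring inherit the nearest fitted slice.
#'
#' @param vol a \linkS4class{GrayVolume} in attenuation units.
#' @param wallAttenuationRange length-2 numeric: attenuation range of the
#'   pot material, separable from soil.
#' @param wallThicknessMm pot wall thickness in mm.
#' @param minVoxels minimum wall voxels per slice for a fit attempt.
#' @return A \linkS4class{PotModel}.
#' @export
detectPot <- function(vol, wallAttenuationRange, wallThicknessMm,
                      minVoxels = 20) {
  stopifnot(is(vol, "GrayVolume"), length(wallAttenuationRange) == 2)
  d <- dim(vol@data)
  vmm <- vol@voxelSizeUm / 1000
  centers <- matrix(NA_real_, d[1], 2)
  radii <- rep(NA_real_, d[1])
  fitted <- rep(FALSE, d[1])
  for (z in seq_len(d[1])) {
    sl <- vol@data[z, , ]
    w <- which(sl >= wallAttenuationRange[1] & sl <= wallAttenuationRange[2],
               arr.ind = TRUE)
    if (nrow(w) < minVoxels) next
    fit <- fitInnerCircle(w)
    if (is.null(fit)) next
    centers[z, ] <- fit$center
    radii[z] <- fit$radius * vmm
    fitted[z] <- TRUE
  }
  if (!any(fitted)) stop("no pot detected")
  # slices without a ring inherit the nearest fitted slice
  fi <- which(fitted)
  for (z in which(!fitted)) {
    nn <- fi[which.min(abs(fi - z))]
    centers[z, ] <- centers[nn, ]
    radii[z] <- radii[nn]
  }
  new("PotModel", centerYx = centers, innerRadiusMm = radii,
      wallThicknessMm = as.numeric(wallThicknessMm),
      wallAttenuationRange = as.numeric(wallAttenuationRange),
      fitted = fitted)
}

# Inner boundary extraction + Kasa algebraic circle fit.
# w: matrix of (row=y, col=x) wall-voxel coordinates in one slice.
fitInnerCircle <- function(w, nBins = 180) {
  cy <- mean(w[, 1]); cx <- mean(w[, 2])
  ang <- atan2(w[, 1] - cy, w[, 2] - cx)
  rad <- sqrt((w[, 1] - cy)^2 + (w[, 2] - cx)^2)
  bin <- pmin(nBins, 1L + as.integer((ang + pi) / (2 * pi) * nBins))
  inner <- tapply(seq_len(nrow(w)), bin, function(ix) ix[which.min(rad[ix])])
  if (length(inner) < nBins / 4) return(NULL)  # ring too incomplete
  py <- w[unlist(inner), 1]; px <- w[unlist(inner), 2]
  # Kasa fit: minimize ||x^2+y^2 + D x + E y + F||
  A <- cbind(px, py, 1)
  b <- -(px^2 + py^2)
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  c0 <- c(-sol[2] / 2, -sol[1] / 2)  # (y, x)
  r <- sqrt(max(0, c0[1]^2 + c0[2]^2 - sol[3]))
  list(center = c0, radius = r)
}

#' Remove the pot wall, exterior and a soil margin
#'
#' Voxels at radius >= (inner radius - \code{soilMarginMm}) from the
#' per-slice pot center are set to the background sentinel 0; interior
#' voxels are untouched.
#'
#' @param vol a \linkS4class{GrayVolume}.
#' @param pot a \linkS4class{PotModel} covering all slices.
#' @param soilMarginMm soil margin stripped inside the wall; default twice
#'   the wall thickness.
#' @return the masked \linkS4class{GrayVolume}.
#' @export
removePot <- function(vol, pot, soilMarginMm = 2 * pot@wallThicknessMm) {
  keep <- potInteriorMask(dim(vol@data), vol@voxelSizeUm, pot, soilMarginMm)
  out <- vol@data
  out[!keep] <- 0
  GrayVolume(out, voxelSizeUm = vol@voxelSizeUm)
}

#' Logical mask of the retained pot interior
#'
#' @param dims integer length-3 volume dims.
#' @param voxelSizeUm voxel size in micrometres.
#' @param pot a \linkS4class{PotModel}.
#' @param soilMarginMm margin inside the inner wall.
#' @return 3D logical array, TRUE inside the retained cylinder.
#' @export
potInteriorMask <- function(dims, voxelSizeUm, pot,
                            soilMarginMm = 2 * pot@wallThicknessMm) {
  vmm <- voxelSizeUm / 1000
  if (any(soilMarginMm >= pot@innerRadiusMm))
    stop("soil margin must be smaller than the pot inner radius")
  keep <- array(FALSE, dims)
  jg <- matrix(seq_len(dims[2]), dims[2], dims[3])
  kg <- matrix(seq_len(dims[3]), dims[2], dims[3], byrow = TRUE)
  for (z in seq_len(dims[1])) {
    cy <- pot@centerYx[z, 1]; cx <- pot@centerYx[z, 2]
    rKeep <- (pot@innerRadiusMm[z] - soilMarginMm) / vmm
    keep[z, , ] <- ((jg - cy)^2 + (kg - cx)^2) < rKeep^2
  }
  keep
}

#' Restrict a volume to an attenuation window
#'
#' Voxels with values outside \code{[aMin, aMax]} are set to the background
#' sentinel 0; in-window values are preserved (both detection branches need
#' the gray structure, so the volume is not binarized).
#'
#' @param vol a \linkS4class{GrayVolume} in attenuation units.
#' @param aMin,aMax window bounds, \code{aMin < aMax}.
#' @return the windowed \linkS4class{GrayVolume}.
#' @export
attenuationWindow <- function(vol, aMin, aMax) {
  stopifnot(is(vol, "GrayVolume"))
  if (aMin >= aMax) stop("aMin must be < aMax")
  out <- vol@data
  out[out < aMin | out > aMax] <- 0
  GrayVolume(out, voxelSizeUm = vol@voxelSizeUm)
}

#' Locate the soil-air interface and the root entry point
#'
#' For every horizontal position the first depth slice whose attenuation
#' exceeds an air/soil cut is recorded. The entry point is the centroid of
#' the topmost connected cluster of root-candidate voxels piercing the
#' surface (candidates deviate from the soil mode toward the root polarity
#' by more than \code{k} robust standard deviations).
#'
#' @param vol a \linkS4class{GrayVolume}, pot already removed.
#' @param aMin lower bound of the attenuation window (used for the default
#'   cut).
#' @param cut air/soil attenuation cut; default midpoint of \code{aMin} and
#'   the soil mode.
#' @param polarity "dark" or "bright" root polarity for entry detection.
#' @param k robust-deviation factor of the entry-candidate test.
#' @return A \linkS4class{SoilSurface}.
#' @export
detectSoilSurface <- function(vol, aMin = NULL, cut = NULL,
                              polarity = "dark", k = 2) {
  stopifnot(is(vol, "GrayVolume"))
  a <- vol@data
  pos <- a[a > 0]
  if (length(pos) < 10) stop("no soil found")
  soilMode <- densityMode(pos)
  if (is.null(cut)) {
    if (is.null(aMin)) aMin <- stats::quantile(pos, 0.001)
    cut <- (aMin + soilMode) / 2
  }
  d <- dim(a)
  m <- a >= cut
  dim(m) <- c(d[1], d[2] * d[3])
  hit <- colSums(m) > 0
  if (!any(hit)) stop("no soil found")
  top <- rep(NA_integer_, d[2] * d[3])
  top[hit] <- apply(m[, hit, drop = FALSE], 2, which.max)
  topDepth <- matrix(top, d[2], d[3])

  entry <- findEntryPoint(a, topDepth, soilMode, polarity, k)
  new("SoilSurface", topDepth = topDepth, entryPoint = entry,
      meanDepthSlices = mean(topDepth, na.rm = TRUE))
}

densityMode <- function(x) {
  dd <- stats::density(x, n = 512)
  dd$x[which.max(dd$y)]
}

findEntryPoint <- function(a, topDepth, soilMode, polarity, k) {
  d <- dim(a)
  s <- stats::mad(a[a > 0], center = soilMode)
  shell <- array(FALSE, d)
  for (j in seq_len(d[2]))
    for (kk in seq_len(d[3])) {
      t0 <- topDepth[j, kk]
      if (is.na(t0)) next
      zz <- t0:min(d[1], t0 + 2)
      shell[zz, j, kk] <- TRUE
    }
  cand <- if (polarity == "dark") {
    shell & a > 0 & a < soilMode - k * s
  } else {
    shell & a > soilMode + k * s
  }
  if (!any(cand)) return(rep(NA_real_, 3))
  lab <- array(cpp_label3d(as.vector(cand), dim(cand), 26L), dim = d)
  sizes <- tabulate(lab[lab > 0])
  # ignore tiny clusters (isolated soil texture dips); the stem crossing
  # the surface is a compact plug of root-scale cross-section
  big <- which(sizes >= max(10, stats::quantile(sizes, 0.9)))
  if (!length(big)) big <- which.max(sizes)
  meanDepth <- tapply(slice.index(lab, 1)[lab > 0], lab[lab > 0], mean)
  cand_labs <- as.integer(names(meanDepth))
  cand_labs <- cand_labs[cand_labs %in% big]
  topLab <- cand_labs[which.min(meanDepth[as.character(cand_labs)])]
  w <- which(lab == topLab, arr.ind = TRUE)
  colMeans(w)
}

#' Serialize pot and surface models for QC
#'
#' @param x a \linkS4class{PotModel} or \linkS4class{SoilSurface}.
#' @param path output JSON path.
#' @return \code{invisible(path)}.
#' @export
writeQcJson <- function(x, path) {
  obj <- if (is(x, "PotModel")) {
    list(type = "PotModel", center_yx = x@centerYx,
         inner_radius_mm = x@innerRadiusMm,
         wall_thickness_mm = x@wallThicknessMm,
         wall_attenuation_range = x@wallAttenuationRange, fitted = x@fitted)
  } else if (is(x, "SoilSurface")) {
    list(type = "SoilSurface", top_depth = x@topDepth,
         entry_point = x@entryPoint,
         mean_depth_slices = x@meanDepthSlices)
  } else stop("unsupported QC object: ", class(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
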