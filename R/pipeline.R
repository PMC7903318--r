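#' Assemble a run configuration
#'
#' Validates and bundles everything a single or batch run needs: input
#' volumes, the one shared \linkS4class{ParameterSet} (inline or preset
#' name), calibration, binning, pot detection settings and the artifacts to
#' emit.
#'
#' @param input character vector of volume paths, a directory, or a glob.
#' @param params a \linkS4class{ParameterSet} or a preset name (exactly one
#'   parameter set per run).
#' @param outDir output directory (created if missing); NULL disables
#'   artifact files.
#' @param calibration an \linkS4class{AttenuationCalibration} (identity
#'   default: the volume already holds attenuation values).
#' @param binFactor integer binning factor applied before all filtering.
#' @param potWallRange attenuation range of the pot wall for
#'   \code{\link{detectPot}}; NULL skips pot removal (e.g. already-cropped
#'   volumes).
#' @param wallThicknessMm pot wall thickness.
#' @param soilMarginMm soil margin stripped inside the wall (default twice
#'   the wall thickness).
#' @param emit artifacts to write: subset of "mask", "responses",
#'   "skeleton", "graph", "traits", "rsml".
#' @param radiusMm halo radius of the soil-around-roots density.
#' @param pruneVox spur-pruning length for the root graph; "auto" uses
#'   \code{max(dRoot)} voxels (spurs shorter than the thickest root radius
#'   are thinning artifacts).
#' @param logLevel "info" or "quiet".
#' @return a validated \code{RunConfig} list.
#' @export
runConfig <- function(input = character(0), params, outDir = NULL,
                      calibration = AttenuationCalibration(),
                      binFactor = 1L, potWallRange = NULL,
                      wallThicknessMm = 2,
                      soilMarginMm = NULL,
                      emit = c("mask", "traits", "rsml"),
                      radiusMm = 1, pruneVox = "auto",
                      logLevel = c("info", "quiet")) {
  if (is.character(params)) params <- presetParameters(params)
  stopifnot(is(params, "ParameterSet"),
            is(calibration, "AttenuationCalibration"))
  emit <- match.arg(emit, c("mask", "responses", "skeleton", "graph",
                            "traits", "rsml"), several.ok = TRUE)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  structure(list(input = input, params = params, outDir = outDir,
                 calibration = calibration,
                 binFactor = as.integer(binFactor),
                 potWallRange = potWallRange,
                 wallThicknessMm = wallThicknessMm,
                 soilMarginMm = soilMarginMm, emit = emit,
                 radiusMm = radiusMm, pruneVox = pruneVox,
                 logLevel = match.arg(logLevel)),
            class = "RunConfig")
}

pipeLog <- function(config, ...) {
  if (identical(config$logLevel, "info"))
    message(sprintf("[rootCT] %s", sprintf(...)))
}

#' Segment one volume with a parameter set
#'
#' The core fixed-order pipeline: calibration, optional pot removal,
#' attenuation windowing, the two parallel detection branches (multiscale
#' vesselness for fine roots on the windowed attenuation volume; local 3D
#' variance on the windowed gray-value volume), threshold fusion, optional
#' median filter and the minimum-volume component filter.
#'
#' @param vol a \linkS4class{GrayVolume} in gray values (or attenuation
#'   units with the identity calibration).
#' @param params a \linkS4class{ParameterSet}.
#' @param calibration an \linkS4class{AttenuationCalibration}.
#' @param potWallRange,wallThicknessMm,soilMarginMm pot removal settings
#'   (NULL range skips pot removal).
#' @return list with \code{mask} (\linkS4class{RootMask}), \code{windowed},
#'   \code{vesselness}, \code{variance}, \code{surface}, \code{interior},
#'   \code{pot}, \code{atten}.
#' @export
segmentVolume <- function(vol, params,
                          calibration = AttenuationCalibration(),
                          potWallRange = NULL, wallThicknessMm = 2,
                          soilMarginMm = NULL) {
  stopifnot(is(vol, "GrayVolume"), is(params, "ParameterSet"))
  atten <- grayToAttenuation(vol, calibration)
  pot <- NULL
  interior <- array(TRUE, dim(atten@data))
  if (!is.null(potWallRange)) {
    pot <- detectPot(atten, potWallRange, wallThicknessMm)
    margin <- soilMarginMm %||% (2 * wallThicknessMm)
    atten <- removePot(atten, pot, margin)
    interior <- potInteriorMask(dim(atten@data), atten@voxelSizeUm, pot,
                                margin)
  }
  windowed <- attenuationWindow(atten, params@aMin, params@aMax)
  surface <- detectSoilSurface(windowed, aMin = params@aMin,
                               polarity = params@polarity)
  vess <- frangiVesselness(windowed, params@dRoot,
                           c = if (is.na(params@frangiC)) NULL else
                             params@frangiC,
                           polarity = params@polarity,
                           responseScale = params@responseScale)
  lam <- if (is.na(params@varianceScale)) max(params@dRoot) else
    params@varianceScale
  windowedGray <- attenuationToGray(windowed, calibration)
  windowedGray@data[windowed@data == 0] <- 0
  varr <- localVariance(windowedGray, lam, maskedZeros = TRUE)
  dil <- params@varianceDilateVox
  if (is.na(dil)) dil <- ceiling(1.5 * lam)
  mask <- mergeResponses(vess, varr, windowed, params@theta1, params@theta2,
                         maxDiameterVox = max(params@dRoot),
                         thicknessTest = params@thicknessTest,
                         connectivity = params@connectivity,
                         dilateVox = dil,
                         provenance = parameterHash(params))
  if (params@medianKernel > 1L)
    mask <- medianFilterMask(mask, params@medianKernel)
  mask <- sizeFilter(mask, params@vMinMm3, params@connectivity)
  list(mask = mask, windowed = windowed, vesselness = vess,
       variance = varr, surface = surface, interior = interior, pot = pot,
       atten = atten)
}

#' Run the full pipeline on one volume
#'
#' Executes segmentation, skeletonization, root-graph construction, trait
#' extraction and RSML export, writing the requested artifacts to the
#' output directory (mask volume, one-row traits CSV, RSML, a JSON log of
#' parameters and stage timings).
#'
#' @param config a \code{RunConfig} from \code{\link{runConfig}}.
#' @param volumePath path of the input volume (any format of
#'   \code{\link{readVolume}}); alternatively pass \code{volume}.
#' @param volume optional \linkS4class{GrayVolume} (overrides
#'   \code{volumePath}).
#' @return list with \code{traits} (\linkS4class{TraitReport}),
#'   \code{mask}, \code{graph}, \code{surface}, \code{timings} and
#'   \code{files} (paths written).
#' @export
runSingle <- function(config, volumePath = NULL, volume = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  name <- if (!is.null(volumePath)) basename(volumePath) else "volume"
  vol <- if (!is.null(volume)) volume else readVolume(volumePath)
  tick("read")
  if (config$binFactor > 1L) {
    vol <- binVolume(vol, config$binFactor)
    tick("bin")
  }
  seg <- segmentVolume(vol, config$params, config$calibration,
                       config$potWallRange, config$wallThicknessMm,
                       config$soilMarginMm)
  tick("segment")
  if (!any(seg$mask@data)) stop("segmentation produced an empty mask")
  skel <- skeletonize(seg$mask)
  tick("skeletonize")
  entry <- snapEntry(skel, seg$surface)
  pv <- if (identical(config$pruneVox, "auto")) max(config$params@dRoot)
        else config$pruneVox
  graph <- buildRootGraph(skel, entry, pruneVox = pv)
  tick("graph")
  gray <- if (config$binFactor > 1L) vol else vol
  traits <- computeTraits(seg$mask, graph, seg$surface, gray = gray,
                          atten = seg$atten, interior = seg$interior,
                          radiusMm = config$radiusMm)
  tick("traits")

  files <- character(0)
  if (!is.null(config$outDir)) {
    base <- file.path(config$outDir, tools::file_path_sans_ext(name))
    if ("mask" %in% config$emit) {
      writeVolume(GrayVolume(array(as.numeric(seg$mask@data),
                                   dim(seg$mask@data)),
                             seg$mask@voxelSizeUm),
                  paste0(base, "_mask.mhd"), dtype = "uint8")
      files <- c(files, paste0(base, "_mask.mhd"))
    }
    if ("responses" %in% config$emit) {
      writeVolume(seg$vesselness, paste0(base, "_vesselness.mhd"),
                  dtype = "float32")
      writeVolume(seg$variance, paste0(base, "_variance.mhd"),
                  dtype = "float32")
      files <- c(files, paste0(base, "_vesselness.mhd"),
                 paste0(base, "_variance.mhd"))
    }
    if ("traits" %in% config$emit) {
      writeTraitsCsv(traits, paste0(base, "_traits.csv"), name,
                     seg$mask@provenance)
      files <- c(files, paste0(base, "_traits.csv"))
    }
    if ("rsml" %in% config$emit) {
      exportRSML(graph, paste0(base, ".rsml"), report = traits)
      files <- c(files, paste0(base, ".rsml"))
    }
    log <- list(input = name, parameters = paramList(config$params),
                parameter_hash = seg$mask@provenance,
                stage_seconds = as.list(timings))
    jsonlite::write_json(log, paste0(base, "_log.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, paste0(base, "_log.json"))
  }
  pipeLog(config, "%s: V_root=%.2f mm^3, L_root=%.2f mm, %d tips", name,
          traits@values$vRootMm3, traits@values$lRootMm,
          traits@values$nTips)
  list(traits = traits, mask = seg$mask, graph = graph,
       surface = seg$surface, timings = timings, files = files)
}

snapEntry <- function(skel, surface) {
  ep <- surface@entryPoint
  if (anyNA(ep)) {
    # fall back to the topmost skeleton voxel (smallest depth, then
    # lexicographic)
    o <- order(skel@voxels[, 1], skel@voxels[, 2], skel@voxels[, 3])
    return(skel@voxels[o[1], ])
  }
  d2 <- (skel@voxels[, 1] - ep[1])^2 + (skel@voxels[, 2] - ep[2])^2 +
    (skel@voxels[, 3] - ep[3])^2
  cand <- which(d2 == min(d2))
  if (length(cand) > 1) {
    v <- skel@voxels[cand, , drop = FALSE]
    cand <- cand[order(v[, 1], v[, 2], v[, 3])][1]
  }
  skel@voxels[cand, ]
}

paramList <- function(params) {
  slots <- lapply(slotNames(params), function(s) slot(params, s))
  names(slots) <- slotNames(params)
  slots
}

writeTraitsCsv <- function(traits, path, inputName, hash,
                           append = FALSE) {
  row <- cbind(data.frame(input = inputName, parameter_hash = hash,
                          stringsAsFactors = FALSE),
               as.data.frame(traits))
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
}

#' Run the pipeline on a batch of volumes
#'
#' Every volume is processed with the one shared parameter set; per-volume
#' failures are logged and skipped. The aggregate CSV is sorted by file
#' name and carries the parameter hash in every row.
#'
#' @param config a \code{RunConfig}; \code{config$input} may contain paths,
#'   directories or globs.
#' @return data.frame of trait rows (invisibly); written to
#'   \code{batch_traits.csv} in the output directory if one is set.
#' @export
runBatch <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  paths <- expandInputs(config$input)
  if (!length(paths)) stop("no volumes matched the input specification")
  paths <- paths[order(basename(paths))]
  rows <- list()
  failures <- character(0)
  for (p in paths) {
    res <- tryCatch(runSingle(config, volumePath = p),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", basename(p),
                                      conditionMessage(res)))
      pipeLog(config, "FAILED %s: %s", basename(p), conditionMessage(res))
      next
    }
    rows[[basename(p)]] <- cbind(
      data.frame(input = basename(p),
                 parameter_hash = res$mask@provenance,
                 stringsAsFactors = FALSE),
      as.data.frame(res$traits))
  }
  if (!length(rows)) stop("all volumes failed: ",
                          paste(failures, collapse = "; "))
  out <- do.call(rbind, rows[order(names(rows))])
  rownames(out) <- NULL
  if (!is.null(config$outDir)) {
    utils::write.table(out, file.path(config$outDir, "batch_traits.csv"),
                       sep = ",", row.names = FALSE)
    if (length(failures))
      writeLines(failures, file.path(config$outDir, "batch_failures.log"))
  }
  invisible(out)
}

expandInputs <- function(input) {
  out <- character(0)
  for (item in input) {
    if (dir.exists(item)) {
      out <- c(out, list.files(item, pattern =
        "\\.(mhd|json|tif|tiff)$", full.names = TRUE))
    } else if (file.exists(item)) {
      out <- c(out, item)
    } else {
      out <- c(out, Sys.glob(item))
    }
  }
  # raw volumes are addressed by their .json sidecar; drop tiff sidecars
  out <- out[!grepl("\\.(tif|tiff)\\.json$", out)]
  unique(out)
}
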