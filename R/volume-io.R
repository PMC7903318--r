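#' Read a 3D volume from disk
#'
#' Supported formats: raw binary with a JSON sidecar (\code{dims},
#' \code{dtype}, \code{byte_order}, \code{voxel_size_um}), MetaImage
#' (\code{.mhd} header + raw data file) and multi-page TIFF stacks (voxel
#' size from a JSON sidecar or the \code{voxelSizeUm} argument). Arrays are
#' stored \code{[depth, y, x]} with one TIFF page / one contiguous raw slab
#' per depth slice.
#'
#' @param path file path (\code{.json}/\code{.raw}, \code{.mhd} or
#'   \code{.tif}/\code{.tiff}).
#' @param format "auto" (by extension), "raw", "mhd" or "tiff".
#' @param voxelSizeUm voxel size override, required for TIFF stacks without
#'   a sidecar.
#' @return A \linkS4class{GrayVolume}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, format = c("auto", "raw", "mhd", "tiff"),
                       voxelSizeUm = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
         raw = readRawVolume(path),
         mhd = readMhdVolume(path),
         tiff = readTiffVolume(path, voxelSizeUm))
}

#' Write a 3D volume to disk
#'
#' Integer volumes round-trip bit-exactly through every format; floating
#' point data round-trips through raw (float64) and MHD (float32/float64).
#' TIFF output is 16-bit and requires integer data in [0, 65535].
#'
#' @param vol a \linkS4class{GrayVolume}.
#' @param path output path (extension selects the sidecar/data file names).
#' @param format "auto", "raw", "mhd" or "tiff".
#' @param dtype storage type: "uint8", "uint16", "float32" or "float64"
#'   ("auto" picks uint16 for integer data in range, float64 otherwise).
#' @return \code{invisible(path)}.
#' @export
writeVolume <- function(vol, path, format = c("auto", "raw", "mhd", "tiff"),
                        dtype = "auto") {
  stopifnot(is(vol, "GrayVolume"))
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ",
                             dir)
  if (dtype == "auto") {
    d <- vol@data
    intLike <- all(d == round(d)) && min(d) >= 0 && max(d) <= 65535
    dtype <- if (intLike) "uint16" else "float64"
  }
  switch(format,
         raw = writeRawVolume(vol, path, dtype),
         mhd = writeMhdVolume(vol, path, dtype),
         tiff = writeTiffVolume(vol, path))
  invisible(path)
}

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = "raw", raw = "raw", mhd = "mhd",
         tif = "tiff", tiff = "tiff",
         stop("cannot guess volume format from extension '", ext, "'"))
}

dtypeInfo <- function(dtype) {
  switch(dtype,
         uint8 = list(what = "integer", size = 1L, signed = FALSE),
         uint16 = list(what = "integer", size = 2L, signed = FALSE),
         float32 = list(what = "numeric", size = 4L, signed = TRUE),
         float64 = list(what = "numeric", size = 8L, signed = TRUE),
         stop("unsupported dtype: ", dtype))
}

# --- raw + JSON sidecar ----------------------------------------------------

sidecarPath <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") path
  else paste0(tools::file_path_sans_ext(path), ".json")
}

readRawVolume <- function(path) {
  meta_path <- sidecarPath(path)
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("dims", "dtype", "voxel_size_um"))
    if (is.null(meta[[key]]))
      stop("metadata is missing required key '", key, "'")
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L) stop("metadata key 'dims' must have length 3")
  data_file <- meta$data_file %||%
    paste0(basename(tools::file_path_sans_ext(meta_path)), ".raw")
  raw_path <- file.path(dirname(meta_path), data_file)
  if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path)
  info <- dtypeInfo(meta$dtype)
  endian <- if (identical(meta$byte_order, "big")) "big" else "little"
  n <- prod(dims)
  expect_bytes <- n * info$size
  if (file.size(raw_path) != expect_bytes)
    stop(sprintf(
      "raw file size mismatch: %d bytes on disk, %d expected for dims %s (%s)",
      file.size(raw_path), expect_bytes, paste(dims, collapse = "x"),
      meta$dtype))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = info$what, n = n, size = info$size,
                  signed = info$signed, endian = endian)
  GrayVolume(array(as.numeric(vals), dim = dims),
             voxelSizeUm = meta$voxel_size_um)
}

writeRawVolume <- function(vol, path, dtype) {
  meta_path <- sidecarPath(path)
  raw_path <- paste0(tools::file_path_sans_ext(meta_path), ".raw")
  info <- dtypeInfo(dtype)
  meta <- list(dims = dim(vol@data), dtype = dtype, byte_order = "little",
               voxel_size_um = vol@voxelSizeUm,
               data_file = basename(raw_path))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  vals <- as.vector(vol@data)
  if (info$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = info$size, endian = "little")
}

# --- MetaImage (.mhd + .raw) ----------------------------------------------

metTypes <- c(uint8 = "MET_UCHAR", uint16 = "MET_USHORT",
              float32 = "MET_FLOAT", float64 = "MET_DOUBLE")

readMhdVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  for (key in c("DimSize", "ElementType", "ElementSpacing",
                "ElementDataFile"))
    if (is.null(kv[[key]])) stop("MHD header missing key '", key, "'")
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("DimSize must have 3 entries")
  spacing <- as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
  dtype <- names(metTypes)[match(kv$ElementType, metTypes)]
  if (is.na(dtype)) stop("unsupported ElementType: ", kv$ElementType)
  info <- dtypeInfo(dtype)
  endian <- if (identical(toupper(kv$BinaryDataByteOrderMSB %||% "FALSE"),
                          "TRUE")) "big" else "little"
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  if (!file.exists(raw_path)) stop("MHD data file not found: ", raw_path)
  n <- prod(dims)
  if (file.size(raw_path) != n * info$size)
    stop("MHD data size mismatch with DimSize")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = info$what, n = n, size = info$size,
                  signed = info$signed, endian = endian)
  # MHD stores x,y,z fastest-first; our layout is depth-fastest, so DimSize
  # is written/read in array order directly (documented symmetric choice).
  GrayVolume(array(as.numeric(vals), dim = dims),
             voxelSizeUm = spacing[1] * 1000)
}

writeMhdVolume <- function(vol, path, dtype) {
  if (dtype == "auto") dtype <- "float32"
  raw_path <- paste0(tools::file_path_sans_ext(path), ".raw")
  sp <- vol@voxelSizeUm / 1000
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           paste("DimSize =", paste(dim(vol@data), collapse = " ")),
           paste("ElementType =", metTypes[[dtype]]),
           paste("ElementSpacing =", paste(rep(format(sp, digits = 17), 3),
                                           collapse = " ")),
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  info <- dtypeInfo(dtype)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  vals <- as.vector(vol@data)
  if (info$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = info$size, endian = "little")
}

# --- TIFF stacks -----------------------------------------------------------

readTiffVolume <- function(path, voxelSizeUm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  if (is.null(voxelSizeUm)) {
    sc <- paste0(path, ".json")
    if (!file.exists(sc))
      stop("missing metadata: provide voxelSizeUm or a sidecar ", sc)
    voxelSizeUm <- jsonlite::read_json(sc)$voxel_size_um
    if (is.null(voxelSizeUm))
      stop("metadata is missing required key 'voxel_size_um'")
  }
  GrayVolume(arr, voxelSizeUm = voxelSizeUm)
}

writeTiffVolume <- function(vol, path) {
  d <- vol@data
  if (any(d != round(d)) || min(d) < 0 || max(d) > 65535)
    stop("TIFF output requires integer data in [0, 65535]; use mhd or raw")
  pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size_um = vol@voxelSizeUm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

# --- binning and calibration ----------------------------------------------

#' Bin a volume by block averaging
#'
#' Each output voxel is the mean of a \code{factor^3} block; trailing partial
#' blocks are dropped so voxels stay cubic. The voxel size grows by
#' \code{factor} (87.7 um binned 2x becomes 175.4 um).
#'
#' @param vol a \linkS4class{GrayVolume}.
#' @param factor positive integer block edge.
#' @return the binned \linkS4class{GrayVolume}.
#' @examples
#' v <- GrayVolume(array(runif(8^3), c(8, 8, 8)), 87.7)
#' voxelSize(binVolume(v, 2))  # 175.4
#' @export
binVolume <- function(vol, factor) {
  stopifnot(is(vol, "GrayVolume"))
  if (length(factor) != 1 || factor != round(factor) || factor <= 0)
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol@data)
  out_d <- d %/% factor
  if (any(out_d < 1L)) stop("volume smaller than one block")
  a <- vol@data[seq_len(out_d[1] * factor), seq_len(out_d[2] * factor),
                seq_len(out_d[3] * factor), drop = FALSE]
  a <- poolAxis1(a, factor)
  a <- aperm(poolAxis1(aperm(a, c(2, 1, 3)), factor), c(2, 1, 3))
  a <- aperm(poolAxis1(aperm(a, c(3, 2, 1)), factor), c(3, 2, 1))
  GrayVolume(a, voxelSizeUm = vol@voxelSizeUm * factor)
}

poolAxis1 <- function(a, f) {
  d <- dim(a)
  dim(a) <- c(f, prod(d) / f)
  out <- colMeans(a)
  dim(out) <- c(d[1] / f, d[2], d[3])
  out
}

#' Convert gray values to attenuation coefficients
#'
#' Elementwise affine normalization \eqn{A = slope \cdot g + intercept}
#' between detector gray values and the attenuation scale on which the
#' windowing parameters (\code{aMin}, \code{aMax}) are stated.
#'
#' @param vol a \linkS4class{GrayVolume} in gray values.
#' @param cal an \linkS4class{AttenuationCalibration}.
#' @return a \linkS4class{GrayVolume} in attenuation units.
#' @export
grayToAttenuation <- function(vol, cal = AttenuationCalibration()) {
  stopifnot(is(vol, "GrayVolume"), is(cal, "AttenuationCalibration"))
  GrayVolume(cal@slope * vol@data + cal@intercept,
             voxelSizeUm = vol@voxelSizeUm)
}

#' Invert an attenuation calibration
#'
#' @param vol a \linkS4class{GrayVolume} in attenuation units.
#' @param cal the \linkS4class{AttenuationCalibration} used for the forward
#'   map.
#' @return a \linkS4class{GrayVolume} in gray values.
#' @export
attenuationToGray <- function(vol, cal) {
  stopifnot(is(vol, "GrayVolume"), is(cal, "AttenuationCalibration"))
  GrayVolume((vol@data - cal@intercept) / cal@slope,
             voxelSizeUm = vol@voxelSizeUm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
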