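#' Sampled, normalized 1D Gaussian kernel
#'
#' @param sigma standard deviation in voxels.
#' @param radius kernel half width; default \code{ceiling(4 * sigma)}.
#' @return numeric kernel summing to 1.
#' @keywords internal
gaussianKernel <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Separable 3D Gaussian filter
#'
#' Correlation with a sampled normalized Gaussian along each axis;
#' half-sample symmetric reflection at the borders.
#'
#' @param arr 3D numeric array.
#' @param sigma standard deviation in voxels (scalar).
#' @return filtered array of the same dimensions.
#' @export
gaussianFilter3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3, sigma > 0)
  k <- gaussianKernel(sigma)
  d <- dim(arr)
  v <- as.vector(arr)
  for (axis in 0:2) v <- cpp_filter_axis(v, d, k, axis)
  array(v, dim = d)
}

#' HessianEigenvalues: per-voxel eigenvalues of the scale-space Hessian
#'
#' @slot lambda1,lambda2,lambda3 3D arrays of eigenvalues sorted by
#'   ascending magnitude |lambda1| <= |lambda2| <= |lambda3|.
#' @slot sigma the Gaussian scale in voxels.
#' @export
setClass("HessianEigenvalues",
  representation(lambda1 = "array", lambda2 = "array", lambda3 = "array",
                 sigma = "numeric"))

#' Eigenvalues of the Gaussian scale-space Hessian
#'
#' The volume is smoothed with a Gaussian of standard deviation
#' \code{sigma}, second derivatives are taken by central finite differences,
#' and the result is gamma-normalized by \code{sigma^2} so responses are
#' comparable across scales. Per-voxel eigenvalues of the symmetric 3x3
#' Hessian are sorted by ascending magnitude: a bright tubular structure has
#' \code{lambda1 ~ 0} and \code{lambda2 ~ lambda3 << 0} on its axis.
#'
#' @param vol a \linkS4class{GrayVolume} (or 3D array).
#' @param sigma Gaussian scale in voxels, > 0.
#' @return A \linkS4class{HessianEigenvalues}.
#' @export
hessianEigenvalues <- function(vol, sigma) {
  arr <- if (is(vol, "GrayVolume")) vol@data else vol
  stopifnot(sigma > 0)
  H <- hessianComponents(arr, sigma)
  d <- dim(arr)
  e <- cpp_eig3_sym(H$h11, H$h22, H$h33, H$h12, H$h13, H$h23)
  new("HessianEigenvalues",
      lambda1 = array(e[, 1], d), lambda2 = array(e[, 2], d),
      lambda3 = array(e[, 3], d), sigma = sigma)
}

# gamma-normalized Hessian components as flat vectors
hessianComponents <- function(arr, sigma) {
  d <- dim(arr)
  s <- as.vector(gaussianFilter3d(arr, sigma))
  d2 <- c(1, -2, 1)
  d1 <- c(-0.5, 0, 0.5)
  g <- sigma^2
  list(h11 = g * cpp_filter_axis(s, d, d2, 0L),
       h22 = g * cpp_filter_axis(s, d, d2, 1L),
       h33 = g * cpp_filter_axis(s, d, d2, 2L),
       h12 = g * cpp_filter_axis(cpp_filter_axis(s, d, d1, 0L), d, d1, 1L),
       h13 = g * cpp_filter_axis(cpp_filter_axis(s, d, d1, 0L), d, d1, 2L),
       h23 = g * cpp_filter_axis(cpp_filter_axis(s, d, d1, 1L), d, d1, 2L))
}

#' Multiscale vesselness filter for fine tubular roots
#'
#' Computes the Hessian-eigenvalue vesselness measure at one scale per
#' target root diameter (\code{sigma = D/2}, radius matching) and takes the
#' voxelwise maximum over scales. The measure combines a plate/line
#' discriminator \eqn{R_A = |\lambda_2|/|\lambda_3|}, a blob discriminator
#' \eqn{R_B = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}} and the
#' second-order structure norm
#' \eqn{S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}:
#' \deqn{v = (1 - e^{-R_A^2/2\alpha^2}) e^{-R_B^2/2\beta^2}
#'           (1 - e^{-S^2/2c^2})}
#' and is zero where the eigenvalue signs violate the tube condition for the
#' chosen polarity (\code{lambda2, lambda3 < 0} for bright tubes, mirrored
#' for dark ones). Background-sentinel voxels (value 0) get response 0.
#'
#' @param vol a \linkS4class{GrayVolume}, typically the attenuation-windowed
#'   volume (background sentinel 0).
#' @param dRoot numeric vector of root diameters in voxels.
#' @param alpha,beta vesselness exponents (defaults 0.5).
#' @param c structure-norm exponent; default half the maximum \eqn{S} over
#'   the volume at each scale.
#' @param polarity "dark" (roots attenuate less than soil) or "bright".
#' @param responseScale multiplier mapping the native [0, 1] response to the
#'   gray-value scale on which \code{theta1} is stated (default 1; the
#'   pipeline uses 65535).
#' @return a \linkS4class{ResponseVolume} with \code{branch = "vesselness"}.
#' @export
frangiVesselness <- function(vol, dRoot, alpha = 0.5, beta = 0.5, c = NULL,
                             polarity = c("dark", "bright"),
                             responseScale = 1) {
  stopifnot(is(vol, "GrayVolume"))
  if (length(dRoot) < 1) stop("dRoot must be non-empty")
  if (any(dRoot <= 0)) stop("dRoot diameters must be > 0")
  polarity <- match.arg(polarity)
  arr <- vol@data
  d <- dim(arr)
  sigmas <- dRoot / 2
  # one pass per scale for the eigenvalues; the structure-norm constant c
  # must be shared across scales, otherwise the gamma-normalized magnitude
  # term cannot select the matching scale
  eigs <- vector("list", length(sigmas))
  for (s in seq_along(sigmas)) {
    H <- hessianComponents(arr, sigmas[s])
    eigs[[s]] <- cpp_eig3_sym(H$h11, H$h22, H$h33, H$h12, H$h13, H$h23)
  }
  S2max <- max(vapply(eigs, function(e)
    max(e[, 1]^2 + e[, 2]^2 + e[, 3]^2), 1.0))
  cc <- if (is.null(c)) 0.5 * sqrt(S2max) else c
  best <- numeric(length(arr))
  if (cc > 0) {
    for (s in seq_along(sigmas)) {
      e <- eigs[[s]]
      l1 <- e[, 1]; l2 <- e[, 2]; l3 <- e[, 3]
      ok <- if (polarity == "bright") (l2 < 0 & l3 < 0) else
        (l2 > 0 & l3 > 0)
      a2 <- abs(l2); a3 <- abs(l3)
      S2 <- l1^2 + l2^2 + l3^2
      RA2 <- (a2 / pmax(a3, .Machine$double.xmin))^2
      RB2 <- l1^2 / pmax(a2 * a3, .Machine$double.xmin)
      v <- (1 - exp(-RA2 / (2 * alpha^2))) * exp(-RB2 / (2 * beta^2)) *
        (1 - exp(-S2 / (2 * cc^2)))
      v[!ok] <- 0
      best <- pmax(best, v)
    }
  }
  best[as.vector(arr) == 0] <- 0
  new("ResponseVolume", data = array(best * responseScale, d),
      voxelSizeUm = vol@voxelSizeUm, branch = "vesselness",
      scales = sigmas)
}

#' Local 3D variance (homogeneity) filter for storage roots
#'
#' Gaussian-weighted local variance
#' \deqn{V_{local} = G_\lambda * I^2 - (G_\lambda * I)^2,}
#' clipped at zero to absorb negative floating-point residue. Thick storage
#' roots are nearly homogeneous inside, so their local variance is low
#' compared to textured soil; the segmentation treats \code{theta2} as an
#' upper bound on this response. Background-sentinel voxels get response 0.
#'
#' @param vol a \linkS4class{GrayVolume}.
#' @param lambdaScale Gaussian scale in voxels, > 0.
#' @param maskedZeros if TRUE, background-sentinel voxels (value 0) are
#'   excluded from the weighted statistics (weights renormalized over
#'   in-window voxels). This keeps the homogeneity response low on the rim
#'   of a storage root whose surrounding soil was clipped by the
#'   attenuation window, instead of reporting the artificial root-to-zero
#'   contrast. Voxels whose neighbourhood holds less than
#'   \code{minSupport} in-window weight get a prohibitively large response.
#' @param minSupport minimal in-window weight fraction for
#'   \code{maskedZeros}.
#' @return a \linkS4class{ResponseVolume} with \code{branch = "variance"}.
#' @export
localVariance <- function(vol, lambdaScale, maskedZeros = FALSE,
                          minSupport = 0.3) {
  stopifnot(is(vol, "GrayVolume"))
  if (lambdaScale <= 0) stop("lambdaScale must be > 0")
  arr <- vol@data
  if (maskedZeros) {
    m0 <- gaussianFilter3d(array(as.numeric(arr != 0), dim(arr)),
                           lambdaScale)
    m1 <- gaussianFilter3d(arr, lambdaScale)
    m2 <- gaussianFilter3d(arr^2, lambdaScale)
    v <- array(1e30, dim(arr))
    ok <- m0 >= minSupport
    v[ok] <- pmax(m2[ok] / m0[ok] - (m1[ok] / m0[ok])^2, 0)
  } else {
    m1 <- gaussianFilter3d(arr, lambdaScale)
    m2 <- gaussianFilter3d(arr^2, lambdaScale)
    v <- pmax(m2 - m1^2, 0)
  }
  v[arr == 0] <- 0
  new("ResponseVolume", data = v, voxelSizeUm = vol@voxelSizeUm,
      branch = "variance", scales = lambdaScale)
}
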