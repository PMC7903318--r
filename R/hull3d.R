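# Incremental 3D convex hull (quickhull-style point insertion with horizon
# re-triangulation). Written for the moderate point counts that remain after
# the per-slice 2D-hull reduction of a voxel mask.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convex hull of a 3D point set
#'
#' @param pts numeric matrix (n x 3).
#' @return list with \code{vertices} (input points), \code{faces} (m x 3
#'   index matrix, outward counterclockwise), \code{normals} (unit, outward),
#'   \code{offsets}, \code{areas} and \code{volume}.
#' @export
convexHull3d <- function(pts) {
  pts <- unique(round(pts, 12))
  n <- nrow(pts)
  if (n < 4)
    stop("degenerate point set: need at least 4 non-coplanar points ",
         "(a flat or linear mask has no 3D hull)")
  scale <- max(apply(pts, 2, function(x) diff(range(x))))
  if (scale <= 0) stop("degenerate point set: all points coincide")
  eps <- 1e-9 * scale

  # initial tetrahedron from extremes
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  ab <- pts[i2, ] - pts[i1, ]
  cr <- t(apply(sweep(pts, 2, pts[i1, ]), 1, function(v) cross3(ab, v)))
  i3 <- which.max(rowSums(cr^2))
  nrm <- cross3(ab, pts[i3, ] - pts[i1, ])
  h <- abs(sweep(pts, 2, pts[i1, ]) %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= eps)
    stop("degenerate point set: points are coplanar; form fraction and ",
         "hull angles are undefined for flat masks")
  O <- colMeans(pts[c(i1, i2, i3, i4), ])

  mkFace <- function(a, b, c) {
    nv <- cross3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    if (sum(nv * (O - pts[a, ])) > 0) { tmp <- b; b <- c; c <- tmp; nv <- -nv }
    len <- sqrt(sum(nv^2))
    list(v = c(a, b, c), n = nv / len, d = sum(nv / len * pts[a, ]))
  }
  faces <- list(mkFace(i1, i2, i3), mkFace(i1, i2, i4),
                mkFace(i1, i3, i4), mkFace(i2, i3, i4))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    N <- t(vapply(faces, `[[`, numeric(3), "n"))
    D <- vapply(faces, `[[`, 1.0, "d")
    vis <- which(as.vector(N %*% pts[p, ]) - D > eps)
    if (!length(vis)) next
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(faces[vis], function(f)
      rbind(f$v[c(1, 2)], f$v[c(2, 3)], f$v[c(3, 1)])))
    keyF <- paste(edges[, 1], edges[, 2])
    keyR <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(keyF %in% keyR), , drop = FALSE]
    faces <- faces[-vis]
    for (r in seq_len(nrow(horizon)))
      faces[[length(faces) + 1]] <- mkFace(horizon[r, 1], horizon[r, 2], p)
  }

  fv <- t(vapply(faces, `[[`, numeric(3), "v"))
  N <- t(vapply(faces, `[[`, numeric(3), "n"))
  D <- vapply(faces, `[[`, 1.0, "d")
  areas <- vapply(faces, function(f) {
    0.5 * sqrt(sum(cross3(pts[f$v[2], ] - pts[f$v[1], ],
                          pts[f$v[3], ] - pts[f$v[1], ])^2))
  }, 1.0)
  vol <- sum(vapply(faces, function(f) {
    a <- pts[f$v[1], ] - O; b <- pts[f$v[2], ] - O; cc <- pts[f$v[3], ] - O
    sum(a * cross3(b, cc)) / 6
  }, 1.0))
  list(vertices = pts, faces = fv, normals = N, offsets = D, areas = areas,
       volume = vol)
}

# Candidate hull points of a mask in mm: per-slice 2D hull of voxel centers,
# expanded to the 8 voxel corners so the hull volume bounds the voxel union
# from above (a solid cube then has form fraction exactly 100%).
maskHullPoints <- function(mask, below = NULL) {
  arr <- mask@data
  if (!is.null(below)) arr <- arr & below
  vox <- which(arr, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("no root voxels below the soil surface")
  cand <- do.call(rbind, lapply(split.data.frame(vox, vox[, 1]), function(s) {
    if (nrow(s) <= 3) return(s)
    s[grDevices::chull(s[, 2], s[, 3]), , drop = FALSE]
  }))
  off <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  corners <- do.call(rbind, lapply(seq_len(8), function(t)
    sweep(cand - 0.5, 2, off[t, ], "+")))
  unique(corners) * (mask@voxelSizeUm / 1000)
}
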