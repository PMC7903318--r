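cpp_neighbor_count26_test <- function(arr) {
  out <- array(rootCT:::cpp_neighbor_count26(as.vector(arr), dim(arr)),
               dim(arr))
  out[arr]
}

test_that("a solid cylinder thins to a single centred chain", {
  d <- c(56, 15, 15)
  arr <- solidCylinder(d, center = c(8, 8), radius = 3, from = 4, to = 53)
  sk <- skeletonize(RootMask(arr, 100))
  # single 26-connected chain of ~50 voxels along the axis (+-2 at ends)
  expect_gte(nrow(sk@voxels), 46)
  expect_lte(nrow(sk@voxels), 52)
  expect_true(all(sk@voxels[, 2] == 8))
  expect_true(all(sk@voxels[, 3] == 8))
  nc <- cpp_neighbor_count26_test(skeletonMask(sk))
  expect_equal(sum(nc == 1), 2)            # two endpoints
  expect_true(all(nc[nc > 0] <= 2))        # no junctions
  # idempotence
  sk2 <- skeletonize(RootMask(skeletonMask(sk), 100))
  expect_identical(skeletonMask(sk2), skeletonMask(sk))
})

test_that("a single voxel is its own skeleton; empty masks error", {
  arr <- array(FALSE, c(5, 5, 5))
  arr[3, 3, 3] <- TRUE
  sk <- skeletonize(RootMask(arr, 100))
  expect_equal(nrow(sk@voxels), 1)
  expect_equal(as.vector(sk@voxels[1, ]), c(3, 3, 3))
  expect_error(skeletonize(RootMask(array(FALSE, c(4, 4, 4)), 100)),
               "empty")
})

test_that("a Y-shaped tube yields one junction and three endpoints", {
  d <- c(60, 40, 40)
  segs <- list(list(c(5, 20, 20), c(30, 20, 20)),
               list(c(30, 20, 20), c(55, 10, 20)),
               list(c(30, 20, 20), c(55, 30, 20)))
  arr <- paintSegments(d, segs, 2.5)
  sk <- skeletonize(RootMask(arr, 100))
  g <- buildRootGraph(sk, c(5, 20, 20), pruneVox = 6)
  expect_equal(countTips(g), 2)
  expect_equal(length(g@edges), 3)
  expect_equal(sum(g@nodes$type == "branch"), 1)
  expect_equal(g@extraComponents, 0)
  expect_error(buildRootGraph(sk, c(5, 2, 2)), "entry not near")
})

test_that("straight chains give one edge and one tip", {
  d <- c(30, 9, 9)
  chain <- paintChain(d, rbind(c(3, 5, 5), c(27, 5, 5)))
  sk <- skeletonize(RootMask(chain, 100))
  g <- buildRootGraph(sk, c(3, 5, 5))
  expect_equal(length(g@edges), 1)
  expect_equal(countTips(g), 1)
  expect_equal(graphLength(g), 25 * 0.1)      # 25 voxels at 100 um
})

test_that("voxel-count and Euclidean length conventions differ as expected", {
  # fully diagonal chain in one plane: Euclidean = voxel-count * sqrt(2)
  d <- c(30, 30, 9)
  pts <- cbind(3:27, 3:27, rep(5, 25))
  arr <- array(FALSE, d)
  arr[pts] <- TRUE
  sk <- skeletonize(RootMask(arr, 100))
  g <- buildRootGraph(sk, c(3, 3, 5))
  lv <- graphLength(g, "voxel")
  le <- graphLength(g, "euclidean")
  expect_equal(lv, 25 * 0.1)
  expect_equal(le, 24 * 0.1 * sqrt(2), tolerance = 1e-8)
})

test_that("an 8-leaf binary tree maps to 8 tips and 15 edges", {
  # constructed voxel-chain tree of depth 3
  d <- c(64, 64, 64)
  arr <- array(FALSE, d)
  paths <- list(rbind(c(4, 32, 32), c(12, 32, 32)))  # stem
  build <- function(p, depth, off) {
    if (depth == 3) return(invisible(NULL))
    len <- 14
    for (s in c(-1, 1)) {
      child <- c(p[1] + len, p[2] + s * off, p[3] + (depth %% 2) * s * 3)
      paths[[length(paths) + 1]] <<- rbind(p, child)
      build(child, depth + 1, ceiling(off / 2))
    }
  }
  build(c(12, 32, 32), 0, 14)
  for (pp in paths) arr <- arr | paintChain(d, pp)
  sk <- skeletonize(RootMask(arr, 100))
  g <- buildRootGraph(sk, c(4, 32, 32))
  expect_equal(countTips(g), 8)
  expect_equal(length(g@edges), 15)  # stem + 2 + 4 + 8
  # edges = nodes - 1 on a tree rooted at the entry
  expect_equal(length(g@edges), nrow(g@nodes) - 1)
})

test_that("graphs are acyclic, fully reachable, and obey node accounting", {
  spec <- phantomSpec(seed = 33L, potDepthMm = 24)
  ph <- rasterizePhantom(generateRootTree(spec), spec)
  sk <- skeletonize(ph$truth@mask)
  d2 <- rowSums(sweep(sk@voxels, 2, ph$truth@entryPoint)^2)
  g <- buildRootGraph(sk, sk@voxels[which.min(d2), ], pruneVox = 10)
  el <- t(vapply(g@edges, function(e) c(e$from, e$to), c(1L, 1L)))
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  expect_true(igraph::is_dag(ig))
  reach <- igraph::subcomponent(ig, g@entryNode, mode = "out")
  expect_equal(length(reach), nrow(g@nodes))
  expect_equal(length(g@edges), nrow(g@nodes) - 1)
  # invariance of length under axis permutation and translation
  vox <- sk@voxels
  skP <- new("Skeleton", voxels = vox[, c(2, 1, 3)],
             dims = sk@dims[c(2, 1, 3)], voxelSizeUm = sk@voxelSizeUm)
  entryP <- sk@voxels[which.min(d2), c(2, 1, 3)]
  gP <- buildRootGraph(skP, entryP, pruneVox = 10)
  expect_equal(graphLength(gP), graphLength(g))
})
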