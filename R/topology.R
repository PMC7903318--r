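#' Thin a root mask to a curve skeleton
#'
#' Topology-preserving 3D thinning (six directional subiterations, removing
#' only simple non-endpoint border voxels) down to a 1-voxel-wide,
#' 26-connected medial curve set. Component count and topology are
#' preserved, and skeletonizing a skeleton returns it unchanged.
#'
#' @param mask a non-empty \linkS4class{RootMask}.
#' @return a \linkS4class{Skeleton}.
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "RootMask"))
  if (!any(mask@data)) stop("empty mask")
  d <- dim(mask@data)
  sk <- cpp_skeletonize3d(as.vector(mask@data), d)
  vox <- which(array(sk, d), arr.ind = TRUE)
  colnames(vox) <- c("i", "j", "k")
  new("Skeleton", voxels = vox, dims = as.integer(d),
      voxelSizeUm = mask@voxelSizeUm)
}

#' Skeleton as a logical array
#'
#' @param skel a \linkS4class{Skeleton}.
#' @return 3D logical array with TRUE at skeleton voxels.
#' @export
skeletonMask <- function(skel) {
  arr <- array(FALSE, skel@dims)
  arr[skel@voxels] <- TRUE
  arr
}

#' Build the directed root graph from a skeleton
#'
#' Nodes are skeleton voxels with other than two 26-neighbours (endpoints
#' and junctions) plus the entry voxel; edges are the voxel chains between
#' nodes. Edges are directed away from the entry by breadth-first search.
#' Rare cycles left by thinning are broken by dropping the longest edge in
#' each cycle (minimum-spanning-tree rule). Only the skeleton component
#' containing the entry is graphed; other components are counted in
#' \code{extraComponents}.
#'
#' @param skel a \linkS4class{Skeleton}.
#' @param entry length-3 voxel coordinate (depth, y, x) of the stem entry;
#'   it must lie within the 26-neighbourhood of a skeleton voxel.
#' @param pruneVox prune terminal edges shorter than this many voxels that
#'   attach to a junction (thinning spurs on thick segments); 0 disables.
#' @param entryTolVox maximal distance from \code{entry} to the skeleton.
#' @return a \linkS4class{RootGraph}.
#' @export
buildRootGraph <- function(skel, entry, pruneVox = 0,
                           entryTolVox = sqrt(3) + 1e-9) {
  stopifnot(is(skel, "Skeleton"))
  vox <- skel@voxels
  n <- nrow(vox)
  d <- skel@dims
  key <- voxKey(vox, d)

  dist2 <- (vox[, 1] - entry[1])^2 + (vox[, 2] - entry[2])^2 +
    (vox[, 3] - entry[3])^2
  if (min(dist2) > entryTolVox^2) stop("entry not near skeleton")
  entryIdx <- which.min(dist2)

  # 26-neighbour voxel adjacency
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  pairs <- NULL
  for (t in seq_len(nrow(off))) {
    nb <- cbind(vox[, 1] + off[t, 1], vox[, 2] + off[t, 2],
                vox[, 3] + off[t, 3])
    hit <- match(voxKey(nb, d), key)
    sel <- which(!is.na(hit) & hit > seq_len(n))
    if (length(sel))
      pairs <- rbind(pairs, cbind(sel, hit[sel]))
  }
  adj <- vector("list", n)
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  degree <- lengths(adj)

  # component containing the entry
  inComp <- rep(FALSE, n)
  stack <- entryIdx
  inComp[entryIdx] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (nb in adj[[cur]]) if (!inComp[nb]) {
      inComp[nb] <- TRUE
      stack <- c(stack, nb)
    }
  }
  extra <- countComponents(adj, !inComp)

  nodeVox <- which((degree != 2L | seq_len(n) == entryIdx) & inComp)
  if (!length(nodeVox)) nodeVox <- entryIdx  # pure cycle through entry
  isNode <- rep(FALSE, n)
  isNode[nodeVox] <- TRUE

  chains <- traceChains(adj, isNode, nodeVox, inComp)
  nodeId <- match(nodeVox, nodeVox)  # 1..m in nodeVox order
  vmm <- skel@voxelSizeUm / 1000

  if (length(chains) == 0) {
    nodes <- data.frame(id = 1L, type = "entry",
                        i = vox[entryIdx, 1], j = vox[entryIdx, 2],
                        k = vox[entryIdx, 3])
    return(new("RootGraph", nodes = nodes, edges = list(),
               voxelSizeUm = skel@voxelSizeUm, entryNode = 1L,
               extraComponents = as.integer(extra)))
  }

  eFrom <- vapply(chains, function(ch) match(ch[1], nodeVox), 1L)
  eTo <- vapply(chains, function(ch) match(ch[length(ch)], nodeVox), 1L)
  eLen <- vapply(chains, function(ch) {
    p <- vox[ch, , drop = FALSE]
    sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                        p[-nrow(p), , drop = FALSE])^2))) * vmm
  }, 1.0)

  # cycle breaking: drop the longest edge of every cycle (= keep the
  # minimum-spanning tree by length); self-loops are never kept
  keep <- which(eFrom != eTo)
  if (!length(keep)) {
    nodes <- data.frame(id = 1L, type = "entry",
                        i = vox[entryIdx, 1], j = vox[entryIdx, 2],
                        k = vox[entryIdx, 3])
    return(new("RootGraph", nodes = nodes, edges = list(),
               voxelSizeUm = skel@voxelSizeUm, entryNode = 1L,
               extraComponents = as.integer(extra)))
  }
  g <- igraph::graph_from_edgelist(cbind(eFrom[keep], eTo[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(nodeVox) -
                                        igraph::vcount(g)))
  mstG <- igraph::mst(g, weights = eLen[keep])
  # map MST edges back to chain indices by endpoints + length
  mstEnds <- igraph::as_edgelist(mstG)
  used <- rep(FALSE, length(keep))
  sel <- integer(0)
  for (r in seq_len(nrow(mstEnds))) {
    a <- mstEnds[r, 1]; b <- mstEnds[r, 2]
    cnd <- which(!used & ((eFrom[keep] == a & eTo[keep] == b) |
                            (eFrom[keep] == b & eTo[keep] == a)))
    cnd <- cnd[which.min(eLen[keep][cnd])]
    used[cnd] <- TRUE
    sel <- c(sel, keep[cnd])
  }

  entryNode <- match(entryIdx, nodeVox)
  dirEdges <- directEdges(sel, eFrom, eTo, chains, entryNode,
                          length(nodeVox))

  edges <- lapply(dirEdges, function(e) {
    ch <- chains[[e$chain]]
    if (e$flip) ch <- rev(ch)
    p <- vox[ch, , drop = FALSE]
    list(from = e$from, to = e$to, polyline = p,
         lengthMm = sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                        p[-nrow(p), , drop = FALSE])^2))) *
           vmm,
         voxelIdx = ch)
  })

  gr <- assembleGraph(edges, nodeVox, vox, entryNode, skel@voxelSizeUm,
                      extra)
  if (pruneVox > 0) gr <- pruneGraph(gr, pruneVox)
  gr
}

voxKey <- function(vox, d) {
  (vox[, 1] - 1) + as.numeric(d[1]) *
    ((vox[, 2] - 1) + as.numeric(d[2]) * (vox[, 3] - 1))
}

countComponents <- function(adj, active) {
  n <- length(adj)
  seen <- !active
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (nb in adj[[cur]]) if (!seen[nb]) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  comps
}

# walk chains of degree-2 voxels between node voxels
traceChains <- function(adj, isNode, nodeVox, inComp) {
  chains <- list()
  seenKey <- character(0)
  for (u in nodeVox) {
    for (w in adj[[u]]) {
      if (!inComp[w]) next
      ch <- c(u, w)
      prev <- u; cur <- w
      while (!isNode[cur]) {
        nxt <- adj[[cur]][adj[[cur]] != prev]
        if (length(nxt) == 0) break  # dead end (shouldn't happen)
        prev <- cur; cur <- nxt[1]
        ch <- c(ch, cur)
      }
      kk <- paste(min(ch[1], ch[length(ch)]), max(ch[1], ch[length(ch)]),
                  paste(sort(c(ch[2], ch[length(ch) - 1])), collapse = "-"),
                  length(ch))
      if (kk %in% seenKey) next
      seenKey <- c(seenKey, kk)
      chains[[length(chains) + 1]] <- ch
    }
  }
  chains
}

directEdges <- function(sel, eFrom, eTo, chains, entryNode, nNodes) {
  # BFS over kept edges from the entry node
  inc <- vector("list", nNodes)
  for (e in sel) {
    inc[[eFrom[e]]] <- c(inc[[eFrom[e]]], e)
    inc[[eTo[e]]] <- c(inc[[eTo[e]]], e)
  }
  visited <- rep(FALSE, nNodes)
  visited[entryNode] <- TRUE
  queue <- entryNode
  out <- list()
  usedEdge <- rep(FALSE, length(eFrom))
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (e in inc[[u]]) {
      if (usedEdge[e]) next
      v <- if (eFrom[e] == u) eTo[e] else eFrom[e]
      if (visited[v]) { usedEdge[e] <- TRUE; next }
      usedEdge[e] <- TRUE
      visited[v] <- TRUE
      queue <- c(queue, v)
      out[[length(out) + 1]] <- list(chain = e, from = u, to = v,
                                     flip = eFrom[e] != u)
    }
  }
  out
}

assembleGraph <- function(edges, nodeVox, vox, entryNode, voxelSizeUm,
                          extra) {
  usedNodes <- sort(unique(c(entryNode,
                             unlist(lapply(edges, function(e)
                               c(e$from, e$to))))))
  remap <- match(seq_along(nodeVox), usedNodes)
  edges <- lapply(edges, function(e) {
    e$from <- remap[e$from]; e$to <- remap[e$to]; e
  })
  outDeg <- tabulate(vapply(edges, `[[`, 1L, "from"),
                     nbins = length(usedNodes))
  type <- ifelse(outDeg == 0, "tip", "branch")
  type[remap[entryNode]] <- "entry"
  nv <- nodeVox[usedNodes]
  nodes <- data.frame(id = seq_along(usedNodes), type = type,
                      i = vox[nv, 1], j = vox[nv, 2], k = vox[nv, 3])
  new("RootGraph", nodes = nodes, edges = edges,
      voxelSizeUm = voxelSizeUm, entryNode = remap[entryNode],
      extraComponents = as.integer(extra))
}

# remove terminal spur edges shorter than pruneVox voxels attached to a
# junction, then merge pass-through nodes
pruneGraph <- function(gr, pruneVox) {
  edges <- gr@edges
  if (!length(edges)) return(gr)
  entryI <- gr@nodes$i[gr@entryNode]
  # iterate spur removal to a fixed point: merging after a prune pass can
  # expose a new short terminal edge (nested forks near a blunt tip);
  # merging first collapses junction clusters so spurs hanging off them
  # by a short intermediate edge are seen
  repeat {
    edges <- mergePassThrough(edges, gr)
    from <- vapply(edges, `[[`, 1L, "from")
    to <- vapply(edges, `[[`, 1L, "to")
    nvox <- vapply(edges, function(e) nrow(e$polyline), 1L)
    outDeg <- tabulate(from, nbins = nrow(gr@nodes))
    headI <- vapply(edges, function(e) e$polyline[nrow(e$polyline), 1], 1.0)
    # short terminal spurs at junctions, plus upward terminal stubs at
    # the entry node (the stem stump above the soil is not root). When
    # every out-edge of a junction is a short terminal prong (a blunt tip
    # that thinning forked), the longest prong is the true continuation
    # and is kept.
    shortTerm <- outDeg[to] == 0 & (nvox - 1) < pruneVox &
      outDeg[from] >= 2
    # at the entry node: upward terminal stubs of any length (the stem
    # above the soil) and short terminal stubs of any direction (surface
    # debris attached to the stem top)
    spur <- which(outDeg[to] == 0 & from == gr@entryNode &
                    outDeg[from] >= 2 &
                    (headI < entryI | (nvox - 1) < pruneVox))
    for (nd in unique(from[shortTerm])) {
      idx <- which(from == nd & shortTerm)
      if (length(idx) == sum(from == nd))
        idx <- idx[-which.max(nvox[idx])]
      spur <- union(spur, idx)
    }
    if (!length(spur)) break
    edges <- edges[-spur]
    edges <- mergePassThrough(edges, gr)
  }
  edges <- mergePassThrough(edges, gr)
  rebuildNodes(gr, edges)
}

mergePassThrough <- function(edges, gr) {
  # merge chains through nodes that have one in- and one out-edge
  repeat {
    from <- vapply(edges, `[[`, 1L, "from")
    to <- vapply(edges, `[[`, 1L, "to")
    outDeg <- tabulate(from, nbins = nrow(gr@nodes))
    inDeg <- tabulate(to, nbins = nrow(gr@nodes))
    mid <- which(inDeg == 1 & outDeg == 1 &
                   seq_len(nrow(gr@nodes)) != gr@entryNode)
    mid <- mid[mid %in% to & mid %in% from]
    if (!length(mid)) break
    m <- mid[1]
    eIn <- which(to == m); eOut <- which(from == m)
    a <- edges[[eIn]]; b <- edges[[eOut]]
    merged <- list(from = a$from, to = b$to,
                   polyline = rbind(a$polyline,
                                    b$polyline[-1, , drop = FALSE]),
                   lengthMm = a$lengthMm + b$lengthMm,
                   voxelIdx = c(a$voxelIdx, b$voxelIdx[-1]))
    edges[[eIn]] <- merged
    edges <- edges[-eOut]
  }
  edges
}

rebuildNodes <- function(gr, edges) {
  oldNodes <- gr@nodes
  usedOld <- sort(unique(c(gr@entryNode,
                           unlist(lapply(edges, function(e)
                             c(e$from, e$to))))))
  remap <- match(seq_len(nrow(oldNodes)), usedOld)
  edges <- lapply(edges, function(e) {
    e$from <- remap[e$from]; e$to <- remap[e$to]; e
  })
  outDeg <- tabulate(vapply(edges, `[[`, 1L, "from"),
                     nbins = length(usedOld))
  type <- ifelse(outDeg == 0, "tip", "branch")
  type[remap[gr@entryNode]] <- "entry"
  nodes <- oldNodes[usedOld, ]
  nodes$id <- seq_along(usedOld)
  nodes$type <- type
  rownames(nodes) <- NULL
  new("RootGraph", nodes = nodes, edges = edges,
      voxelSizeUm = gr@voxelSizeUm, entryNode = remap[gr@entryNode],
      extraComponents = gr@extraComponents)
}

#' Number of root tips
#'
#' Tips are graph nodes without outgoing edges.
#'
#' @param graph a \linkS4class{RootGraph}.
#' @return integer tip count.
#' @export
countTips <- function(graph) {
  stopifnot(is(graph, "RootGraph"))
  sum(graph@nodes$type == "tip" |
        (graph@nodes$type == "entry" & length(graph@edges) == 0))
}

#' Total root length from the graph
#'
#' The primary convention counts distinct skeleton voxels across all edges
#' and multiplies by the voxel edge length; \code{method = "euclidean"}
#' instead sums Euclidean polyline lengths.
#'
#' @param graph a \linkS4class{RootGraph}.
#' @param method "voxel" (default) or "euclidean".
#' @return length in mm.
#' @export
graphLength <- function(graph, method = c("voxel", "euclidean")) {
  method <- match.arg(method)
  stopifnot(is(graph, "RootGraph"))
  if (!length(graph@edges)) return(0)
  if (method == "euclidean")
    return(sum(vapply(graph@edges, `[[`, 1.0, "lengthMm")))
  allVox <- do.call(rbind, lapply(graph@edges, `[[`, "polyline"))
  nDistinct <- nrow(unique(allVox))
  nDistinct * graph@voxelSizeUm / 1000
}
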