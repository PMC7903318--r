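#' Export a root graph as RSML
#'
#' Writes root system markup language: one scene with one plant, root
#' elements nested by graph topology (edges leaving the entry are top-level
#' roots; edges leaving an edge's head node are its laterals), geometry as
#' 3D polylines in mm. Coordinates are written at full double precision so
#' a parse round-trip reproduces them exactly. Axis mapping: \code{x} =
#' array axis 3, \code{y} = array axis 2, \code{z} = depth (axis 1).
#'
#' @param graph a directed acyclic \linkS4class{RootGraph}.
#' @param path output file path.
#' @param report optional \linkS4class{TraitReport} stored as plant
#'   annotations.
#' @param meta named list merged into the metadata block (e.g.
#'   \code{list(software = "...")}).
#' @return \code{invisible(path)}.
#' @export
exportRSML <- function(graph, path, report = NULL, meta = list()) {
  stopifnot(is(graph, "RootGraph"))
  checkAcyclic(graph)
  vmm <- graph@voxelSizeUm / 1000
  doc <- xml2::xml_new_root("rsml")
  md <- xml2::xml_add_child(doc, "metadata")
  defaults <- list(version = "1", unit = "mm",
                   resolution = format(vmm, digits = 17),
                   `last-modified` = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   software = "rootCT")
  for (key in union(names(defaults), names(meta))) {
    val <- meta[[key]] %||% defaults[[key]]
    xml2::xml_add_child(md, key, as.character(val))
  }
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1", label = "plant_1")
  if (!is.null(report)) {
    ann <- xml2::xml_add_child(plant, "annotations")
    for (nm in names(report@values)) {
      v <- report@values[[nm]]
      if (is.numeric(v) && length(v) == 1 && is.finite(v)) {
        a <- xml2::xml_add_child(ann, "annotation", name = nm)
        xml2::xml_add_child(a, "value", format(v, digits = 17))
      }
    }
  }
  children <- edgeChildren(graph)
  rootEdges <- which(vapply(graph@edges, `[[`, 1L, "from") ==
                       graph@entryNode)
  cnt <- 0
  for (e in rootEdges) {
    cnt <- cnt + 1
    addRootElement(plant, graph, e, children, as.character(cnt), vmm)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

checkAcyclic <- function(graph) {
  if (!length(graph@edges)) return(invisible(TRUE))
  el <- t(vapply(graph@edges, function(e) c(e$from, e$to), c(1L, 1L)))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  if (!igraph::is_dag(g)) stop("cyclic graph cannot be exported as RSML")
  invisible(TRUE)
}

# children[[edge]] = edges whose tail is this edge's head
edgeChildren <- function(graph) {
  from <- vapply(graph@edges, `[[`, 1L, "from")
  to <- vapply(graph@edges, `[[`, 1L, "to")
  lapply(seq_along(graph@edges), function(e) which(from == to[e]))
}

addRootElement <- function(parentNode, graph, e, children, id, vmm) {
  edge <- graph@edges[[e]]
  rt <- xml2::xml_add_child(parentNode, "root", ID = id,
                            label = paste0("root_", id))
  geom <- xml2::xml_add_child(rt, "geometry")
  pl <- xml2::xml_add_child(geom, "polyline")
  p <- (edge$polyline - 0.5) * vmm  # voxel centers in mm
  for (r in seq_len(nrow(p)))
    xml2::xml_add_child(pl, "point",
                        x = format(p[r, 3], digits = 17),
                        y = format(p[r, 2], digits = 17),
                        z = format(p[r, 1], digits = 17))
  kids <- children[[e]]
  for (s in seq_along(kids))
    addRootElement(rt, graph, kids[s], children, paste0(id, ".", s), vmm)
}

#' Read an RSML file
#'
#' @param path RSML file path.
#' @return list with \code{metadata} (named list) and \code{roots}, a
#'   recursive list of roots; each root has \code{id}, \code{polyline}
#'   (matrix with columns depth, y, x in mm) and \code{children}.
#' @export
readRSML <- function(path) {
  doc <- xml2::read_xml(path)
  md <- xml2::xml_find_first(doc, "./metadata")
  metadata <- list()
  if (!inherits(md, "xml_missing"))
    for (ch in xml2::xml_children(md))
      metadata[[xml2::xml_name(ch)]] <- xml2::xml_text(ch)
  parseRoot <- function(node) {
    pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    poly <- cbind(
      depth = as.numeric(xml2::xml_attr(pts, "z")),
      y = as.numeric(xml2::xml_attr(pts, "y")),
      x = as.numeric(xml2::xml_attr(pts, "x")))
    list(id = xml2::xml_attr(node, "ID"),
         polyline = poly,
         children = lapply(xml2::xml_find_all(node, "./root"), parseRoot))
  }
  roots <- lapply(xml2::xml_find_all(doc, "./scene/plant/root"), parseRoot)
  list(metadata = metadata, roots = roots)
}

#' Validate RSML structure
#'
#' Structural validation against the RSML layout: a single \code{rsml} root
#' with a \code{metadata} block carrying \code{version} and \code{unit}, a
#' \code{scene} with at least one \code{plant}, and every \code{root}
#' element carrying a \code{geometry/polyline} with at least two points
#' whose \code{x}, \code{y}, \code{z} attributes are numeric.
#'
#' @param path RSML file path.
#' @return \code{TRUE} (invisibly); stops with the list of violations
#'   otherwise.
#' @export
validateRSML <- function(path) {
  doc <- xml2::read_xml(path)
  issues <- character(0)
  if (xml2::xml_name(doc) != "rsml") issues <- c(issues, "root element must be <rsml>")
  md <- xml2::xml_find_first(doc, "./metadata")
  if (inherits(md, "xml_missing")) {
    issues <- c(issues, "missing <metadata>")
  } else {
    for (key in c("version", "unit"))
      if (inherits(xml2::xml_find_first(md, paste0("./", key)),
                   "xml_missing"))
        issues <- c(issues, paste0("metadata missing <", key, ">"))
  }
  if (inherits(xml2::xml_find_first(doc, "./scene"), "xml_missing"))
    issues <- c(issues, "missing <scene>")
  if (!length(xml2::xml_find_all(doc, "./scene/plant")))
    issues <- c(issues, "scene has no <plant>")
  for (rt in xml2::xml_find_all(doc, ".//root")) {
    pts <- xml2::xml_find_all(rt, "./geometry/polyline/point")
    rid <- xml2::xml_attr(rt, "ID")
    if (length(pts) < 2)
      issues <- c(issues, paste0("root ", rid,
                                 ": polyline needs >= 2 points"))
    for (att in c("x", "y", "z"))
      if (anyNA(suppressWarnings(as.numeric(xml2::xml_attr(pts, att)))))
        issues <- c(issues, paste0("root ", rid, ": non-numeric ", att))
  }
  if (length(issues)) stop("invalid RSML: ", paste(issues, collapse = "; "))
  invisible(TRUE)
}
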