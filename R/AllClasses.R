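#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib NeuriteTrace, .registration = TRUE
NULL

#' SwcTree: a rooted neuron morphology
#'
#' A rooted tree of annotation nodes in the standard 7-column SWC layout:
#' `id`, `type` (1 = soma), `x`, `y`, `z` (voxel units, 0-based, voxel centers
#' at integer coordinates), `radius` (voxels) and `parent` (`-1` for the
#' root). The `metadata` slot carries generator bookkeeping (e.g. per-fiber
#' specifications for synthetic scenes) and is not written to disk.
#'
#' @slot nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @slot metadata list of optional annotations.
#' @export
setClass("SwcTree",
  slots = c(nodes = "data.frame", metadata = "list"),
  prototype = prototype(
    nodes = data.frame(id = integer(), type = integer(),
                       x = numeric(), y = numeric(), z = numeric(),
                       radius = numeric(), parent = integer()),
    metadata = list()
  )
)

setValidity("SwcTree", function(object) {
  nd <- object@nodes
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (nrow(nd) == 0L) return(TRUE)
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  roots <- which(nd$parent == -1L)
  if (length(roots) != 1L) return("tree must have exactly one root (parent == -1)")
  nonroot <- nd$parent[nd$parent != -1L]
  if (!all(nonroot %in% nd$id)) return("dangling parent reference")
  # cycle check: every node must reach the root
  pidx <- match(nd$parent, nd$id) # NA for root
  ord <- rep(NA_integer_, nrow(nd))
  ord[roots] <- 0L
  repeat {
    newly <- which(is.na(ord) & !is.na(ord[pidx]))
    if (!length(newly)) break
    ord[newly] <- ord[pidx[newly]] + 1L
  }
  if (anyNA(ord)) return("cyclic or disconnected parent chain")
  TRUE
})

#' Construct an SwcTree
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @param metadata optional list of annotations.
#' @return A validated [SwcTree-class] object.
#' @examples
#' soma <- data.frame(id = 1L, type = 1L, x = 5, y = 5, z = 5,
#'                    radius = 3, parent = -1L)
#' SwcTree(soma)
#' @export
SwcTree <- function(nodes, metadata = list()) {
  nodes <- as.data.frame(nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  rownames(nodes) <- NULL
  new("SwcTree", nodes = nodes, metadata = metadata)
}

#' @describeIn SwcTree Number of nodes.
#' @param x,object An `SwcTree`.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname SwcTree
#' @export
setMethod("nNodes", "SwcTree", function(x) nrow(x@nodes))

#' Accessors for SwcTree
#'
#' `swcNodes()` returns the node table; `rootNode()` the root row;
#' `treePathLength()` the total cable length (sum of parent-child Euclidean
#' segment lengths, in voxels).
#'
#' @param x An `SwcTree`.
#' @return `swcNodes`: data.frame; `rootNode`: one-row data.frame;
#'   `treePathLength`: numeric scalar.
#' @export
swcNodes <- function(x) {
  stopifnot(is(x, "SwcTree"))
  x@nodes
}

#' @rdname swcNodes
#' @export
rootNode <- function(x) {
  nd <- swcNodes(x)
  nd[nd$parent == -1L, , drop = FALSE]
}

#' @rdname swcNodes
#' @export
treePathLength <- function(x) {
  nd <- swcNodes(x)
  if (nrow(nd) < 2L) return(0)
  pidx <- match(nd$parent, nd$id)
  keep <- !is.na(pidx)
  sum(sqrt((nd$x[keep] - nd$x[pidx[keep]])^2 +
           (nd$y[keep] - nd$y[pidx[keep]])^2 +
           (nd$z[keep] - nd$z[pidx[keep]])^2))
}

setMethod("show", "SwcTree", function(object) {
  nd <- object@nodes
  cat(sprintf("SwcTree with %d node(s)\n", nrow(nd)))
  if (nrow(nd)) {
    r <- rootNode(object)
    cat(sprintf("  root: id %d at (%.1f, %.1f, %.1f), type %d\n",
                r$id, r$x, r$y, r$z, r$type))
    cat(sprintf("  cable length: %.1f voxels\n", treePathLength(object)))
  }
  invisible(object)
})

#' MetricsReport: reconstruction-vs-gold evaluation summary
#'
#' Holds the directional spatial-distance triplets (gold-to-reconstruction
#' `*12`, reconstruction-to-gold `*21`, and their average), intensity
#' stratified recall, the path-length ratio and the self-crossing count.
#' All distances are in voxels; `pds*` and recalls are fractions in \[0,1\].
#'
#' @slot sd12,sd21,sd numeric; average nearest-point distances.
#' @slot ssd12,ssd21,ssd numeric; same restricted to distances > 2 voxels.
#' @slot pds12,pds21,pds numeric; fraction of points with distance > 2 voxels.
#' @slot recallByIntensity data.frame with bin edges, counts and recall.
#' @slot weakRecall numeric; recall at image intensity below the weak
#'   threshold (default 20 on the 8-bit scale).
#' @slot pathLengthRatio numeric; reconstruction cable length / gold length.
#' @slot nSelfCrossings integer; qualifying close-pair count.
#' @export
setClass("MetricsReport",
  slots = c(sd12 = "numeric", sd21 = "numeric", sd = "numeric",
            ssd12 = "numeric", ssd21 = "numeric", ssd = "numeric",
            pds12 = "numeric", pds21 = "numeric", pds = "numeric",
            recallByIntensity = "data.frame",
            weakRecall = "numeric",
            pathLengthRatio = "numeric",
            nSelfCrossings = "integer"),
  prototype = prototype(recallByIntensity = data.frame(),
                        weakRecall = NA_real_,
                        pathLengthRatio = NA_real_,
                        nSelfCrossings = NA_integer_)
)

setValidity("MetricsReport", function(object) {
  for (s in c("pds12", "pds21", "pds")) {
    v <- slot(object, s)
    if (length(v) && !is.na(v) && (v < 0 || v > 1))
      return(sprintf("%s must lie in [0,1]", s))
  }
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (voxels; lower distances are better)\n")
  cat(sprintf("  SD12/SD21/SD:    %.3f / %.3f / %.3f\n",
              object@sd12, object@sd21, object@sd))
  cat(sprintf("  SSD12/SSD21/SSD: %.3f / %.3f / %.3f\n",
              object@ssd12, object@ssd21, object@ssd))
  cat(sprintf("  PDS12/PDS21/PDS: %.3f / %.3f / %.3f\n",
              object@pds12, object@pds21, object@pds))
  if (!is.na(object@weakRecall))
    cat(sprintf("  weak-fiber recall: %.3f\n", object@weakRecall))
  if (!is.na(object@pathLengthRatio))
    cat(sprintf("  path length ratio: %.3f\n", object@pathLengthRatio))
  if (!is.na(object@nSelfCrossings))
    cat(sprintf("  self-crossing pairs: %d\n", object@nSelfCrossings))
  invisible(object)
})

#' Convert a MetricsReport to a flat named list
#'
#' @param report A [MetricsReport-class].
#' @return Named list of scalar metrics (recall histogram omitted).
#' @export
metricsAsList <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  list(sd12 = report@sd12, sd21 = report@sd21, sd = report@sd,
       ssd12 = report@ssd12, ssd21 = report@ssd21, ssd = report@ssd,
       pds12 = report@pds12, pds21 = report@pds21, pds = report@pds,
       weak_recall = report@weakRecall,
       path_length_ratio = report@pathLengthRatio,
       n_self_crossings = report@nSelfCrossings)
}
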