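# Reconstruction extraction: threshold -> connected component containing the
# soma -> 3D thinning -> skeleton voxel graph -> shortest-path spanning tree
# rooted at the soma -> SWC. A deliberately simple built-in tracer so the
# pipeline is end-to-end testable; fused volumes can also be exported for
# external tracers.

voxelEncode <- function(v, shape) v[, 1] + shape[1] * (v[, 2] + shape[2] * v[, 3])

#' Extract an SWC reconstruction from a fused volume
#'
#' @param fused Volume in \[0,1\] (image fused with segmentation).
#' @param threshold Foreground threshold in (0, 1).
#' @param somaXYZ Soma position (x, y, z), 0-based voxel units.
#' @param pruneLength Remove terminal skeleton twigs shorter than this many
#'   voxels (0 disables pruning).
#' @return An [SwcTree-class] with a single root at the soma and no cycles.
#' @export
extractReconstruction <- function(fused, threshold = 0.5, somaXYZ,
                                  pruneLength = 2) {
  stopifnot(length(dim(fused)) == 3L)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  shape <- dim(fused)
  v0 <- round(somaXYZ)
  if (any(v0 < 0) || any(v0 >= shape)) stop("soma lies outside the volume")
  mask <- fused >= threshold
  i0 <- v0[1] + 1 + shape[1] * (v0[2] + shape[2] * v0[3])
  if (!mask[i0])
    stop("disconnected soma: the soma voxel is below the tracing threshold")
  lab <- ccLabel3d(as.logical(mask), as.integer(shape))
  comp <- lab == lab[i0]
  skel <- thin3d(comp, as.integer(shape), as.integer(i0))
  idx <- which(skel) # 1-based linear indices
  coords <- cbind(x = (idx - 1) %% shape[1],
                  y = ((idx - 1) %/% shape[1]) %% shape[2],
                  z = (idx - 1) %/% (shape[1] * shape[2]))
  n <- length(idx)
  somaVert <- match(i0, idx)
  stopifnot(!is.na(somaVert))
  # 26-neighbour edges via the 13 positive offsets
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
  enc <- voxelEncode(coords, shape)
  edges <- list(); wts <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < shape[1] &
          nb[, 2] >= 0 & nb[, 2] < shape[2] &
          nb[, 3] >= 0 & nb[, 3] < shape[3]
    j <- match(voxelEncode(nb[ok, , drop = FALSE], shape), enc)
    hit <- !is.na(j)
    if (any(hit)) {
      edges[[k]] <- cbind(which(ok)[hit], j[hit])
      wts[[k]] <- rep(sqrt(sum(offs[k, ]^2)), sum(hit))
    }
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(em))
    g <- igraph::add_edges(g, t(em), weight = unlist(wts))
  sp <- igraph::shortest_paths(g, from = somaVert, to = igraph::V(g),
                               mode = "all", predecessors = TRUE,
                               output = "vpath")
  pred <- as.integer(sp$predecessors)
  # order nodes by BFS from the soma so parents precede children
  ord <- as.integer(igraph::bfs(g, root = somaVert, unreachable = FALSE)$order)
  ord <- ord[!is.na(ord)]
  newId <- integer(n)
  newId[ord] <- seq_along(ord)
  nd <- data.frame(id = seq_along(ord),
                   type = ifelse(seq_along(ord) == 1L, 1L, 3L),
                   x = coords[ord, 1], y = coords[ord, 2], z = coords[ord, 3],
                   radius = 1,
                   parent = ifelse(seq_along(ord) == 1L, -1L, newId[pred[ord]]))
  tree <- SwcTree(nd)
  if (pruneLength > 0) tree <- pruneShortTwigs(tree, pruneLength)
  tree
}

# remove terminal chains shorter than minLen voxels (never the root)
pruneShortTwigs <- function(tree, minLen) {
  repeat {
    nd <- swcNodes(tree)
    if (nrow(nd) < 2L) return(tree)
    nKids <- table(factor(nd$parent, levels = nd$id))
    leaves <- nd$id[nKids[as.character(nd$id)] == 0 & nd$parent != -1L]
    drop <- integer()
    for (lf in leaves) {
      chain <- integer(); len <- 0; cur <- lf
      repeat {
        row <- match(cur, nd$id)
        par <- nd$parent[row]
        chain <- c(chain, cur)
        if (par == -1L) break
        prow <- match(par, nd$id)
        len <- len + sqrt((nd$x[row] - nd$x[prow])^2 +
                          (nd$y[row] - nd$y[prow])^2 +
                          (nd$z[row] - nd$z[prow])^2)
        if (nKids[as.character(par)] > 1 || len >= minLen) break
        cur <- par
      }
      if (len < minLen) drop <- c(drop, chain)
    }
    if (!length(drop)) return(tree)
    keep <- !(nd$id %in% drop)
    if (all(keep)) return(tree)
    tree <- SwcTree(nd[keep, , drop = FALSE], metadata = tree@metadata)
  }
}
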