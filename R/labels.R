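#' Rasterize a tree's fiber points into a binary label volume
#'
#' The tree is resampled to connective points at `step` spacing, each point is
#' rounded to its nearest voxel and stamped with a uniform fiber width
#' (default 3 x 3 x 1 voxels in x, y, z — neurites are near-isotropic in-plane
#' but thin in z at fMOST-like resolution). Points falling outside `shape`
#' are dropped.
#'
#' @param tree An [SwcTree-class] (coordinates in 0-based voxel units).
#' @param shape Integer vector (x, y, z) giving the target volume size.
#' @param fiberWidth Structuring element size (x, y, z); odd integers.
#' @param step Resampling step in voxels.
#' @return Binary (0/1) array of dim `shape`.
#' @export
rasterizeTree <- function(tree, shape, fiberWidth = c(3, 3, 1), step = 1.0) {
  stopifnot(length(shape) == 3L, all(shape >= 1), all(fiberWidth %% 2 == 1))
  lab <- array(0L, dim = shape)
  pts <- resampleTree(tree, step)
  if (nrow(pts) == 0L) return(lab)
  vox <- round(pts) # 0-based voxel coordinates
  vox <- unique(vox)
  half <- (fiberWidth - 1) / 2
  offs <- as.matrix(expand.grid(dx = -half[1]:half[1],
                                dy = -half[2]:half[2],
                                dz = -half[3]:half[3]))
  for (k in seq_len(nrow(offs))) {
    p <- sweep(vox, 2, offs[k, ], "+")
    keep <- p[, 1] >= 0 & p[, 1] < shape[1] &
            p[, 2] >= 0 & p[, 2] < shape[2] &
            p[, 3] >= 0 & p[, 3] < shape[3]
    if (any(keep)) lab[p[keep, , drop = FALSE] + 1] <- 1L
  }
  lab
}

#' Soma mask: fixed-size cuboid (or ellipsoid) at the root
#'
#' The root is covered by a fixed-size cuboid, 18 x 18 x 6 voxels (x, y, z) by
#' default, clipped at the volume bounds. Even sizes cannot be centered on a
#' voxel, so the cuboid is anchored as the floor-centered half-open range
#' `[c - s/2, c + s/2)`, which keeps exactly `prod(size)` voxels when
#' unclipped. The same mask is painted into training images (at a configured
#' intensity) and into label volumes. An ellipsoid with semi-axes `size/2` is
#' available as an alternative.
#'
#' @param tree An [SwcTree-class] with a root node.
#' @param shape Volume size (x, y, z).
#' @param size Cuboid size (x, y, z), default `c(18, 18, 6)`.
#' @param somaShape `"cuboid"` (default) or `"ellipsoid"`.
#' @return Binary (0/1) array of dim `shape`.
#' @export
somaMask <- function(tree, shape, size = c(18, 18, 6), somaShape = c("cuboid", "ellipsoid")) {
  somaShape <- match.arg(somaShape)
  stopifnot(length(shape) == 3L, length(size) == 3L)
  r <- rootNode(tree)
  if (nrow(r) != 1L) stop("tree has no root")
  cpos <- round(c(r$x, r$y, r$z)) # 0-based center voxel
  if (any(cpos < 0) || any(cpos >= shape)) stop("root lies outside the volume")
  lab <- array(0L, dim = shape)
  lo <- floor(cpos - size / 2)
  hi <- floor(cpos + size / 2) - 1 # inclusive, half-open upper bound
  cl <- pmax(lo, 0)
  ch <- pmin(hi, shape - 1)
  if (any(ch < cl)) return(lab)
  xs <- (cl[1]:ch[1]) + 1; ys <- (cl[2]:ch[2]) + 1; zs <- (cl[3]:ch[3]) + 1
  if (somaShape == "cuboid") {
    lab[xs, ys, zs] <- 1L
  } else {
    semi <- size / 2
    g <- expand.grid(x = xs - 1, y = ys - 1, z = zs - 1)
    d <- ((g$x - cpos[1]) / semi[1])^2 + ((g$y - cpos[2]) / semi[2])^2 +
         ((g$z - cpos[3]) / semi[3])^2
    sel <- as.matrix(g[d <= 1, , drop = FALSE]) + 1
    if (nrow(sel)) lab[sel] <- 1L
  }
  lab
}

#' Build the full training label volume for a tree
#'
#' Union of the rasterized fiber points ([rasterizeTree()]) and the soma mask
#' ([somaMask()]). Adding nodes to the tree can only add foreground voxels
#' (rasterization is monotone).
#'
#' @inheritParams rasterizeTree
#' @inheritParams somaMask
#' @param somaSize Soma cuboid size (x, y, z).
#' @return Binary (0/1) array of dim `shape`.
#' @export
makeLabelVolume <- function(tree, shape, fiberWidth = c(3, 3, 1),
                            somaSize = c(18, 18, 6),
                            somaShape = "cuboid", step = 1.0) {
  lab <- rasterizeTree(tree, shape, fiberWidth = fiberWidth, step = step)
  if (nNodes(tree) > 0L)
    lab <- pmax(lab, somaMask(tree, shape, size = somaSize, somaShape = somaShape))
  lab
}

#' Paint the soma cuboid into an image volume
#'
#' Training images get the same fixed-size soma mask as the labels, overlaid
#' at a configured intensity (default: the image maximum), so the network
#' sees a consistent soma appearance.
#'
#' @param vol Image volume, dim (x, y, z), values in \[0,1\].
#' @param tree An [SwcTree-class] with a root node.
#' @param intensity Intensity to paint; default `max(vol)`.
#' @inheritParams somaMask
#' @return The modified volume.
#' @export
applySomaToImage <- function(vol, tree, intensity = NULL,
                             size = c(18, 18, 6), somaShape = "cuboid") {
  if (is.null(intensity)) intensity <- max(vol)
  m <- somaMask(tree, dim(vol), size = size, somaShape = somaShape)
  vol[m == 1L] <- intensity
  vol
}
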