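#' Read a neuron morphology from an SWC file
#'
#' Parses the standard whitespace-separated 7-column SWC format
#' (id, type, x, y, z, radius, parent); lines starting with `#` are comments.
#' Structural defects (duplicate ids, dangling parents, cycles, multiple
#' roots) raise an error that names the offending line or id.
#'
#' @param path Path to an SWC file.
#' @return An [SwcTree-class].
#' @export
readSWC <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  rows <- raw[keep]
  if (!length(rows))
    return(SwcTree(data.frame(id = integer(), type = integer(),
                              x = numeric(), y = numeric(), z = numeric(),
                              radius = numeric(), parent = integer())))
  fields <- strsplit(trimws(rows), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d: expected 7 columns, got %d",
                 lineNo[bad[1]], length(fields[[bad[1]]])))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("SWC parse error at line %d: non-numeric field",
                 lineNo[which(rowSums(is.na(m)) > 0)[1]]))
  nd <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5],
                   radius = m[, 6], parent = as.integer(m[, 7]))
  dup <- which(duplicated(nd$id))
  if (length(dup))
    stop(sprintf("SWC parse error at line %d: duplicate id %d",
                 lineNo[dup[1]], nd$id[dup[1]]))
  dangling <- which(nd$parent != -1L & !(nd$parent %in% nd$id))
  if (length(dangling))
    stop(sprintf("SWC parse error at line %d: parent %d does not exist",
                 lineNo[dangling[1]], nd$parent[dangling[1]]))
  roots <- which(nd$parent == -1L)
  if (length(roots) != 1L)
    stop(sprintf("SWC file must contain exactly one root, found %d",
                 length(roots)))
  tr <- SwcTree(nd)
  v <- validObject(tr, test = TRUE)
  if (!isTRUE(v)) stop("SWC parse error: ", v)
  tr
}

#' Write a neuron morphology to an SWC file
#'
#' Coordinates and radii are printed with 4 decimal places, so a
#' write-then-read round trip is lossless to that precision and byte
#' deterministic.
#'
#' @param tree An [SwcTree-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSWC <- function(tree, path) {
  stopifnot(is(tree, "SwcTree"))
  nd <- swcNodes(tree)
  con <- file(path, open = "wb") # binary: fixed \n on every platform
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con, sep = "\n")
  if (nrow(nd))
    writeLines(sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                       nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent),
               con, sep = "\n")
  invisible(path)
}

#' Resample a tree to evenly spaced connective points
#'
#' Every parent-to-child segment is linearly interpolated at spacing at most
#' `step` voxels with both endpoints included, so consecutive points along a
#' segment are never more than `step` apart. Shared segment endpoints are
#' emitted once.
#'
#' @param tree An [SwcTree-class].
#' @param step Maximum spacing between consecutive points (voxels), > 0.
#' @return Numeric matrix with columns x, y, z (possibly 0 rows).
#' @examples
#' tr <- SwcTree(data.frame(id = 1:2, type = c(1L, 3L),
#'                          x = c(0, 3), y = 0, z = 0,
#'                          radius = 1, parent = c(-1L, 1L)))
#' resampleTree(tr, 1) # 4 points at x = 0,1,2,3
#' @export
resampleTree <- function(tree, step = 1.0) {
  stopifnot(is(tree, "SwcTree"), step > 0)
  nd <- swcNodes(tree)
  if (nrow(nd) == 0L)
    return(matrix(numeric(), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  pidx <- match(nd$parent, nd$id)
  pts <- list(as.matrix(rootNode(tree)[, c("x", "y", "z")]))
  children <- which(!is.na(pidx))
  for (i in children) {
    a <- c(nd$x[pidx[i]], nd$y[pidx[i]], nd$z[pidx[i]])
    b <- c(nd$x[i], nd$y[i], nd$z[i])
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq_len(n) / n # exclude the parent endpoint (emitted upstream)
    pts[[length(pts) + 1L]] <-
      cbind(a[1] + t * (b[1] - a[1]),
            a[2] + t * (b[2] - a[2]),
            a[3] + t * (b[3] - a[3]))
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y", "z")
  rownames(out) <- NULL
  out
}
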