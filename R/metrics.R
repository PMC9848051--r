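# Reconstruction-vs-gold spatial metrics. Both morphologies are resampled to
# 1-voxel connective point spacing before comparison, so "points" approximates
# "voxels". All metrics are directional: *12 runs gold-to-reconstruction
# (recall-like), *21 reconstruction-to-gold (precision-like), and the plain
# name is their average. Lower is better.

#' Nearest-neighbour distances between two point clouds
#'
#' For every row of `A`, the minimum Euclidean distance to any row of `B`.
#'
#' @param A,B Numeric matrices with columns x, y, z; `B` must be nonempty.
#' @return Numeric vector of length `nrow(A)`.
#' @export
nearestDistances <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(B) == 0L) stop("reference point set B is empty")
  if (nrow(A) == 0L) return(numeric())
  stopifnot(ncol(A) == 3L, ncol(B) == 3L)
  nearestDistCpp(A, B)
}

treePoints <- function(tree, resample = TRUE, step = 1.0) {
  if (is(tree, "SwcTree")) {
    if (resample) resampleTree(tree, step)
    else as.matrix(swcNodes(tree)[, c("x", "y", "z")])
  } else as.matrix(tree)
}

#' Spatial distance (SD) between two morphologies
#'
#' `sd12` is the mean nearest-point distance from gold to reconstruction,
#' `sd21` the reverse, `sd` their average.
#'
#' @param gold,recon [SwcTree-class] objects (or point matrices).
#' @param resample Resample trees to 1-voxel spacing first (default).
#' @param step Resampling step.
#' @return Named numeric vector `c(sd12, sd21, sd)`.
#' @export
sdMetrics <- function(gold, recon, resample = TRUE, step = 1.0) {
  A <- treePoints(gold, resample, step); B <- treePoints(recon, resample, step)
  sd12 <- mean(nearestDistances(A, B))
  sd21 <- mean(nearestDistances(B, A))
  c(sd12 = sd12, sd21 = sd21, sd = (sd12 + sd21) / 2)
}

#' Substantial spatial distance (SSD)
#'
#' Mean of nearest-point distances restricted to those larger than `thresh`
#' (2 voxels by default); 0 when no distance exceeds it — no substantial
#' discrepancy.
#'
#' @inheritParams sdMetrics
#' @param thresh Distance threshold in voxels.
#' @return Named numeric vector `c(ssd12, ssd21, ssd)`.
#' @export
ssdMetrics <- function(gold, recon, thresh = 2, resample = TRUE, step = 1.0) {
  A <- treePoints(gold, resample, step); B <- treePoints(recon, resample, step)
  f <- function(d) if (any(d > thresh)) mean(d[d > thresh]) else 0
  s12 <- f(nearestDistances(A, B))
  s21 <- f(nearestDistances(B, A))
  c(ssd12 = s12, ssd21 = s21, ssd = (s12 + s21) / 2)
}

#' Percentage of different structure (PDS)
#'
#' Fraction of points whose nearest-point distance exceeds `thresh`
#' (2 voxels by default).
#'
#' @inheritParams ssdMetrics
#' @return Named numeric vector `c(pds12, pds21, pds)`, each in \[0,1\].
#' @export
pdsMetrics <- function(gold, recon, thresh = 2, resample = TRUE, step = 1.0) {
  A <- treePoints(gold, resample, step); B <- treePoints(recon, resample, step)
  p12 <- mean(nearestDistances(A, B) > thresh)
  p21 <- mean(nearestDistances(B, A) > thresh)
  c(pds12 = p12, pds21 = p21, pds = (p12 + p21) / 2)
}

#' Recall stratified by image intensity
#'
#' Every resampled gold point counts as traced iff its nearest
#' reconstruction point lies within `matchRadius` voxels. Recall is reported
#' per intensity bin of the image value at the gold point, plus the pooled
#' recall over weak points (intensity below `weakThreshold`, default 20 on
#' the 8-bit scale).
#'
#' @inheritParams sdMetrics
#' @param image Intensity volume in \[0,1\] aligned with the coordinates.
#' @param breaks Bin edges on the normalized intensity scale.
#' @param matchRadius Match radius in voxels.
#' @param weakThreshold Weak-fiber threshold (normalized).
#' @return List with `table` (data.frame: bin edges, n, recall),
#'   `weakRecall`, `overallRecall`.
#' @export
recallByIntensity <- function(gold, recon, image,
                              breaks = c(seq(0, 250, by = 10), 260) / 255,
                              matchRadius = 2, weakThreshold = 20 / 255,
                              resample = TRUE, step = 1.0) {
  A <- treePoints(gold, resample, step)
  B <- treePoints(recon, resample, step)
  shape <- dim(image)
  vox <- round(A)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), shape[a] - 1)
  inten <- image[vox + 1]
  traced <- nearestDistances(A, B) <= matchRadius
  bin <- cut(inten, breaks = breaks, include.lowest = TRUE, right = FALSE)
  tab <- data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    n = as.integer(table(bin)),
    recall = as.numeric(tapply(traced, bin, mean))
  )
  weak <- inten < weakThreshold
  list(table = tab,
       weakRecall = if (any(weak)) mean(traced[weak]) else NA_real_,
       overallRecall = mean(traced))
}

#' Ratio of reconstruction cable length to gold cable length
#'
#' @inheritParams sdMetrics
#' @return Numeric scalar; 1 means equal total path length.
#' @export
pathLengthRatio <- function(gold, recon) {
  treePathLength(recon) / treePathLength(gold)
}

ancestorSets <- function(nd, generations) {
  pidx <- match(nd$parent, nd$id)
  lapply(seq_len(nrow(nd)), function(i) {
    anc <- integer(generations + 1L)
    cur <- i
    k <- 0L
    while (!is.na(cur) && k <= generations) {
      k <- k + 1L
      anc[k] <- cur
      cur <- pidx[cur]
    }
    anc[seq_len(k)]
  })
}

#' Count self-crossing node pairs of a morphology
#'
#' Pairs of topologically distant nodes of the same neuron passing within
#' `distThresh` voxels of each other — a driver of over-tracing. Nodes closer
#' than `somaExclusion` voxels to the root are excluded, as are pairs that
#' are related within `generationExclusion` generations (ancestor/descendant
#' or sharing a common ancestor within that horizon). An optional central
#' `crop` (x, y, z extent, centered on the root) restricts the counted nodes.
#'
#' @param tree An [SwcTree-class].
#' @param somaExclusion Radius around the root to ignore (voxels).
#' @param generationExclusion Topological kinship horizon (generations).
#' @param distThresh Spatial closeness threshold (voxels).
#' @param crop Optional (x, y, z) crop size centered on the root.
#' @return Integer count of qualifying unordered pairs.
#' @export
selfCrossingCount <- function(tree, somaExclusion = 50,
                              generationExclusion = 10, distThresh = 1,
                              crop = NULL) {
  nd <- swcNodes(tree)
  if (nrow(nd) < 2L) return(0L)
  r <- rootNode(tree)
  anc <- ancestorSets(nd, generationExclusion)
  dRoot <- sqrt((nd$x - r$x)^2 + (nd$y - r$y)^2 + (nd$z - r$z)^2)
  keep <- dRoot >= somaExclusion
  if (!is.null(crop)) {
    half <- crop / 2
    keep <- keep &
      abs(nd$x - r$x) <= half[1] &
      abs(nd$y - r$y) <= half[2] &
      abs(nd$z - r$z) <= half[3]
  }
  ki <- which(keep)
  if (length(ki) < 2L) return(0L)
  P <- cbind(nd$x[ki], nd$y[ki], nd$z[ki])
  count <- 0L
  for (a in seq_len(length(ki) - 1L)) {
    d2 <- (P[-seq_len(a), 1] - P[a, 1])^2 +
          (P[-seq_len(a), 2] - P[a, 2])^2 +
          (P[-seq_len(a), 3] - P[a, 3])^2
    close <- which(d2 < distThresh^2)
    for (b in close) {
      i <- ki[a]; j <- ki[a + b]
      if (!any(anc[[i]] %in% anc[[j]])) count <- count + 1L
    }
  }
  count
}

#' Full evaluation of a reconstruction against its gold standard
#'
#' Computes SD/SSD/PDS triplets, intensity-stratified recall (when an image
#' is supplied), the path-length ratio and the self-crossing count of the
#' reconstruction.
#'
#' @inheritParams sdMetrics
#' @param image Optional intensity volume for the recall stratification.
#' @param thresh SSD/PDS distance threshold (voxels).
#' @param matchRadius Recall match radius (voxels).
#' @param weakThreshold Weak-fiber intensity threshold (normalized).
#' @return A [MetricsReport-class].
#' @export
evaluatePair <- function(gold, recon, image = NULL, thresh = 2,
                         matchRadius = 2, weakThreshold = 20 / 255) {
  sdv <- sdMetrics(gold, recon)
  ssdv <- ssdMetrics(gold, recon, thresh)
  pdsv <- pdsMetrics(gold, recon, thresh)
  rec <- if (!is.null(image))
    recallByIntensity(gold, recon, image, matchRadius = matchRadius,
                      weakThreshold = weakThreshold)
  else list(table = data.frame(), weakRecall = NA_real_)
  new("MetricsReport",
      sd12 = unname(sdv["sd12"]), sd21 = unname(sdv["sd21"]), sd = unname(sdv["sd"]),
      ssd12 = unname(ssdv["ssd12"]), ssd21 = unname(ssdv["ssd21"]), ssd = unname(ssdv["ssd"]),
      pds12 = unname(pdsv["pds12"]), pds21 = unname(pdsv["pds21"]), pds = unname(pdsv["pds"]),
      recallByIntensity = rec$table,
      weakRecall = rec$weakRecall,
      pathLengthRatio = pathLengthRatio(gold, recon),
      nSelfCrossings = selfCrossingCount(recon))
}

#' Batch evaluation over gold/reconstruction pairs
#'
#' @param pairs List of lists with elements `gold`, `recon` and optional
#'   `image` (objects or file paths).
#' @param ... Passed to [evaluatePair()].
#' @return data.frame with one metrics row per pair plus `mean` and `sd`
#'   summary rows.
#' @export
evaluateBatch <- function(pairs, ...) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    gold <- if (is.character(p$gold)) readSWC(p$gold) else p$gold
    recon <- if (is.character(p$recon)) readSWC(p$recon) else p$recon
    image <- if (!is.null(p$image) && is.character(p$image)) readVolume(p$image) else p$image
    rep <- evaluatePair(gold, recon, image, ...)
    cbind(data.frame(pair = i), as.data.frame(metricsAsList(rep)))
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "pair"
  msum <- df[1, ]; msum$pair <- NA; msum[num] <- lapply(df[num], mean, na.rm = TRUE)
  ssum <- df[1, ]; ssum$pair <- NA; ssum[num] <- lapply(df[num], stats::sd, na.rm = TRUE)
  msum$summary <- "mean"; ssum$summary <- "sd"; df$summary <- ""
  rbind(df, msum, ssum)
}
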