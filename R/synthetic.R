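# Seeded synthetic fiber phantoms with the statistical structure of
# single-neuron light-microscopy crops: sparse branching tubular fibers of
# ~1-voxel radius, a bimodal (weak/strong) peak-intensity distribution, a
# bright soma, Gaussian background noise, oval plaque artifacts, and partial
# labels (some rendered fibers absent from the annotation).

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic scene configuration
#'
#' Defaults emulate a small crop of a sparsely labeled single-neuron volume:
#' a dim background (mean 0.01 on the unit scale) with Gaussian noise, about
#' a third of fibers "weak" (peak intensity below the 20/255 weak-fiber
#' threshold), the rest well above it, a bright soma, oval plaque artifacts,
#' and a fifth of the fibers present in the image but missing from the label.
#'
#' @param volume_shape Volume size (x, y, z).
#' @param n_fibers Number of fibers to grow.
#' @param weak_fraction Probability a fiber is weak.
#' @param weak_intensity_range,strong_intensity_range Peak-intensity ranges
#'   (normalized); the weak range sits below the weak threshold 20/255.
#' @param background_mean Background intensity.
#' @param noise_sigma Additive Gaussian noise s.d.
#' @param n_plaques Number of oval plaque artifacts.
#' @param plaque_amplitude,plaque_radius Ranges for plaque peak elevation and
#'   in-plane radius (voxels).
#' @param unlabeled_fraction Probability a fiber is left out of the label.
#' @param soma_position (x, y, z) or `NULL` for the volume center.
#' @param soma_radii Ellipsoid semi-axes for the rendered soma.
#' @param soma_intensity Rendered soma intensity.
#' @param radius_range Fiber tube radius range (voxels).
#' @param fiber_length_range Number of unit steps per fiber.
#' @param branch_prob Probability a fiber sprouts from an existing fiber
#'   instead of the soma.
#' @param max_turn_deg Per-step turning-angle cap (degrees).
#' @param weak_threshold Normalized weak-fiber intensity threshold.
#' @param rng_seed Integer seed; every generator draw flows from it.
#' @param ... Overrides appended verbatim.
#' @return A validated list of class `sceneConfig`.
#' @export
sceneConfig <- function(volume_shape = c(64, 64, 32),
                        n_fibers = 20,
                        weak_fraction = 0.3,
                        weak_intensity_range = c(0.04, 0.075),
                        strong_intensity_range = c(0.25, 0.9),
                        background_mean = 0.01,
                        noise_sigma = 0.01,
                        n_plaques = 2,
                        plaque_amplitude = c(0.08, 0.18),
                        plaque_radius = c(4, 8),
                        unlabeled_fraction = 0.2,
                        soma_position = NULL,
                        soma_radii = c(5, 5, 2.5),
                        soma_intensity = 0.9,
                        radius_range = c(1.0, 1.3),
                        fiber_length_range = c(15, 40),
                        branch_prob = 0.35,
                        max_turn_deg = 30,
                        weak_threshold = 20 / 255,
                        rng_seed = 0L,
                        ...) {
  cfg <- c(as.list(environment()), list(...))
  if (is.null(cfg$soma_position)) cfg$soma_position <- floor(cfg$volume_shape / 2)
  validateSceneConfig(cfg)
  class(cfg) <- c("sceneConfig", "list")
  cfg
}

validateSceneConfig <- function(cfg) {
  stopifnot(length(cfg$volume_shape) == 3L, all(cfg$volume_shape >= 1))
  for (f in c("weak_fraction", "unlabeled_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  for (f in c("weak_intensity_range", "strong_intensity_range")) {
    v <- cfg[[f]]
    if (any(v < 0) || any(v > 1)) stop(f, " must lie within [0, 1]")
  }
  if (any(cfg$soma_position < 0) || any(cfg$soma_position >= cfg$volume_shape))
    stop("soma_position must lie inside the volume")
  invisible(cfg)
}

#' Fiber specification
#'
#' One tubular fiber: an ordered 3D centerline (voxel units, consecutive
#' points at most 1.5 voxels apart), a tube radius, a normalized peak
#' intensity in (0, 1], and a `labeled` flag.
#'
#' @param centerline Numeric matrix (n >= 2 rows, columns x, y, z).
#' @param radius Tube radius in voxels.
#' @param peak_intensity Peak intensity in (0, 1].
#' @param labeled Is the fiber present in the annotation?
#' @param node_ids Optional SWC node ids of the centerline points.
#' @param parent_fiber Index of the fiber it sprouts from (0 = soma).
#' @return List of class `fiberSpec`.
#' @export
fiberSpec <- function(centerline, radius, peak_intensity, labeled = TRUE,
                      node_ids = integer(), parent_fiber = 0L) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L) stop("centerline needs at least 2 points")
  gaps <- sqrt(rowSums(diff(centerline)^2))
  if (any(gaps > 1.5 + 1e-9))
    stop("consecutive centerline points must be <= 1.5 voxels apart")
  if (peak_intensity <= 0 || peak_intensity > 1)
    stop("peak_intensity must lie in (0, 1]")
  structure(list(centerline = centerline, radius = radius,
                 peak_intensity = peak_intensity, labeled = labeled,
                 node_ids = as.integer(node_ids),
                 parent_fiber = as.integer(parent_fiber)),
            class = c("fiberSpec", "list"))
}

unitv <- function(v) v / sqrt(sum(v^2))

# rotate `dir` toward a random perturbation, capping the turn angle
jitterDirection <- function(dir, maxTurnRad) {
  cand <- unitv(dir + 0.4 * stats::rnorm(3))
  d <- sum(cand * dir)
  ang <- acos(min(1, max(-1, d)))
  if (ang <= maxTurnRad) return(cand)
  perp <- cand - d * dir
  if (sum(perp^2) < 1e-12) return(dir)
  unitv(cos(maxTurnRad) * dir + sin(maxTurnRad) * unitv(perp))
}

# grow the soma-rooted random-walk tree; returns list(tree, fibers)
growTree <- function(cfg) {
  shape <- cfg$volume_shape
  soma <- cfg$soma_position
  nodes <- data.frame(id = 1L, type = 1L, x = soma[1], y = soma[2], z = soma[3],
                      radius = max(cfg$soma_radii), parent = -1L)
  fibers <- list()
  if (cfg$n_fibers > 0 && any(shape < c(16, 16, 8)))
    stop("volume too small to place any fiber (need at least 16 x 16 x 8)")
  lo <- rep(1, 3); hi <- shape - 2 # keep clear of the faces for rendering
  nextId <- 2L
  for (f in seq_len(cfg$n_fibers)) {
    fromSoma <- length(fibers) == 0L || stats::runif(1) >= cfg$branch_prob
    if (fromSoma) {
      parentFiber <- 0L
      attachId <- 1L
      start <- soma
    } else {
      parentFiber <- sample.int(length(fibers), 1L)
      pf <- fibers[[parentFiber]]
      k <- sample.int(length(pf$node_ids), 1L)
      attachId <- pf$node_ids[k]
      start <- pf$centerline[k, ]
    }
    dir <- unitv(stats::rnorm(3))
    nSteps <- sample(cfg$fiber_length_range[1]:cfg$fiber_length_range[2], 1L)
    pts <- matrix(0, nrow = nSteps, ncol = 3)
    p <- start
    maxTurn <- cfg$max_turn_deg * pi / 180
    got <- 0L
    for (s in seq_len(nSteps)) {
      dir <- jitterDirection(dir, maxTurn)
      cand <- p + dir
      # reflect off the walls component-wise
      for (a in 1:3) {
        if (cand[a] < lo[a] || cand[a] > hi[a]) {
          dir[a] <- -dir[a]
          cand[a] <- p[a] + dir[a]
        }
      }
      cand <- pmin(pmax(cand, lo), hi)
      p <- cand
      got <- got + 1L
      pts[got, ] <- p
    }
    if (got < 2L) next
    pts <- pts[seq_len(got), , drop = FALSE]
    colnames(pts) <- c("x", "y", "z")
    weak <- stats::runif(1) < cfg$weak_fraction
    rng <- if (weak) cfg$weak_intensity_range else cfg$strong_intensity_range
    peak <- stats::runif(1, rng[1], rng[2])
    radius <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
    ids <- nextId:(nextId + got - 1L)
    nextId <- nextId + got
    nodes <- rbind(nodes,
                   data.frame(id = ids, type = 3L,
                              x = pts[, 1], y = pts[, 2], z = pts[, 3],
                              radius = radius,
                              parent = c(attachId, ids[-length(ids)])))
    fibers[[length(fibers) + 1L]] <-
      fiberSpec(pts, radius, peak, labeled = TRUE, node_ids = ids,
                parent_fiber = parentFiber)
  }
  list(tree = SwcTree(nodes, metadata = list(fibers = fibers, config = cfg)),
       fibers = fibers)
}

#' Generate a random soma-rooted fiber tree
#'
#' Fibers are bounded-turning-angle random walks sprouting from the soma or,
#' with probability `branch_prob`, from an existing fiber. All nodes stay
#' inside the volume. Deterministic given `cfg$rng_seed`. The generated
#' per-fiber specifications ([fiberSpec()]) are stored in the tree's
#' `metadata$fibers`.
#'
#' @param cfg A [sceneConfig()].
#' @return An [SwcTree-class]; with `n_fibers = 0` it holds only the soma.
#' @export
generateTree <- function(cfg) {
  validateSceneConfig(cfg)
  withSeed(cfg$rng_seed, growTree(cfg))$tree
}

gaussianStamp <- function(vol, center, sigmaXYZ, peak, cutoff = 3) {
  shape <- dim(vol)
  r <- ceiling(cutoff * sigmaXYZ)
  lo <- pmax(floor(center - r), 0)
  hi <- pmin(ceiling(center + r), shape - 1)
  if (any(hi < lo)) return(vol)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) / sigmaXYZ[1])^2
  dy2 <- ((ys - center[2]) / sigmaXYZ[2])^2
  dz2 <- ((zs - center[3]) / sigmaXYZ[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  blob <- peak * exp(-q / 2)
  sub <- vol[xs + 1, ys + 1, zs + 1, drop = FALSE]
  vol[xs + 1, ys + 1, zs + 1] <- pmax(sub, array(blob, dim(sub)))
  vol
}

# interpolate a polyline at `spacing` along its arc
densifyPolyline <- function(pts, spacing = 0.5) {
  if (nrow(pts) < 2L) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (i in 2:nrow(pts)) {
    a <- pts[i - 1, ]; b <- pts[i, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / spacing))
    t <- seq_len(n) / n
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Render fibers and soma into an intensity volume
#'
#' Each fiber is drawn as a tube with a Gaussian radial profile
#' (`sigma = radius / 1.5`, truncated at 3 sigma) at its peak intensity;
#' overlapping structures combine by maximum. The soma (if the tree has any
#' node) is drawn as a bright ellipsoid. The result sits on a constant
#' background and is clipped to \[0,1\]. No randomness.
#'
#' @param tree An [SwcTree-class] (possibly empty; only the root is used,
#'   to place the soma).
#' @param fibers List of [fiberSpec()]s.
#' @param cfg A [sceneConfig()].
#' @return Numeric array, dim `cfg$volume_shape`, values in \[0,1\].
#' @export
renderVolume <- function(tree, fibers, cfg) {
  vol <- array(cfg$background_mean, dim = cfg$volume_shape)
  for (fb in fibers) {
    sigma <- fb$radius / 1.5
    cl <- densifyPolyline(fb$centerline, spacing = 0.5)
    for (i in seq_len(nrow(cl)))
      vol <- gaussianStamp(vol, cl[i, ], rep(sigma, 3), fb$peak_intensity)
  }
  if (nNodes(tree) > 0L) {
    r <- rootNode(tree)
    cpos <- c(r$x, r$y, r$z)
    shape <- dim(vol)
    semi <- cfg$soma_radii
    lo <- pmax(floor(cpos - semi), 0); hi <- pmin(ceiling(cpos + semi), shape - 1)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    q <- outer(outer(((xs - cpos[1]) / semi[1])^2,
                     ((ys - cpos[2]) / semi[2])^2, "+"),
               ((zs - cpos[3]) / semi[3])^2, "+")
    sub <- vol[xs + 1, ys + 1, zs + 1, drop = FALSE]
    vol[xs + 1, ys + 1, zs + 1] <-
      pmax(sub, array(ifelse(q <= 1, cfg$soma_intensity, 0), dim(sub)))
  }
  clip01(vol)
}

# plaque placement with minimum-distance rejection so blobs stay disjoint
placePlaques <- function(cfg) {
  shape <- cfg$volume_shape
  centers <- matrix(numeric(), ncol = 3)
  radii <- list()
  attempts <- 0L
  while (nrow(centers) < cfg$n_plaques && attempts < 500L) {
    attempts <- attempts + 1L
    r <- c(stats::runif(2, cfg$plaque_radius[1], cfg$plaque_radius[2]),
           stats::runif(1, cfg$plaque_radius[1] / 2, cfg$plaque_radius[2] / 2))
    c0 <- c(stats::runif(1, r[1], shape[1] - 1 - r[1]),
            stats::runif(1, r[2], shape[2] - 1 - r[2]),
            stats::runif(1, r[3], shape[3] - 1 - r[3]))
    ok <- TRUE
    for (j in seq_along(radii)) {
      minSep <- max(r) + max(radii[[j]]) + 2
      if (sqrt(sum((c0 - centers[j, ])^2)) < minSep) { ok <- FALSE; break }
    }
    if (ok) {
      centers <- rbind(centers, c0)
      radii[[length(radii) + 1L]] <- r
    }
  }
  if (nrow(centers) < cfg$n_plaques)
    stop("could not place ", cfg$n_plaques, " disjoint plaques in this volume")
  list(centers = centers, radii = radii)
}

addArtifactsImpl <- function(vol, cfg) {
  if (cfg$n_plaques > 0) {
    pl <- placePlaques(cfg)
    for (j in seq_len(nrow(pl$centers))) {
      amp <- stats::runif(1, cfg$plaque_amplitude[1], cfg$plaque_amplitude[2])
      c0 <- pl$centers[j, ]; r <- pl$radii[[j]]
      shape <- dim(vol)
      lo <- pmax(floor(c0 - r), 0); hi <- pmin(ceiling(c0 + r), shape - 1)
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      q <- outer(outer(((xs - c0[1]) / r[1])^2, ((ys - c0[2]) / r[2])^2, "+"),
                 ((zs - c0[3]) / r[3])^2, "+")
      bump <- pmax(1 - q, 0) * amp
      vol[xs + 1, ys + 1, zs + 1] <- vol[xs + 1, ys + 1, zs + 1] +
        array(bump, dim(vol[xs + 1, ys + 1, zs + 1, drop = FALSE]))
    }
  }
  if (cfg$noise_sigma > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, cfg$noise_sigma), dim(vol))
  clip01(vol)
}

#' Add imaging artifacts: Gaussian noise and oval plaques
#'
#' Adds `n_plaques` smooth ellipsoidal intensity elevations (placed with a
#' minimum-separation rule so they form distinct blobs) and i.i.d. Gaussian
#' noise of s.d. `noise_sigma`, then clips to \[0,1\]. With
#' `noise_sigma = 0` and `n_plaques = 0` the input is returned unchanged.
#' Draws from the current RNG stream; seed upstream for determinism.
#'
#' @param vol Intensity volume in \[0,1\].
#' @param cfg A [sceneConfig()].
#' @return Volume of the same shape in \[0,1\].
#' @export
addArtifacts <- function(vol, cfg) {
  stopifnot(all(vol >= 0), all(vol <= 1))
  addArtifactsImpl(vol, cfg)
}

partialLabelsImpl <- function(tree, cfg) {
  fibers <- tree@metadata$fibers
  if (is.null(fibers)) stop("tree carries no fiber metadata; use generateTree()")
  nf <- length(fibers)
  drop <- stats::runif(nf) < cfg$unlabeled_fraction
  # a fiber sprouting from a dropped fiber is dropped too (labels stay a
  # connected subtree containing the soma)
  repeat {
    cascade <- vapply(seq_len(nf), function(i) {
      pf <- fibers[[i]]$parent_fiber
      !drop[i] && pf > 0L && drop[pf]
    }, logical(1))
    if (!any(cascade)) break
    drop[cascade] <- TRUE
  }
  for (i in seq_len(nf)) fibers[[i]]$labeled <- !drop[i]
  keepIds <- c(1L, unlist(lapply(fibers[!drop], `[[`, "node_ids")))
  nd <- swcNodes(tree)
  labeled <- SwcTree(nd[nd$id %in% keepIds, , drop = FALSE],
                     metadata = list(fibers = fibers[!drop], config = cfg))
  full <- SwcTree(nd, metadata = list(fibers = fibers, config = cfg))
  list(labeled = labeled, full = full)
}

#' Split a generated tree into labeled and full versions
#'
#' Each fiber is left out of the annotation with probability
#' `unlabeled_fraction` (descendant fibers of a dropped fiber are dropped
#' with it; the soma never is), emulating partially annotated gold standards.
#' The labeled tree is always a connected subtree of the full tree containing
#' the root. Draws from the current RNG stream.
#'
#' @param tree A tree from [generateTree()] (with fiber metadata).
#' @param cfg A [sceneConfig()].
#' @return List with `labeled` and `full` [SwcTree-class] objects; each
#'   fiber's `labeled` flag is updated in the metadata.
#' @export
makePartialLabels <- function(tree, cfg) partialLabelsImpl(tree, cfg)

#' Generate a complete synthetic scene
#'
#' Orchestrates [generateTree()], [renderVolume()], [addArtifacts()] and
#' [makePartialLabels()] under a single seed: identical configurations give
#' byte-identical scenes.
#'
#' @param cfg A [sceneConfig()].
#' @return List with `image` (noisy volume), `clean` (pre-artifact volume),
#'   `gold` (full tree), `labeled` (annotated subtree) and `config`.
#' @export
generateScene <- function(cfg) {
  validateSceneConfig(cfg)
  withSeed(cfg$rng_seed, {
    gt <- growTree(cfg)
    clean <- renderVolume(gt$tree, gt$fibers, cfg)
    image <- addArtifactsImpl(clean, cfg)
    pl <- partialLabelsImpl(gt$tree, cfg)
    list(image = image, clean = clean, gold = pl$full, labeled = pl$labeled,
         config = cfg)
  })
}

#' Write a scene to disk
#'
#' Writes `image.tif` (multi-page float TIFF), `gold.swc`, `labeled.swc` and
#' `config.yaml` into `dir`.
#'
#' @param scene Output of [generateScene()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(scene$image, file.path(dir, "image.tif"))
  writeSWC(scene$gold, file.path(dir, "gold.swc"))
  writeSWC(scene$labeled, file.path(dir, "labeled.swc"))
  cfg <- scene$config
  cfg$soma_position <- as.numeric(cfg$soma_position)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
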