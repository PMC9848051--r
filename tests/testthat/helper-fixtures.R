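# Shared fixtures, built in code. Heavy objects (scenes, a small trained
# checkpoint) are computed once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# simple hand-built trees -----------------------------------------------------

somaOnlyTree <- function(x = 10, y = 10, z = 5) {
  SwcTree(data.frame(id = 1L, type = 1L, x = x, y = y, z = z,
                     radius = 3, parent = -1L))
}

# a straight segment of given length along +x attached to a soma
lineTree <- function(len = 10, soma = c(5, 5, 5)) {
  n <- len + 1L
  SwcTree(data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1L)),
                     x = soma[1] + 0:(n - 1L), y = soma[2], z = soma[3],
                     radius = 1, parent = c(-1L, seq_len(n - 1L))))
}

# random valid tree: nodes attach to a uniformly chosen earlier node
randomTree <- function(n = 40, span = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- data.frame(id = 1L, type = 1L, x = span / 2, y = span / 2, z = span / 2,
                   radius = 1, parent = -1L)
  for (i in 2:n) {
    p <- sample.int(i - 1L, 1L)
    nd <- rbind(nd, data.frame(
      id = i, type = 3L,
      x = min(max(nd$x[p] + stats::rnorm(1), 0), span),
      y = min(max(nd$y[p] + stats::rnorm(1), 0), span),
      z = min(max(nd$z[p] + stats::rnorm(1), 0), span),
      radius = 1, parent = p))
  }
  SwcTree(nd)
}

# drop a fraction of leaf-most nodes (keeps validity): nested prunings
pruneTreeNodes <- function(tree, keepIds) {
  nd <- swcNodes(tree)
  keep <- nd$id %in% keepIds | nd$parent == -1L
  # close under ancestors
  repeat {
    need <- unique(nd$parent[keep & nd$parent != -1L])
    add <- nd$id %in% need & !keep
    if (!any(add)) break
    keep <- keep | add
  }
  SwcTree(nd[keep, , drop = FALSE])
}

# cached synthetic scenes -----------------------------------------------------

cachedScene <- function(seed, ...) {
  key <- paste0("scene_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateScene(sceneConfig(rng_seed = seed, ...))
  .fixtures[[key]]
}

# a small trained checkpoint shared by tracing/pipeline tests: 2 scenes,
# short schedule -- enough for the network to find the strong fibers
cachedTinyCheckpoint <- function() {
  if (is.null(.fixtures$tinyCkpt)) {
    scenes <- list(cachedScene(301), cachedScene(302))
    ds <- prepareDataset(scenes)
    .fixtures$tinyCkpt <- trainNetwork(
      ds, trainConfig(tiny = TRUE, iterations = 80L, seed = 11L))
  }
  .fixtures$tinyCkpt
}

# brute-force oracles ----------------------------------------------------------

# nearest distances by explicit per-point scan
oracleNearest <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min(colSums((t(B) - A[i, ])^2))), numeric(1))
}

# per-voxel label oracle: direct box-membership test against every point
oracleRasterize <- function(pts, shape, fiberWidth = c(3, 3, 1)) {
  lab <- array(0L, dim = shape)
  half <- (fiberWidth - 1) / 2
  cx <- array(rep(0:(shape[1] - 1), times = shape[2] * shape[3]), shape)
  cy <- array(rep(rep(0:(shape[2] - 1), each = shape[1]), times = shape[3]), shape)
  cz <- array(rep(0:(shape[3] - 1), each = shape[1] * shape[2]), shape)
  vox <- unique(round(pts))
  for (k in seq_len(nrow(vox))) {
    hit <- abs(cx - vox[k, 1]) <= half[1] &
           abs(cy - vox[k, 2]) <= half[2] &
           abs(cz - vox[k, 3]) <= half[3]
    lab[hit] <- 1L
  }
  lab
}
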