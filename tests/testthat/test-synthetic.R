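test_that("n_fibers = 0 yields a soma-only tree", {
  tr <- generateTree(sceneConfig(n_fibers = 0, rng_seed = 3))
  expect_equal(nNodes(tr), 1L)
  expect_equal(rootNode(tr)$type, 1L)
})

test_that("tree generation is deterministic: same seed, byte-identical SWC", {
  cfg <- sceneConfig(rng_seed = 7)
  p1 <- tempfile(fileext = ".swc"); p2 <- tempfile(fileext = ".swc")
  writeSWC(generateTree(cfg), p1)
  writeSWC(generateTree(cfg), p2)
  expect_identical(readBin(p1, "raw", 1e7), readBin(p2, "raw", 1e7))
})

test_that("node count for the frozen seed matches the recorded value", {
  tr <- generateTree(sceneConfig(n_fibers = 20, rng_seed = 7))
  expect_equal(nNodes(tr), 561L) # regression fixture, frozen once
})

test_that("all generated nodes lie inside the volume", {
  for (seed in c(1, 7, 42)) {
    cfg <- sceneConfig(rng_seed = seed)
    nd <- swcNodes(generateTree(cfg))
    expect_true(all(nd$x >= 0 & nd$x < cfg$volume_shape[1]))
    expect_true(all(nd$y >= 0 & nd$y < cfg$volume_shape[2]))
    expect_true(all(nd$z >= 0 & nd$z < cfg$volume_shape[3]))
  }
})

test_that("a volume too small for fibers is rejected", {
  expect_error(generateTree(sceneConfig(volume_shape = c(10, 10, 4),
                                        soma_position = c(5, 5, 2))),
               "too small")
})

test_that("rendering zero fibers with no noise gives a constant background", {
  cfg <- sceneConfig(background_mean = 0.05, noise_sigma = 0)
  vol <- renderVolume(new("SwcTree"), list(), cfg)
  expect_equal(vol, array(0.05, dim = cfg$volume_shape))
})

test_that("a rendered fiber peaks near its nominal intensity on the centerline", {
  cfg <- sceneConfig(background_mean = 0.01, noise_sigma = 0)
  cl <- cbind(x = seq(10, 50, by = 1), y = 32, z = 16)
  fb <- fiberSpec(cl, radius = 1, peak_intensity = 0.6)
  vol <- renderVolume(new("SwcTree"), list(fb), cfg)
  onCl <- vol[cbind(cl[, 1] + 1, cl[, 2] + 1, cl[, 3] + 1)]
  expect_gte(max(onCl), 0.5) # peak minus discretization loss
  # a weak fiber still rises above background along its centerline
  fbWeak <- fiberSpec(cl, radius = 1, peak_intensity = 0.06)
  volW <- renderVolume(new("SwcTree"), list(fbWeak), cfg)
  expect_gt(mean(volW[cbind(cl[, 1] + 1, cl[, 2] + 1, cl[, 3] + 1)]),
            cfg$background_mean)
})

test_that("every gold node sits on a voxel brighter than background (pre-noise)", {
  for (seed in c(11, 12)) {
    sc <- cachedScene(seed)
    nd <- swcNodes(sc$gold)
    vox <- cbind(round(nd$x), round(nd$y), round(nd$z)) + 1
    expect_true(all(sc$clean[vox] > sc$config$background_mean))
  }
})

test_that("artifact-free call returns the input unchanged", {
  cfg <- sceneConfig(noise_sigma = 0, n_plaques = 0)
  vol <- array(runif(prod(cfg$volume_shape)), cfg$volume_shape)
  expect_identical(addArtifacts(vol, cfg), vol)
})

test_that("noise sigma is honoured within 20% in a signal-free region", {
  cfg <- sceneConfig(noise_sigma = 0.02, n_plaques = 0,
                     background_mean = 0.5)
  vol <- array(0.5, cfg$volume_shape)
  set.seed(99)
  out <- addArtifacts(vol, cfg)
  s <- sd(out)
  expect_gt(s, 0.02 * 0.8)
  expect_lt(s, 0.02 * 1.2)
})

test_that("plaques form exactly n_plaques connected elevated blobs", {
  cfg <- sceneConfig(n_plaques = 3, noise_sigma = 0, background_mean = 0.05)
  vol <- array(0.05, cfg$volume_shape)
  set.seed(4)
  out <- addArtifacts(vol, cfg)
  elevated <- out > 0.05 + 1e-6
  lab <- NeuriteTrace:::ccLabel3d(as.logical(elevated), as.integer(dim(out)))
  expect_equal(max(lab), 3L)
})

test_that("unlabeled_fraction 0 and 1 are the exact edge cases", {
  sc <- cachedScene(13)
  cfg0 <- sc$config; cfg0$unlabeled_fraction <- 0
  set.seed(1)
  pl0 <- makePartialLabels(sc$gold, cfg0)
  expect_equal(swcNodes(pl0$labeled), swcNodes(pl0$full))
  cfg1 <- sc$config; cfg1$unlabeled_fraction <- 1
  set.seed(1)
  pl1 <- makePartialLabels(sc$gold, cfg1)
  expect_equal(nNodes(pl1$labeled), 1L) # soma only
})

test_that("half-unlabeled split keeps roughly half the cable length", {
  sc <- cachedScene(14)
  cfg <- sc$config; cfg$unlabeled_fraction <- 0.5
  set.seed(20)
  pl <- makePartialLabels(sc$gold, cfg)
  frac <- treePathLength(pl$labeled) / treePathLength(pl$full)
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})

test_that("labeled tree is a connected subgraph of gold containing the root", {
  for (seed in c(11, 12, 13)) {
    sc <- cachedScene(seed)
    ndL <- swcNodes(sc$labeled); ndG <- swcNodes(sc$gold)
    expect_true(all(ndL$id %in% ndG$id))
    m <- merge(ndL, ndG, by = "id")
    expect_equal(m$x.x, m$x.y)
    expect_equal(m$parent.x, m$parent.y)
    expect_true(1L %in% ndL$id)
    expect_true(isTRUE(validObject(sc$labeled, test = TRUE)))
  }
})

test_that("scene generation is fully deterministic per seed", {
  a <- generateScene(sceneConfig(rng_seed = 5))
  b <- generateScene(sceneConfig(rng_seed = 5))
  expect_identical(a$image, b$image)
  expect_identical(swcNodes(a$gold), swcNodes(b$gold))
  expect_identical(swcNodes(a$labeled), swcNodes(b$labeled))
})

test_that("weak_fraction controls the share of weak fibers", {
  sc <- generateScene(sceneConfig(rng_seed = 8, weak_fraction = 0.5,
                                  n_fibers = 40))
  peaks <- vapply(sc$gold@metadata$fibers, `[[`, numeric(1), "peak_intensity")
  weak <- mean(peaks < sc$config$weak_threshold)
  expect_gt(weak, 0.3)
  expect_lt(weak, 0.7)
})

test_that("fiber specs enforce their invariants", {
  expect_error(fiberSpec(matrix(c(0, 0, 0), 1), 1, 0.5), "at least 2")
  expect_error(fiberSpec(rbind(c(0, 0, 0), c(3, 0, 0)), 1, 0.5), "1.5 voxels")
  expect_error(fiberSpec(rbind(c(0, 0, 0), c(1, 0, 0)), 1, 0), "peak_intensity")
})

test_that("scenes round-trip through disk as TIFF + SWC + YAML", {
  sc <- cachedScene(11)
  dir <- tempfile("scene")
  writeScene(sc, dir)
  img <- readVolume(file.path(dir, "image.tif"))
  expect_equal(dim(img), dim(sc$image))
  expect_equal(img, sc$image, tolerance = 1e-6)
  gold <- readSWC(file.path(dir, "gold.swc"))
  expect_equal(nNodes(gold), nNodes(sc$gold))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$rng_seed, sc$config$rng_seed)
})
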