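test_that("nearest distances: identity, 3-4-5 case, empty reference error", {
  A <- matrix(runif(30), ncol = 3)
  expect_equal(nearestDistances(A, A), rep(0, 10))
  expect_equal(nearestDistances(matrix(c(0, 0, 0), 1),
                                matrix(c(3, 4, 0), 1)), 5)
  expect_error(nearestDistances(A, A[0, , drop = FALSE]), "empty")
})

test_that("nearest distances match the brute-force oracle", {
  set.seed(10)
  for (rep in 1:10) {
    A <- matrix(runif(3 * sample(5:500, 1), 0, 50), ncol = 3)
    B <- matrix(runif(3 * sample(5:500, 1), 0, 50), ncol = 3)
    expect_equal(nearestDistances(A, B), oracleNearest(A, B), tolerance = 1e-10)
  }
})

test_that("SD of identical trees is zero; single points give (5,5,5)", {
  tr <- randomTree(30, seed = 1)
  expect_equal(unname(sdMetrics(tr, tr)), c(0, 0, 0))
  A <- matrix(c(0, 0, 0), 1); B <- matrix(c(3, 4, 0), 1)
  expect_equal(unname(sdMetrics(A, B)), c(5, 5, 5))
})

test_that("SD averaging identity and symmetry hold", {
  g <- randomTree(40, seed = 2)
  r <- randomTree(40, seed = 3)
  m <- sdMetrics(g, r)
  expect_equal(unname(m["sd"]), unname((m["sd12"] + m["sd21"]) / 2))
  m2 <- sdMetrics(r, g)
  expect_equal(unname(m["sd"]), unname(m2["sd"]))
  expect_equal(unname(m["sd12"]), unname(m2["sd21"]))
})

test_that("pruning the reconstruction raises sd12 and keeps sd21 at zero", {
  g <- randomTree(60, seed = 4)
  ids <- swcNodes(g)$id
  sizes <- c(55, 40, 25, 10)
  prev <- -Inf
  for (k in sizes) {
    r <- pruneTreeNodes(g, ids[seq_len(k)])
    m <- sdMetrics(g, r)
    expect_gte(unname(m["sd12"]) + 1e-12, prev)
    prev <- unname(m["sd12"])
    expect_equal(unname(m["sd21"]), 0) # pruned copy: recon is a subset
  }
})

test_that("SSD keeps only distances beyond the threshold", {
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  B <- rbind(c(1, 0, 0), c(15, 0, 0)) # distances 1 and 5
  m <- ssdMetrics(A, B)
  expect_equal(unname(m["ssd12"]), 5)
  # all within threshold -> 0
  expect_equal(unname(ssdMetrics(A, rbind(c(1, 0, 0), c(9, 0, 0)))["ssd12"]), 0)
})

test_that("PDS is the fraction of distant points and stays in [0,1]", {
  A <- rbind(c(0, 0, 0), c(10, 0, 0))
  B <- rbind(c(1, 0, 0), c(15, 0, 0))
  expect_equal(unname(pdsMetrics(A, B)["pds12"]), 0.5)
  tr <- randomTree(30, seed = 5)
  m <- pdsMetrics(tr, randomTree(30, seed = 6))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(pdsMetrics(tr, tr)["pds"]), 0)
})

test_that("SSD/PDS match brute-force filtered oracles on random clouds", {
  set.seed(11)
  for (rep in 1:10) {
    A <- matrix(runif(3 * 80, 0, 30), ncol = 3)
    B <- matrix(runif(3 * 60, 0, 30), ncol = 3)
    d12 <- oracleNearest(A, B); d21 <- oracleNearest(B, A)
    m <- ssdMetrics(A, B)
    expect_equal(unname(m["ssd12"]),
                 if (any(d12 > 2)) mean(d12[d12 > 2]) else 0)
    expect_equal(unname(m["ssd21"]),
                 if (any(d21 > 2)) mean(d21[d21 > 2]) else 0)
    p <- pdsMetrics(A, B)
    expect_equal(unname(p["pds12"]), mean(d12 > 2))
    expect_equal(unname(p["pds21"]), mean(d21 > 2))
  }
})

test_that("metrics are invariant under a rigid translation of both trees", {
  g <- randomTree(40, seed = 7)
  r <- randomTree(35, seed = 8)
  shift <- function(tr, v) {
    nd <- swcNodes(tr)
    nd$x <- nd$x + v[1]; nd$y <- nd$y + v[2]; nd$z <- nd$z + v[3]
    SwcTree(nd)
  }
  v <- c(5.3, -2.1, 7.7)
  expect_equal(sdMetrics(g, r), sdMetrics(shift(g, v), shift(r, v)))
  expect_equal(pdsMetrics(g, r), pdsMetrics(shift(g, v), shift(r, v)))
})

test_that("intensity-stratified recall separates weak from strong points", {
  # gold has two branches; the reconstruction covers only the bright one
  soma <- c(20, 20, 10)
  nd <- data.frame(
    id = 1:21, type = c(1L, rep(3L, 20)),
    x = c(soma[1], soma[1] + 1:10, soma[1] - 1:10),
    y = soma[2], z = soma[3], radius = 1,
    parent = c(-1L, 1L, 2:10, 1L, 12:20))
  gold <- SwcTree(nd)
  recon <- SwcTree(nd[1:11, ]) # only the +x branch
  img <- array(0, c(40, 40, 20))
  # bright (50) near the soma and along the covered branch; weak (10) only on
  # the far part of the uncovered branch, > matchRadius from any recon point
  img[(soma[1] - 2):(soma[1] + 11) + 1, soma[2] + 1, soma[3] + 1] <- 50 / 255
  img[(soma[1] - 10):(soma[1] - 3) + 1, soma[2] + 1, soma[3] + 1] <- 10 / 255
  rec <- recallByIntensity(gold, recon, img, matchRadius = 2)
  expect_equal(rec$weakRecall, 0) # weak points entirely untraced
  strongBins <- rec$table[rec$table$bin_lo >= 20 / 255 & rec$table$n > 0, ]
  expect_true(all(strongBins$recall == 1))
  # recon == gold -> recall 1 in every nonempty bin
  full <- recallByIntensity(gold, gold, img)
  expect_true(all(full$table$recall[full$table$n > 0] == 1))
  expect_equal(full$overallRecall, 1)
})

test_that("path length ratio: identity, scaling and pruning", {
  g <- randomTree(40, seed = 9)
  expect_equal(pathLengthRatio(g, g), 1)
  nd <- swcNodes(g)
  nd$x <- nd$x * 2; nd$y <- nd$y * 2; nd$z <- nd$z * 2
  expect_equal(pathLengthRatio(g, SwcTree(nd)), 2)
  half <- pruneTreeNodes(g, swcNodes(g)$id[1:20])
  expect_equal(pathLengthRatio(g, half),
               treePathLength(half) / treePathLength(g))
})

test_that("a straight unbranched neurite has no self-crossings", {
  tr <- lineTree(200, soma = c(0, 5, 5))
  expect_equal(selfCrossingCount(tr), 0L)
})

test_that("two distant branches passing close together count one crossing", {
  # branch A runs along +x at y = 100; branch B descends vertically at
  # x = 80 and stops 0.45 voxels short of A -- exactly one unrelated pair
  # ends up closer than 1 voxel, far from the soma
  soma <- c(0, 100, 0)
  xsA <- 1:120
  a <- data.frame(id = 1 + seq_along(xsA), type = 3L, x = xsA, y = 100, z = 0,
                  radius = 1, parent = c(1L, 1 + seq_len(length(xsA) - 1)))
  ysB <- seq(160.45, 100.45, by = -1)
  b <- data.frame(id = 121 + seq_along(ysB), type = 3L, x = 80, y = ysB, z = 0,
                  radius = 1, parent = c(1L, 121 + seq_len(length(ysB) - 1)))
  nd <- rbind(data.frame(id = 1L, type = 1L, x = soma[1], y = soma[2],
                         z = soma[3], radius = 1, parent = -1L), a, b)
  tr <- SwcTree(nd)
  n <- selfCrossingCount(tr, somaExclusion = 50, generationExclusion = 10,
                         distThresh = 1)
  expect_equal(n, 1L)
})

test_that("self-crossing counts match the all-pairs oracle with exclusions", {
  oracleCrossings <- function(tree, somaEx, genEx, thresh) {
    nd <- swcNodes(tree)
    pidx <- match(nd$parent, nd$id)
    anc <- function(i) {
      out <- i; cur <- i
      for (k in seq_len(genEx)) {
        cur <- pidx[cur]
        if (is.na(cur)) break
        out <- c(out, cur)
      }
      out
    }
    r <- nd[nd$parent == -1L, ]
    keep <- sqrt((nd$x - r$x)^2 + (nd$y - r$y)^2 + (nd$z - r$z)^2) >= somaEx
    cnt <- 0L
    for (i in seq_len(nrow(nd) - 1)) for (j in (i + 1):nrow(nd)) {
      if (!keep[i] || !keep[j]) next
      d <- sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
                (nd$z[i] - nd$z[j])^2)
      if (d >= thresh) next
      if (length(intersect(anc(i), anc(j)))) next
      cnt <- cnt + 1L
    }
    cnt
  }
  set.seed(12)
  for (rep in 1:50) {
    tr <- randomTree(n = 35, span = 12)
    expect_equal(
      selfCrossingCount(tr, somaExclusion = 3, generationExclusion = 4,
                        distThresh = 1.5),
      oracleCrossings(tr, 3, 4, 1.5))
  }
})

test_that("evaluatePair of a tree against itself is the exact optimum", {
  sc <- cachedScene(101)
  mr <- evaluatePair(sc$gold, sc$gold, image = sc$image)
  expect_equal(mr@sd, 0)
  expect_equal(mr@ssd, 0)
  expect_equal(mr@pds, 0)
  expect_equal(mr@pathLengthRatio, 1)
  expect_true(is.na(mr@weakRecall) || mr@weakRecall == 1)
  expect_equal(mr@sd, (mr@sd12 + mr@sd21) / 2)
})

test_that("batch evaluation emits per-pair rows plus summary rows", {
  g <- randomTree(30, seed = 13)
  r <- pruneTreeNodes(g, swcNodes(g)$id[1:20])
  out <- evaluateBatch(list(list(gold = g, recon = r),
                            list(gold = g, recon = g)))
  expect_equal(nrow(out), 4) # 2 pairs + mean + sd
  expect_true(all(c("sd12", "pds", "path_length_ratio") %in% names(out)))
  expect_equal(out$summary, c("", "", "mean", "sd"))
  expect_equal(out$sd[3], mean(out$sd[1:2]))
})
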