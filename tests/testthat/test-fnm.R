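test_that("false negatives are exactly foreground with probability below 0.5", {
  F <- array(0, c(2, 2, 1)); F[1, 1, 1] <- 1; F[2, 1, 1] <- 1
  P <- array(0, c(2, 2, 1)); P[1, 1, 1] <- 0.4; P[2, 1, 1] <- 0.9
  fn <- extractFalseNegatives(F, P)
  expect_true(fn[1, 1, 1])
  expect_false(fn[2, 1, 1])
  expect_false(any(fn[F == 0]))
  # perfect foreground prediction leaves the set empty
  expect_false(any(extractFalseNegatives(F, array(1, dim(F)))))
  expect_error(extractFalseNegatives(F, array(0.5, c(3, 3, 1))), "shape")
  expect_error(extractFalseNegatives(F, F * 2), "\\[0, 1\\]")
})

test_that("FN extraction and the weighted loss match nested-loop oracles", {
  for (seed in 1:20) {
    set.seed(seed)
    dims <- c(2, 1, 8, 8, 8)
    F <- array(rbinom(prod(dims), 1, 0.3), dims)
    P <- array(runif(prod(dims)), dims)
    fn <- extractFalseNegatives(F, P)
    # brute-force 5-index loop
    ora <- array(FALSE, dims)
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
      for (l in 1:dims[4]) for (m in 1:dims[5])
        ora[i, j, k, l, m] <- F[i, j, k, l, m] == 1 && P[i, j, k, l, m] < 0.5
    expect_identical(fn, ora)
    w <- buildWeightMap(fn, 1.5)
    loss <- array(runif(prod(dims)), dims)
    got <- weightedVoxelLoss(loss, w)
    acc <- 0
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3])
      for (l in 1:dims[4]) for (m in 1:dims[5])
        acc <- acc + w[i, j, k, l, m] * loss[i, j, k, l, m]
    expect_equal(got, acc / prod(dims))
  }
})

test_that("weight map is wFN on FN and 1 elsewhere; FPs stay at 1", {
  fn <- array(FALSE, c(4, 4, 1))
  expect_equal(buildWeightMap(fn, 1.5), array(1, c(4, 4, 1)))
  fn[2, 3, 1] <- TRUE
  w <- buildWeightMap(fn, 1.5)
  expect_equal(w[2, 3, 1], 1.5)
  expect_equal(sum(w), prod(dim(w)) - 1 + 1.5)
  expect_error(buildWeightMap(fn, 0.5), ">= 1")
})

test_that("weighted loss arithmetic: single voxel and all-ones reduction", {
  expect_equal(weightedVoxelLoss(0.2, 1.5), 0.3)
  set.seed(1)
  l <- array(runif(64), c(4, 4, 4))
  expect_equal(weightedVoxelLoss(l, array(1, dim(l))), mean(l))
})

test_that("dice loss limits and hand-computed value", {
  F <- array(rbinom(4^3, 1, 0.4), c(4, 4, 4))
  expect_lt(diceLoss(F, F), 1e-4)
  expect_gt(diceLoss(1 - F, F), 0.999)
  set.seed(2)
  P <- array(runif(4^3), c(4, 4, 4))
  expect_equal(diceLoss(P, F),
               1 - 2 * sum(P * F) / (sum(P) + sum(F) + 1e-5))
})

test_that("aux weight 0 reduces deep supervision to the final head", {
  set.seed(3)
  net <- buildNetwork(2, 4)
  img <- array(runif(8^3), c(8, 8, 8))
  lab <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  fw <- netForward(net, img)
  both <- deepSupervisionLoss(fw, lab, auxWeight = 0)
  p <- NeuriteTrace:::softmax2(fw$final)[, 2]
  fnm <- extractFalseNegatives(array(as.numeric(lab)), array(p))
  w <- as.numeric(buildWeightMap(fnm, 1.5))
  f <- as.numeric(lab)
  ce <- -(f * log(pmax(p, 1e-12)) + (1 - f) * log(pmax(1 - p, 1e-12)))
  expect_equal(both$loss, diceLoss(p, f) + sum(w * ce) / length(f),
               tolerance = 1e-10)
})

test_that("perfect prediction: near-zero loss and FNM exactly a no-op", {
  lab <- array(0, c(8, 8, 8)); lab[3:5, 3:5, 4] <- 1
  # logits that imply probability ~1 on foreground, ~0 elsewhere
  f <- as.numeric(lab)
  big <- 20
  fake <- list(final = cbind((1 - f) * big, f * big),
               aux = NULL, dims = c(8, 8, 8), auxDims = c(4, 4, 4))
  fa <- NeuriteTrace:::downsampleLabelMax(f, c(8, 8, 8))
  fake$aux <- cbind((1 - fa) * big, fa * big)
  on <- deepSupervisionLoss(fake, lab, wFN = 1.5, fnm = TRUE)
  off <- deepSupervisionLoss(fake, lab, fnm = FALSE)
  expect_identical(on$loss, off$loss) # exact equality, not approximate
  expect_equal(on$nFN, 0L)
  expect_lt(on$loss, 1e-4)
})

test_that("raising wFN strictly increases the CE term iff FN is nonempty", {
  set.seed(4)
  net <- buildNetwork(2, 4)
  img <- array(runif(8^3), c(8, 8, 8))
  lab <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  fw <- netForward(net, img)
  l1 <- deepSupervisionLoss(fw, lab, wFN = 1.0)
  l2 <- deepSupervisionLoss(fw, lab, wFN = 1.5)
  l3 <- deepSupervisionLoss(fw, lab, wFN = 2.0)
  expect_gt(l2$nFN, 0)
  expect_gt(l2$ce, l1$ce)
  expect_gt(l3$ce, l2$ce)
  expect_equal(l1$dice, l2$dice) # dice is unweighted by default
  # with an empty FN set the CE term is flat in wFN
  lab0 <- array(0, c(8, 8, 8))
  e1 <- deepSupervisionLoss(fw, lab0, wFN = 1.0)
  e2 <- deepSupervisionLoss(fw, lab0, wFN = 2.0)
  expect_identical(e1$ce, e2$ce)
})

test_that("training reduces the loss on a small synthetic problem", {
  sc <- cachedScene(301)
  ds <- prepareDataset(list(sc))
  cfg <- trainConfig(tiny = TRUE, iterations = 40L, crop = c(16, 16, 16),
                     seed = 2L)
  ck <- trainNetwork(ds, cfg)
  expect_equal(nrow(ck$log), 40L)
  expect_lt(mean(tail(ck$log$loss, 5)), ck$log$loss[1])
})

test_that("wFN = 1 training is bit-identical to the FNM-disabled baseline", {
  sc <- cachedScene(301)
  ds <- prepareDataset(list(sc))
  base <- trainConfig(tiny = TRUE, iterations = 5L, crop = c(16, 16, 16),
                      seed = 7L)
  cfgA <- base; cfgA$fnm <- TRUE; cfgA$w_fn <- 1.0
  cfgB <- base; cfgB$fnm <- FALSE
  a <- trainNetwork(ds, cfgA)
  b <- trainNetwork(ds, cfgB)
  expect_identical(a$net$params, b$net$params)
  expect_identical(a$log$loss, b$log$loss)
})

test_that("default configuration carries the reference hyperparameters", {
  cfg <- trainConfig()
  expect_equal(cfg$lr, 0.01)
  expect_equal(cfg$momentum, 0.99)
  expect_equal(cfg$weight_decay, 3e-5)
  expect_equal(cfg$iterations, 15200L)
  expect_equal(cfg$crop, c(160, 160, 128))
  expect_equal(cfg$w_fn, 1.5)
})

test_that("degenerate training inputs are rejected", {
  expect_error(trainNetwork(list(), trainConfig(tiny = TRUE)), "empty")
  sc <- cachedScene(301)
  ds <- prepareDataset(list(sc))
  cfg <- trainConfig(tiny = TRUE, crop = c(128, 128, 128))
  expect_error(trainNetwork(ds, cfg), "crop larger")
})
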