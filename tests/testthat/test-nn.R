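test_that("network output matches the input shape with 2 channels", {
  set.seed(1)
  net <- buildNetwork(2, 8)
  img <- array(0.5, c(16, 16, 16))
  fw <- netForward(net, img)
  expect_equal(dim(fw$final), c(16^3, 2))
  expect_equal(dim(fw$aux), c(8^3, 2))
  p <- forwardProbability(fw)
  expect_equal(dim(p), c(16, 16, 16))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("tiny-mode parameter count matches the recorded value", {
  set.seed(1)
  expect_equal(parameterCount(buildNetwork(2, 8)), 21204L)
})

test_that("inputs that do not fit the stride budget are rejected", {
  set.seed(1)
  net <- buildNetwork(3, 4)
  expect_error(netForward(net, array(0, c(10, 10, 10))), "divisible")
  expect_error(netForward(net, array(0, c(4, 4, 4))), "too small")
})

test_that("flipping input and unflipping output changes shape consistently only", {
  # no equivariance guarantee is made; the contract is shape, not values
  set.seed(2)
  net <- buildNetwork(2, 4)
  img <- array(runif(16^3), c(16, 16, 16))
  p1 <- forwardProbability(netForward(net, img))
  p2 <- forwardProbability(netForward(net, img[16:1, , ]))
  expect_equal(dim(p1), dim(p2))
})

test_that("analytic gradients match finite differences", {
  set.seed(2)
  net <- buildNetwork(2, 4)
  img <- array(runif(8^3), c(8, 8, 8))
  lab <- array(rbinom(8^3, 1, 0.2), c(8, 8, 8))
  lossOf <- function(n) deepSupervisionLoss(netForward(n, img), lab,
                                            fnm = FALSE)$loss
  fw <- netForward(net, img, withCache = TRUE)
  ls <- deepSupervisionLoss(fw, lab, fnm = FALSE, withGrad = TRUE)
  g <- NeuriteTrace:::netBackward(net, fw, ls$dFinal, ls$dAux)
  eps <- 1e-6
  for (nm in c("headF.W", "headA.b", "enc1.W1", "enc2.W2", "dec1.Wu",
               "dec1.W1", "enc1.g1", "enc2.be2")) {
    p <- net$params[[nm]]
    i <- sample(length(p), 1)
    up <- net; up$params[[nm]][i] <- p[i] + eps
    dn <- net; dn$params[[nm]][i] <- p[i] - eps
    fd <- (lossOf(up) - lossOf(dn)) / (2 * eps)
    expect_equal(unname(g[[nm]][i]), fd, tolerance = 1e-4, label = nm)
  }
})

test_that("fused convolution agrees with the im2col reference", {
  set.seed(3)
  for (rep in 1:3) {
    dims <- sample(3:7, 3, replace = TRUE)
    ci <- sample(1:3, 1); co <- sample(1:3, 1)
    x <- matrix(rnorm(prod(dims) * ci), ncol = ci)
    W <- matrix(rnorm(27 * ci * co), 27 * ci, co)
    ref <- NeuriteTrace:::im2col3(x, as.integer(dims)) %*% W
    expect_equal(NeuriteTrace:::conv3fwd(x, as.integer(dims), W), ref,
                 tolerance = 1e-12)
    dy <- matrix(rnorm(prod(dims) * co), ncol = co)
    expect_equal(NeuriteTrace:::conv3bwdData(dy, as.integer(dims), W),
                 NeuriteTrace:::col2im3(dy %*% t(W), as.integer(dims)),
                 tolerance = 1e-12)
    expect_equal(NeuriteTrace:::conv3dW(x, dy, as.integer(dims)),
                 crossprod(NeuriteTrace:::im2col3(x, as.integer(dims)), dy),
                 tolerance = 1e-12)
  }
})

test_that("augmentation with zero probabilities is the identity", {
  img <- array(runif(8^3), c(8, 8, 8))
  lab <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  aug <- list(flip_p = 0, gamma_p = 0, gamma_range = c(0.7, 1.4),
              noise_p = 0, noise_sigma_max = 0.05,
              resize_p = 0, resize_range = c(0.8, 1.2))
  out <- augmentSample(img, lab, aug)
  expect_identical(out$image, img)
  expect_identical(out$label, lab)
})

test_that("double flip along one axis is the identity", {
  img <- array(runif(6 * 8 * 4), c(6, 8, 4))
  for (axis in 1:3)
    expect_identical(NeuriteTrace:::flipAxis(NeuriteTrace:::flipAxis(img, axis),
                                             axis), img)
})

test_that("labels stay binary under any augmentation", {
  set.seed(6)
  img <- array(runif(16^3), c(16, 16, 16))
  lab <- array(rbinom(16^3, 1, 0.3), c(16, 16, 16))
  aug <- list(flip_p = 0.5, gamma_p = 1, gamma_range = c(0.7, 1.4),
              noise_p = 1, noise_sigma_max = 0.05,
              resize_p = 1, resize_range = c(0.8, 1.2))
  for (i in 1:10) {
    out <- augmentSample(img, lab, aug)
    expect_true(all(out$label %in% c(0, 1)))
    expect_equal(dim(out$image), dim(img))
  }
})

test_that("tiling machinery is exact without normalization", {
  # instance norm computes per-window statistics, so only a norm-free network
  # can make tiled == untiled a strict identity
  set.seed(4)
  net <- buildNetwork(2, 4, norm = "none")
  vol <- array(runif(48 * 32 * 32), c(48, 32, 32))
  whole <- forwardProbability(netForward(net, vol))
  tiled <- predictVolume(net, vol, tile = c(32, 32, 32), overlap = 24)
  expect_lt(max(abs(whole - tiled)), 1e-6)
})

test_that("tile covering the whole volume equals a single forward pass", {
  set.seed(5)
  net <- buildNetwork(2, 4)
  vol <- array(runif(16^3), c(16, 16, 16))
  direct <- forwardProbability(netForward(net, vol))
  tiled <- predictVolume(net, vol, tile = c(16, 16, 16))
  expect_equal(tiled, direct)
})

test_that("tiled probabilities stay within [0,1] and cover padded volumes", {
  set.seed(5)
  net <- buildNetwork(2, 4)
  vol <- array(runif(20 * 24 * 12), c(20, 24, 12)) # smaller than the tile
  p <- predictVolume(net, vol, tile = c(32, 32, 32))
  expect_equal(dim(p), dim(vol))
  expect_true(all(p >= 0 & p <= 1))
})
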