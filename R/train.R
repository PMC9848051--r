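#' Training configuration
#'
#' The full-scale profile is the reference training recipe: Nesterov SGD with
#' initial learning rate 0.01, momentum 0.99, weight decay 3e-5, 15 200
#' iterations, (160 x 160 x 128) crops (x, y, z), deep supervision on the
#' last two blocks and false-negative weight 1.5. `tiny = TRUE` switches to
#' a 2-level / 8-channel network, 32^3 crops and 200 iterations, sized for
#' single-CPU experiments on synthetic scenes.
#'
#' @param tiny Use the reduced CPU profile.
#' @param ... Field overrides (see Details).
#' @details Fields: `lr`, `momentum`, `weight_decay`, `iterations`, `crop`
#'   (x, y, z), `w_fn`, `fnm`, `levels`, `base_channels`, `batch_size`,
#'   `poly_power`, `aux_weight`, `weighted_dice`, `norm`, `seed`, and the
#'   augmentation block `aug` (probabilities and ranges for flips, gamma
#'   jitter, Gaussian noise and resizing).
#' @return List of class `trainConfig`.
#' @export
trainConfig <- function(tiny = FALSE, ...) {
  cfg <- list(
    lr = 0.01, momentum = 0.99, weight_decay = 3e-5,
    iterations = 15200L, crop = c(160, 160, 128),
    w_fn = 1.5, fnm = TRUE,
    levels = 4L, base_channels = 16L, batch_size = 1L,
    poly_power = 0.9, aux_weight = 0.5, weighted_dice = FALSE,
    norm = "instance", seed = 1L,
    aug = list(flip_p = 0.5, gamma_p = 0.3, gamma_range = c(0.7, 1.4),
               noise_p = 0.3, noise_sigma_max = 0.05,
               resize_p = 0.2, resize_range = c(0.8, 1.2))
  )
  if (tiny) {
    cfg$levels <- 2L; cfg$base_channels <- 8L
    cfg$crop <- c(32, 32, 32); cfg$iterations <- 200L
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (cfg$w_fn < 1) stop("w_fn must be >= 1")
  class(cfg) <- c("trainConfig", "list")
  cfg
}

randomCrop <- function(image, label, crop) {
  shape <- dim(image)
  if (any(crop > shape)) stop("crop larger than the image")
  lo <- vapply(1:3, function(a)
    if (shape[a] == crop[a]) 1L else sample.int(shape[a] - crop[a] + 1L, 1L),
    integer(1))
  ix <- lo[1]:(lo[1] + crop[1] - 1L)
  iy <- lo[2]:(lo[2] + crop[2] - 1L)
  iz <- lo[3]:(lo[3] + crop[3] - 1L)
  list(image = image[ix, iy, iz, drop = FALSE],
       label = label[ix, iy, iz, drop = FALSE])
}

flipAxis <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

resizeNearest <- function(a, scale) {
  d <- dim(a)
  # sample the input on a grid scaled about the crop center; output keeps
  # the original size, nearest-neighbour for both image and label
  idx <- lapply(1:3, function(ax) {
    c0 <- (d[ax] + 1) / 2
    i <- round(c0 + (seq_len(d[ax]) - c0) / scale)
    pmin(pmax(i, 1L), d[ax])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Randomly augment an (image, label) training pair
#'
#' Random per-axis flips, gamma jitter (image only), additive Gaussian noise
#' (image only) and nearest-neighbour resizing, each applied with its
#' configured probability. Geometric transforms are applied identically to
#' image and label; the label stays strictly binary. All probabilities set
#' to zero return the pair unchanged.
#'
#' @param image,label Aligned 3D arrays (label binary).
#' @param aug Augmentation settings (see [trainConfig()]).
#' @return List with augmented `image` and `label`.
#' @export
augmentSample <- function(image, label, aug) {
  for (axis in 1:3) {
    if (stats::runif(1) < aug$flip_p) {
      image <- flipAxis(image, axis)
      label <- flipAxis(label, axis)
    }
  }
  if (stats::runif(1) < aug$resize_p) {
    s <- stats::runif(1, aug$resize_range[1], aug$resize_range[2])
    image <- resizeNearest(image, s)
    label <- resizeNearest(label, s)
  }
  if (stats::runif(1) < aug$gamma_p) {
    g <- stats::runif(1, aug$gamma_range[1], aug$gamma_range[2])
    image <- clip01(image)^g
  }
  if (stats::runif(1) < aug$noise_p) {
    s <- stats::runif(1, 0, aug$noise_sigma_max)
    image <- clip01(image + array(stats::rnorm(length(image), 0, s), dim(image)))
  }
  list(image = image, label = label)
}

# one Nesterov SGD step (PyTorch convention) with L2 weight decay
sgdStep <- function(params, grads, state, lr, momentum, wd) {
  for (nm in names(params)) {
    g <- grads[[nm]] + wd * params[[nm]]
    v <- momentum * state[[nm]] + g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (g + momentum * v)
  }
  list(params = params, state = state)
}

#' Train the segmentation network with online false-negative mining
#'
#' The iteration loop: sample a scene, crop, augment, forward, extract the
#' false-negative set from the current final-head prediction, build the
#' weight map, compute the deep-supervision loss (dice + FN-weighted
#' cross-entropy on both heads), backpropagate, and take a Nesterov SGD step
#' under polynomial learning-rate decay `lr0 * (1 - it/iters)^power`.
#' Deterministic given `cfg$seed`. With `cfg$fnm = FALSE` (or `w_fn = 1`)
#' the run is the unweighted baseline.
#'
#' @param dataset List of samples, each a list with `image` (enhanced,
#'   \[0,1\]) and `label` (binary) arrays of equal shape.
#' @param cfg A [trainConfig()].
#' @param logPath Optional CSV path for the per-iteration loss log.
#' @return List of class `checkpoint`: `net`, `cfg`, `log` (data.frame with
#'   iteration, lr, loss, dice, ce, n_fn).
#' @export
trainNetwork <- function(dataset, cfg = trainConfig(tiny = TRUE), logPath = NULL) {
  if (!length(dataset)) stop("empty dataset")
  for (s in dataset)
    if (any(dim(s$image) < cfg$crop)) stop("crop larger than an image in the dataset")
  withSeed(cfg$seed, {
    net <- buildNetwork(cfg$levels, cfg$base_channels, 1, 2, norm = cfg$norm)
    state <- lapply(net$params, function(p) p * 0)
    logRows <- vector("list", cfg$iterations)
    for (it in seq_len(cfg$iterations)) {
      lr <- cfg$lr * (1 - (it - 1) / cfg$iterations)^cfg$poly_power
      grads <- NULL
      lossAcc <- diceAcc <- ceAcc <- 0; fnAcc <- 0L
      for (b in seq_len(cfg$batch_size)) {
        s <- dataset[[sample.int(length(dataset), 1L)]]
        cr <- randomCrop(s$image, s$label, cfg$crop)
        au <- augmentSample(cr$image, cr$label, cfg$aug)
        fw <- netForward(net, au$image, withCache = TRUE)
        ls <- deepSupervisionLoss(fw, au$label, wFN = cfg$w_fn, fnm = cfg$fnm,
                                  auxWeight = cfg$aux_weight,
                                  weightedDice = cfg$weighted_dice,
                                  withGrad = TRUE)
        g <- netBackward(net, fw, ls$dFinal, ls$dAux)
        grads <- if (is.null(grads)) g else
          stats::setNames(lapply(names(g), function(nm) grads[[nm]] + g[[nm]]),
                          names(g))
        lossAcc <- lossAcc + ls$loss; diceAcc <- diceAcc + ls$dice
        ceAcc <- ceAcc + ls$ce; fnAcc <- fnAcc + ls$nFN
      }
      if (cfg$batch_size > 1)
        grads <- lapply(grads, function(g) g / cfg$batch_size)
      up <- sgdStep(net$params, grads, state, lr, cfg$momentum, cfg$weight_decay)
      net$params <- up$params; state <- up$state
      logRows[[it]] <- data.frame(iteration = it, lr = lr,
                                  loss = lossAcc / cfg$batch_size,
                                  dice = diceAcc / cfg$batch_size,
                                  ce = ceAcc / cfg$batch_size,
                                  n_fn = fnAcc)
    }
    log <- do.call(rbind, logRows)
    if (!is.null(logPath)) utils::write.csv(log, logPath, row.names = FALSE)
    structure(list(net = net, cfg = cfg, log = log), class = c("checkpoint", "list"))
  })
}

#' Save / load a training checkpoint
#'
#' Single-file serialized weights plus the configuration snapshot.
#'
#' @param ckpt A checkpoint from [trainNetwork()].
#' @param path File path (`.rds`).
#' @return `loadCheckpoint` returns the checkpoint; `saveCheckpoint` the path.
#' @export
saveCheckpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "checkpoint")) stop("not a checkpoint file: ", path)
  ckpt
}
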