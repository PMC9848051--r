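# A compact vanilla 3D U-Net: symmetric encoder-decoder with skip
# connections, two 3x3x3 conv + instance-norm + ReLU layers per block,
# 2x2x2 max pooling, nearest-neighbour upsampling followed by a 3x3x3 conv,
# and two 2-channel output heads (final block, plus the preceding block for
# deep supervision). Parameters live in a flat named list; gradients mirror
# the names exactly.

chAt <- function(base, l) as.integer(base * 2^(l - 1))

#' Build a 3D encoder-decoder segmentation network
#'
#' Weights are He-initialized from the current RNG stream (seed upstream for
#' reproducibility). `levels = 4, baseChannels = 16` is the full-scale
#' default; `levels = 2, baseChannels = 8` is the tiny CPU profile used by
#' the tests. Instance normalization precedes every nonlinearity;
#' `norm = "none"` disables it (useful to verify tiling exactness).
#'
#' @param levels Number of resolution levels, >= 2.
#' @param baseChannels Channels of the first level (doubled per level).
#' @param inChannels,outChannels Input / output channel counts.
#' @param norm `"instance"` or `"none"`.
#' @return A network object (list with `arch` and flat `params`).
#' @export
buildNetwork <- function(levels = 4, baseChannels = 16, inChannels = 1,
                         outChannels = 2, norm = c("instance", "none")) {
  norm <- match.arg(norm)
  stopifnot(levels >= 2)
  P <- list()
  convInit <- function(cin, cout)
    matrix(stats::rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
           nrow = 27 * cin, ncol = cout)
  addBlock <- function(prefix, cin, cout) {
    P[[paste0(prefix, ".W1")]] <<- convInit(cin, cout)
    P[[paste0(prefix, ".b1")]] <<- numeric(cout)
    P[[paste0(prefix, ".g1")]] <<- rep(1, cout)
    P[[paste0(prefix, ".be1")]] <<- numeric(cout)
    P[[paste0(prefix, ".W2")]] <<- convInit(cout, cout)
    P[[paste0(prefix, ".b2")]] <<- numeric(cout)
    P[[paste0(prefix, ".g2")]] <<- rep(1, cout)
    P[[paste0(prefix, ".be2")]] <<- numeric(cout)
  }
  for (l in seq_len(levels)) {
    cin <- if (l == 1) inChannels else chAt(baseChannels, l - 1)
    addBlock(paste0("enc", l), cin, chAt(baseChannels, l))
  }
  for (l in seq_len(levels - 1)) {
    P[[paste0("dec", l, ".Wu")]] <- convInit(chAt(baseChannels, l + 1), chAt(baseChannels, l))
    P[[paste0("dec", l, ".bu")]] <- numeric(chAt(baseChannels, l))
    addBlock(paste0("dec", l), 2 * chAt(baseChannels, l), chAt(baseChannels, l))
  }
  c1 <- chAt(baseChannels, 1); c2 <- chAt(baseChannels, 2)
  P[["headF.W"]] <- matrix(stats::rnorm(c1 * outChannels, sd = sqrt(2 / c1)), c1, outChannels)
  P[["headF.b"]] <- numeric(outChannels)
  P[["headA.W"]] <- matrix(stats::rnorm(c2 * outChannels, sd = sqrt(2 / c2)), c2, outChannels)
  P[["headA.b"]] <- numeric(outChannels)
  structure(list(arch = list(levels = levels, baseChannels = baseChannels,
                             inChannels = inChannels, outChannels = outChannels,
                             norm = norm),
                 params = P),
            class = c("unet3d", "list"))
}

#' Number of trainable parameters
#'
#' @param net A network from [buildNetwork()].
#' @return Integer parameter count.
#' @export
parameterCount <- function(net) sum(vapply(net$params, length, integer(1)))

blockForward <- function(P, prefix, x, dims, norm) {
  g <- function(s) P[[paste0(prefix, ".", s)]]
  c1 <- convForward(x, dims, g("W1"), g("b1"))
  n1 <- if (norm == "instance") inormForward(c1$y, g("g1"), g("be1")) else list(y = c1$y)
  r1 <- reluForward(n1$y)
  c2 <- convForward(r1$y, dims, g("W2"), g("b2"))
  n2 <- if (norm == "instance") inormForward(c2$y, g("g2"), g("be2")) else list(y = c2$y)
  r2 <- reluForward(n2$y)
  list(y = r2$y,
       cache = list(c1 = c1, n1 = n1, r1 = r1, c2 = c2, n2 = n2, r2 = r2,
                    cin = ncol(x)))
}

blockBackward <- function(dy, cache, P, prefix, dims, norm, G) {
  g <- function(s) P[[paste0(prefix, ".", s)]]
  acc <- function(s, v) {
    nm <- paste0(prefix, ".", s)
    G[[nm]] <- if (is.null(G[[nm]])) v else G[[nm]] + v
  }
  d <- reluBackward(dy, cache$r2)
  if (norm == "instance") {
    nb <- inormBackward(d, cache$n2, g("g2"))
    acc("g2", nb$dg); acc("be2", nb$db)
    d <- nb$dx
  }
  cb <- convBackward(d, cache$c2, g("W2"), dims, ncol(cache$c2$y))
  acc("W2", cb$dW); acc("b2", cb$db)
  d <- reluBackward(cb$dx, cache$r1)
  if (norm == "instance") {
    nb <- inormBackward(d, cache$n1, g("g1"))
    acc("g1", nb$dg); acc("be1", nb$db)
    d <- nb$dx
  }
  cb <- convBackward(d, cache$c1, g("W1"), dims, cache$cin)
  acc("W1", cb$dW); acc("b1", cb$db)
  cb$dx
}

#' Forward pass of the segmentation network
#'
#' @param net A network from [buildNetwork()].
#' @param img 3D array (x, y, z) or [N, C] matrix of input intensities; each
#'   spatial dimension must be divisible by `2^(levels - 1)`.
#' @param dims Spatial dims (x, y, z); taken from `dim(img)` for arrays.
#' @param withCache Keep intermediate activations (needed for backprop).
#' @return List with `final` (`[N, 2]` logits at full resolution), `aux`
#'   (logits of the deep-supervision head at half resolution), `dims`,
#'   `auxDims`, and (optionally) `cache`.
#' @export
netForward <- function(net, img, dims = NULL, withCache = FALSE) {
  if (is.null(dims)) {
    stopifnot(length(dim(img)) == 3L)
    dims <- dim(img)
    img <- matrix(as.numeric(img), ncol = net$arch$inChannels)
  }
  L <- net$arch$levels
  if (any(dims %% 2^(L - 1) != 0))
    stop("input dims (", paste(dims, collapse = "x"),
         ") must be divisible by ", 2^(L - 1))
  if (any(dims / 2^(L - 1) < 2))
    stop("input too small for ", L, " resolution levels")
  P <- net$params; norm <- net$arch$norm
  d <- vector("list", L); d[[1]] <- as.integer(dims)
  enc <- vector("list", L); pools <- vector("list", L)
  x <- img
  for (l in seq_len(L)) {
    if (l > 1) {
      pl <- maxpool3(enc[[l - 1]]$y, d[[l - 1]])
      pools[[l]] <- pl
      d[[l]] <- d[[l - 1]] %/% 2L
      x <- pl$y
    }
    enc[[l]] <- blockForward(P, paste0("enc", l), x, d[[l]], norm)
  }
  dec <- vector("list", L - 1); ups <- vector("list", L - 1)
  y <- enc[[L]]$y
  for (l in rev(seq_len(L - 1))) {
    idx <- upsampleIndex(d[[l + 1]])
    u <- upsampleForward(y, idx)
    uc <- convForward(u, d[[l]], P[[paste0("dec", l, ".Wu")]],
                      P[[paste0("dec", l, ".bu")]])
    ups[[l]] <- list(idx = idx, uc = uc, nLo = nrow(y))
    cat2 <- cbind(uc$y, enc[[l]]$y)
    dec[[l]] <- blockForward(P, paste0("dec", l), cat2, d[[l]], norm)
    y <- dec[[l]]$y
  }
  hf <- conv1Forward(y, P[["headF.W"]], P[["headF.b"]])
  auxSrc <- if (L >= 3) dec[[2]]$y else enc[[L]]$y
  ha <- conv1Forward(auxSrc, P[["headA.W"]], P[["headA.b"]])
  out <- list(final = hf$y, aux = ha$y, dims = d[[1]], auxDims = d[[2]])
  if (withCache)
    out$cache <- list(d = d, enc = enc, pools = pools, dec = dec, ups = ups,
                      decIn = y, auxSrc = auxSrc)
  out
}

# Backward pass: dFinal / dAux are gradients w.r.t. the two heads' logits.
# Returns a flat named list of parameter gradients.
netBackward <- function(net, fw, dFinal, dAux) {
  P <- net$params; norm <- net$arch$norm; L <- net$arch$levels
  cc <- fw$cache
  G <- new.env(parent = emptyenv())
  hb <- conv1Backward(dFinal, cc$decIn, P[["headF.W"]])
  G[["headF.W"]] <- hb$dW; G[["headF.b"]] <- hb$db
  ab <- conv1Backward(dAux, cc$auxSrc, P[["headA.W"]])
  G[["headA.W"]] <- ab$dW; G[["headA.b"]] <- ab$db
  dskip <- vector("list", L) # gradient flowing into enc block outputs
  dy <- hb$dx # gradient at dec block 1 output
  for (l in seq_len(L - 1)) {
    if (l == 2 && L >= 3) dy <- dy + ab$dx
    dcat <- blockBackward(dy, cc$dec[[l]]$cache, P, paste0("dec", l),
                          cc$d[[l]], norm, G)
    cl <- chAt(net$arch$baseChannels, l)
    duc <- dcat[, seq_len(cl), drop = FALSE]
    dskip[[l]] <- dcat[, cl + seq_len(cl), drop = FALSE]
    cb <- convBackward(duc, cc$ups[[l]]$uc, P[[paste0("dec", l, ".Wu")]],
                       cc$d[[l]], chAt(net$arch$baseChannels, l + 1))
    G[[paste0("dec", l, ".Wu")]] <- cb$dW
    G[[paste0("dec", l, ".bu")]] <- cb$db
    dy <- upsampleBackward(cb$dx, cc$ups[[l]]$idx, cc$ups[[l]]$nLo)
  }
  # dy now targets the bottleneck (enc L) output
  if (L == 2) dy <- dy + ab$dx
  for (l in rev(seq_len(L))) {
    dout <- dy
    if (l < L && !is.null(dskip[[l]])) dout <- dout + dskip[[l]]
    dx <- blockBackward(dout, cc$enc[[l]]$cache, P, paste0("enc", l),
                        cc$d[[l]], norm, G)
    if (l > 1) {
      dy <- maxpool3_back(dx, cc$pools[[l]]$argmax, prod(cc$d[[l - 1]]))
    }
  }
  grads <- as.list(G)
  # zero-fill anything untouched (e.g. norm params when norm = "none")
  for (nm in names(P)) if (is.null(grads[[nm]])) grads[[nm]] <- P[[nm]] * 0
  grads[names(P)]
}

#' Per-voxel foreground probability from a forward pass
#'
#' Softmax over the two channels of the final head; channel 2 is foreground.
#'
#' @param fw Output of [netForward()].
#' @return 3D array of probabilities with the input's spatial dims.
#' @export
forwardProbability <- function(fw) {
  p <- softmax2(fw$final)[, 2]
  array(p, dim = fw$dims)
}
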