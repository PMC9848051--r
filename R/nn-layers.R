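# Dense 3D network primitives. Feature maps are [Nvox, C] matrices over an
# (X, Y, Z) grid flattened column-major (x fastest), matching R arrays of
# dim c(X, Y, Z). Convolutions are 3x3x3 zero-padded, realized as
# im2col + GEMM; backward passes are exact adjoints so gradients are
# analytically correct (verified by finite differences in the tests).

addBias <- function(y, b) y + rep(b, each = nrow(y))

convForward <- function(x, dims, W, b) {
  y <- addBias(conv3fwd(x, as.integer(dims), W), b)
  list(y = y, x = x, dims = as.integer(dims))
}

convBackward <- function(dy, cache, W, dims, cin) {
  list(dx = conv3bwdData(dy, cache$dims, W),
       dW = conv3dW(cache$x, dy, cache$dims),
       db = colSums(dy))
}

conv1Forward <- function(x, W, b) list(y = addBias(x %*% W, b))

conv1Backward <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

# instance normalization: per-channel over all voxels of the window
inormForward <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x)
  m <- colMeans(x)
  xc <- x - rep(m, each = n)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xn <- xc * rep(istd, each = n)
  y <- xn * rep(g, each = n) + rep(b, each = n)
  list(y = y, xn = xn, istd = istd)
}

inormBackward <- function(dy, cache, g) {
  n <- nrow(dy)
  xn <- cache$xn
  dg <- colSums(dy * xn)
  db <- colSums(dy)
  dxn <- dy * rep(g, each = n)
  t1 <- colMeans(dxn)
  t2 <- colMeans(dxn * xn)
  dx <- rep(cache$istd, each = n) *
    (dxn - rep(t1, each = n) - xn * rep(t2, each = n))
  list(dx = dx, dg = dg, db = db)
}

reluForward <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, mask = x > 0)
}

reluBackward <- function(dy, cache) dy * cache$mask

# nearest-neighbour x2 upsampling index map for a low-res (X,Y,Z) grid:
# hi voxel (hx, hy, hz) reads lo voxel (ceil(h/2))
upsampleIndex <- function(dimsLo) {
  X <- dimsLo[1]; Y <- dimsLo[2]; Z <- dimsLo[3]
  hx <- rep(seq_len(2 * X), times = 2 * Y * 2 * Z)
  hy <- rep(rep(seq_len(2 * Y), each = 2 * X), times = 2 * Z)
  hz <- rep(seq_len(2 * Z), each = 4 * X * Y)
  lx <- (hx + 1L) %/% 2L; ly <- (hy + 1L) %/% 2L; lz <- (hz + 1L) %/% 2L
  lx + X * (ly - 1L) + X * Y * (lz - 1L)
}

upsampleForward <- function(x, idx) x[idx, , drop = FALSE]

upsampleBackward <- function(dy, idx, nLo) {
  dx <- rowsum(dy, group = idx, reorder = TRUE)
  # every low-res voxel receives 8 contributions, so rows cover 1..nLo
  stopifnot(nrow(dx) == nLo)
  dx
}

softmax2 <- function(z) {
  m <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - m); e2 <- exp(z[, 2] - m)
  s <- e1 + e2
  cbind(e1 / s, e2 / s)
}
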