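#' Sliding-window whole-volume inference
#'
#' The volume is processed in overlapping tiles; each tile contributes the
#' probability of its central region (a margin of `overlap/2` is discarded on
#' interior tile faces), remaining overlaps are averaged, and volumes smaller
#' than the tile are zero-padded and cropped back. With normalization
#' disabled and `overlap` at least the network's receptive-field diameter,
#' tiled and single-pass predictions agree to numerical precision; with
#' instance normalization the per-window statistics differ slightly by
#' construction.
#'
#' @param net A network from [buildNetwork()] (or a checkpoint's `$net`).
#' @param vol Input volume, dim (x, y, z), values in \[0,1\].
#' @param tile Tile size (x, y, z); must be divisible by `2^(levels-1)`.
#' @param overlap Overlap between neighbouring tiles (voxels, even).
#' @return Foreground-probability array in \[0,1\], same dim as `vol`.
#' @export
predictVolume <- function(net, vol, tile = c(32, 32, 32), overlap = 8) {
  stopifnot(length(dim(vol)) == 3L, overlap %% 2 == 0)
  shape <- dim(vol)
  pad <- pmax(tile - shape, 0)
  if (any(pad > 0)) {
    padded <- array(0, dim = shape + pad)
    padded[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <- vol
    p <- predictVolume(net, padded, tile, overlap)
    return(p[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE])
  }
  starts <- function(D, t) {
    s <- seq(1L, D - t + 1L, by = max(t - overlap, 1L))
    unique(c(s, D - t + 1L))
  }
  sx <- starts(shape[1], tile[1])
  sy <- starts(shape[2], tile[2])
  sz <- starts(shape[3], tile[3])
  acc <- array(0, dim = shape)
  cnt <- array(0, dim = shape)
  m <- overlap %/% 2
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    ix <- x0:(x0 + tile[1] - 1L)
    iy <- y0:(y0 + tile[2] - 1L)
    iz <- z0:(z0 + tile[3] - 1L)
    fw <- netForward(net, vol[ix, iy, iz, drop = FALSE])
    p <- forwardProbability(fw)
    w <- array(1, dim = tile)
    trim <- function(w, axis, s0, t, D) {
      if (s0 > 1L) {
        idx <- lapply(tile, seq_len); idx[[axis]] <- seq_len(m)
        w[idx[[1]], idx[[2]], idx[[3]]] <- 0
      }
      if (s0 + t - 1L < D) {
        idx <- lapply(tile, seq_len); idx[[axis]] <- (t - m + 1L):t
        w[idx[[1]], idx[[2]], idx[[3]]] <- 0
      }
      w
    }
    if (m > 0) {
      w <- trim(w, 1, x0, tile[1], shape[1])
      w <- trim(w, 2, y0, tile[2], shape[2])
      w <- trim(w, 3, z0, tile[3], shape[3])
    }
    acc[ix, iy, iz] <- acc[ix, iy, iz] + p * w
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + w
  }
  stopifnot(all(cnt > 0))
  acc / cnt
}
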