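#' Read a multi-page TIFF as a 3D volume
#'
#' Pages are z-slices; the returned array has dim `c(x, y, z)` with intensity
#' already scaled to \[0,1\] (integer TIFFs are divided by their dtype
#' maximum by the reader, float TIFFs are passed through).
#'
#' @param path Path to a multi-page TIFF.
#' @return Numeric 3D array, dim (x, y, z).
#' @export
readVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1] # drop extra channels
    t(m) # rows are y, columns x -> transpose to [x, y]
  })
  vol <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- pages[[z]]
  vol
}

#' Write a 3D volume as a multi-page TIFF
#'
#' @param vol Numeric 3D array, dim (x, y, z), values in \[0,1\].
#' @param path Output path.
#' @param bitDepth 8, 16 or 32 (32 = float32). Default 32.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path, bitDepth = 32) {
  stopifnot(length(dim(vol)) == 3L, bitDepth %in% c(8, 16, 32))
  pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = bitDepth)
  invisible(path)
}

#' Normalize raw integer intensities to the unit interval
#'
#' Absolute scaling by the dtype maximum (`2^bitDepth - 1`), not by the
#' per-volume maximum, so the weak-fiber threshold (raw value 20 on the 8-bit
#' scale) always maps to the same normalized value 20/255.
#'
#' @param vol Numeric array of raw intensities, >= 0.
#' @param bitDepth 8 or 16, or `NULL` to use `maxValue`.
#' @param maxValue Explicit dtype maximum overriding `bitDepth`.
#' @return Array of the same shape with values in \[0,1\].
#' @export
normalizeIntensities <- function(vol, bitDepth = 8, maxValue = NULL) {
  if (any(vol < 0)) stop("negative intensities are not allowed")
  if (is.null(maxValue)) {
    if (!bitDepth %in% c(8, 16)) stop("bitDepth must be 8 or 16")
    maxValue <- 2^bitDepth - 1
  }
  out <- vol / maxValue
  if (any(out > 1)) stop("intensities exceed the stated dtype maximum")
  out
}

# clamp helper used throughout
clip01 <- function(x) pmin(pmax(x, 0), 1)
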