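#' Fuse segmentation confidence with the original image
#'
#' Elementwise convex combination `alpha * x + (1 - alpha) * p` of the
#' original (normalized) image and the foreground probability. With the
#' default `alpha = 0.8` the image dominates but confidently segmented dim
#' fibers are lifted above tracing thresholds, and a soma disconnected in
#' the segmentation is rescued by its image intensity.
#'
#' @param x Image volume in \[0,1\].
#' @param p Probability volume in \[0,1\], same shape.
#' @param alpha Mixing weight in \[0,1\]; `1` returns `x`, `0` returns `p`.
#' @return Fused volume in \[0,1\].
#' @examples
#' fuseVolumes(0.5, 1.0, 0.8) # 0.6
#' @export
fuseVolumes <- function(x, p, alpha = 0.8) {
  if (!identical(dim(x), dim(p)) || length(x) != length(p))
    stop("image and probability volumes must have identical shape")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (any(x < 0) || any(x > 1) || any(p < 0) || any(p > 1))
    stop("inputs must lie in [0, 1]")
  if (alpha == 1) return(x)
  if (alpha == 0) return(p)
  alpha * x + (1 - alpha) * p
}
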