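#' Generate a synthetic sarcomere striation image
#'
#' Renders a sinusoidal striation pattern (ACTN2-like Z-band periodicity)
#' with a given spatial period.  Local stripe orientation is perturbed by a
#' smooth zero-mean Gaussian field of the requested angular SD, so
#' \code{jitter_deg = 0} gives a globally coherent pattern and large jitter
#' approaches an isotropic texture.
#'
#' @param spacing_px stripe period in pixels; must be >= 4 (aliasing guard).
#' @param jitter_deg SD of the local orientation perturbation, degrees.
#' @param size image side in pixels (square image).
#' @param seed integer seed.
#' @return A numeric matrix in [0, 1].
#' @export
generate_striation_image <- function(spacing_px, jitter_deg = 0, size = 256L,
                                     seed = 1L) {
  if (spacing_px < 4) stopf("spacing_px must be >= 4 (got %.3g)", spacing_px)
  with_rng(seed, {
    x <- matrix(seq_len(size), size, size, byrow = TRUE)
    y <- matrix(seq_len(size), size, size)
    if (jitter_deg > 0) {
      th <- matrix(rnorm(size * size), size, size)
      # correlation length ~2 periods, capped so the kernel fits the image
      th <- EBImage::gblur(th, sigma = min(2 * spacing_px, (size - 1) / 7))
      th <- th / sd(th) * jitter_deg * pi / 180
    } else th <- matrix(0, size, size)
    0.5 + 0.5 * sin(2 * pi * (x * cos(th) + y * sin(th)) / spacing_px)
  })
}
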