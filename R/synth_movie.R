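#' Recipe for a synthetic beating-tissue movie
#'
#' A textured field deforming under a known displacement profile.  Two
#' motion modes are supported: \code{"translation"} (constant velocity,
#' px/frame) and \code{"pulse"} (a train of Gaussian velocity pulses along
#' a fixed direction, one pulse per period, emulating periodic tissue
#' contraction).  Motion can be restricted to a smooth circular active
#' region to emulate a locally contracting patch.
#'
#' @param n_frames number of frames.
#' @param fps frame rate (default 100 frames/s).
#' @param pixel_size_um lateral calibration (um/px).
#' @param size_px image side in pixels (square frames).
#' @param mode "translation" or "pulse".
#' @param velocity_px translation mode: c(u, v) in px/frame.
#' @param peak_velocity_um_s,pulse_width_s,period_s pulse mode: peak speed
#'   (um/s), Gaussian FWHM (s) and pulse period (s).
#' @param direction pulse mode: unit direction of motion c(ux, uy).
#' @param region optional list(cx, cy, radius) in px restricting motion to
#'   a smooth circular patch.
#' @param texture_sigma granularity of the random texture (Gaussian
#'   smoothing sigma, px).
#' @param noise_sd additive Gaussian noise SD per frame.
#' @param seed integer seed.
#' @return A recipe object of class \code{movie_recipe}.
#' @export
movie_recipe <- function(n_frames = 100L, fps = 100, pixel_size_um = 1,
                         size_px = 128L, mode = c("translation", "pulse"),
                         velocity_px = c(0.5, 0),
                         peak_velocity_um_s = 30, pulse_width_s = 0.2,
                         period_s = 1, direction = c(1, 0),
                         region = NULL, texture_sigma = 2,
                         noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (fps <= 0) stopf("fps must be > 0")
  if (!all(is.finite(velocity_px))) stopf("velocity must be finite")
  structure(as.list(environment()), class = "movie_recipe")
}

#' Generate a movie with known per-frame velocity fields
#'
#' Frame t is frame 1 warped by the cumulative ground-truth displacement
#' (bilinear interpolation), plus optional noise.  The true velocity of
#' each inter-frame step is returned alongside, both as px/frame vectors
#' and as a speed profile in um/s.
#'
#' @param recipe a \code{\link{movie_recipe}}.
#' @return A list: \code{frames} (array [y, x, t]), \code{truth} with
#'   \code{velocity_px} (matrix t-1 x 2, px/frame), \code{speed_um_s}
#'   (per-step speed), and \code{mask} (active-region weight matrix).
#' @export
generate_movie <- function(recipe) {
  stopifnot(inherits(recipe, "movie_recipe"))
  r <- recipe
  with_rng(r$seed, {
    n <- r$size_px
    base <- EBImage::gblur(matrix(runif(n * n), n, n), sigma = r$texture_sigma)
    base <- (base - min(base)) / (max(base) - min(base))

    n_steps <- r$n_frames - 1L
    if (r$mode == "translation") {
      vel <- matrix(rep(r$velocity_px, each = n_steps), n_steps, 2)
    } else {
      dirn <- r$direction / sqrt(sum(r$direction^2))
      t_mid <- (seq_len(n_steps) - 0.5) / r$fps
      sigma <- r$pulse_width_s / (2 * sqrt(2 * log(2)))
      k <- floor(t_mid / r$period_s)
      speed <- r$peak_velocity_um_s *
        exp(-((t_mid - (k + 0.5) * r$period_s)^2) / (2 * sigma^2))
      v_pxf <- speed / r$pixel_size_um / r$fps
      vel <- cbind(v_pxf * dirn[1], v_pxf * dirn[2])
    }

    if (!is.null(r$region)) {
      dx <- matrix(seq_len(n), n, n, byrow = TRUE) - r$region$cx
      dy <- matrix(seq_len(n), n, n) - r$region$cy
      mask <- exp(-(dx^2 + dy^2) / (2 * (r$region$radius / 2)^2))
    } else mask <- matrix(1, n, n)

    cum <- apply(vel, 2, cumsum)
    if (n_steps == 1L) cum <- matrix(cum, 1)
    if (max(abs(cum)) * max(mask) > n / 2)
      stopf("cumulative displacement %.1f px exceeds half the frame (%d px)",
            max(abs(cum)), n %/% 2)

    frames <- array(0, c(n, n, r$n_frames))
    frames[, , 1] <- base
    for (t in seq_len(n_steps)) {
      frames[, , t + 1L] <- bilinear_warp(base, cum[t, 1] * mask,
                                          cum[t, 2] * mask)
    }
    if (r$noise_sd > 0)
      frames <- frames + array(rnorm(length(frames), 0, r$noise_sd),
                               dim(frames))

    speed_um_s <- sqrt(rowSums(vel^2)) * r$pixel_size_um * r$fps
    list(frames = frames,
         truth = list(velocity_px = vel, speed_um_s = speed_um_s,
                      mask = mask),
         recipe = r)
  })
}

#' Write / read a movie as multi-page TIFF
#'
#' One page per frame; intensities linearly mapped to [0, 1] for 16-bit
#' storage (scale restored on reading via a JSON sidecar).
#'
#' @param frames array [y, x, t].
#' @param path TIFF path.
#' @return \code{write_movie_tiff} returns \code{path} invisibly;
#'   \code{read_movie_tiff} returns the frame array.
#' @export
write_movie_tiff <- function(frames, path) {
  hi <- max(frames, 1e-12); lo <- min(frames, 0)
  pages <- lapply(seq_len(dim(frames)[3]), function(t)
    (frames[, , t] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(lo = lo, hi = hi), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages))
    arr[, , t] <- pages[[t]] * (meta$hi - meta$lo) + meta$lo
  arr
}
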