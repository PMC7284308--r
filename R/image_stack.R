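#' Calibrated multichannel 3D image stack
#'
#' Container for a multichannel confocal stack: a 4D numeric array indexed
#' \code{[y, x, z, channel]} together with the lateral pixel size and the
#' axial step, both in micrometres.
#'
#' @param data 4D numeric array \code{[y, x, z, channel]}.
#' @param channels character vector of channel names (length = 4th dim).
#' @param pixel_size_um lateral calibration, micrometres per pixel.
#' @param z_step_um axial distance between consecutive slices, micrometres.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(data, channels, pixel_size_um, z_step_um) {
  if (length(dim(data)) != 4L)
    stopf("`data` must be a 4D array [y, x, z, channel], got %d dims",
          length(dim(data)))
  if (length(channels) != dim(data)[4])
    stopf("%d channel names for %d channels", length(channels), dim(data)[4])
  if (pixel_size_um <= 0 || z_step_um <= 0)
    stopf("calibration must be positive")
  structure(
    list(data = data, channels = as.character(channels),
         pixel_size_um = pixel_size_um, z_step_um = z_step_um),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d x %d px, %d slices, %d channel(s) [%s]\n  %.3g um/px, z-step %.3g um\n",
    d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", "),
    x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Extract one 2D slice from a stack
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channel channel name or index.
#' @param z slice index.
#' @return A numeric matrix \code{[y, x]}.
#' @export
get_slice <- function(stack, channel, z) {
  ci <- channel_index(stack, channel)
  if (z < 1 || z > dim(stack$data)[3]) stopf("slice %d out of range", z)
  stack$data[, , z, ci]
}

channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channels)
    if (is.na(ci)) stopf("channel '%s' not present (have: %s)", channel,
                         paste(stack$channels, collapse = ", "))
    ci
  } else {
    ci <- as.integer(channel)
    if (ci < 1 || ci > length(stack$channels))
      stopf("channel index %d out of range", ci)
    ci
  }
}

#' Write / read a stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered channel-major within z (page = (z-1)*n_channels + c).
#' Calibration and channel names go to \code{<path>.json}.  Intensities are
#' linearly mapped to [0, 1] for 16-bit storage; the scale is recorded in
#' the sidecar and undone on reading.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path TIFF file path.
#' @return \code{write_stack_tiff} returns \code{path} invisibly;
#'   \code{read_stack_tiff} returns an \code{image_stack}.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  hi <- max(stack$data, 1e-12)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (z in seq_len(d[3])) for (ci in seq_len(d[4])) {
    pages[[k]] <- pmin(pmax(stack$data[, , z, ci] / hi, 0), 1)
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = stack$channels, pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um, n_z = d[3], intensity_scale = hi)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  nz <- meta$n_z
  d1 <- dim(pages[[1]])
  data <- array(0, c(d1[1], d1[2], nz, nch))
  k <- 1L
  for (z in seq_len(nz)) for (ci in seq_len(nch)) {
    data[, , z, ci] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  image_stack(data, meta$channels, meta$pixel_size_um, meta$z_step_um)
}
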