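#' Recipe for a synthetic microtissue nuclei stack
#'
#' Describes a spheroid-like field of ellipsoidal nuclei with known poses,
#' identities and imaging artefacts.  The rendered stack carries a DAPI
#' channel (all nuclei), one marker channel per identity (TNNI for
#' cardiomyocytes, COL1A1 for fibroblasts, CD31 for endothelial cells)
#' painted on the nuclear footprint, and a Ki67 channel for proliferative
#' nuclei, optionally contaminated with diagonal fibrous streaks.
#'
#' @param n_nuclei number of nuclei to place.
#' @param dim_zyx integer field size in voxels, (z, y, x).
#' @param pixel_size_um lateral calibration (um/px).
#' @param z_step_um axial step (um).
#' @param inplane_um range (min, max) of in-plane semi-axes, um.
#' @param axial_um range (min, max) of the axial semi-axis, um.
#' @param min_spacing_um minimum Euclidean distance between centers, um.
#' @param composition named fractions per identity (CM, EC, CF); must sum
#'   to 1.  Allocation to nuclei is deterministic (floor + remainder to the
#'   largest fractional part, ties to the larger fraction then first name).
#' @param proliferative_fraction fraction of Ki67-positive nuclei in [0, 1].
#' @param dapi_intensity,marker_intensity,ki67_intensity paint intensities
#'   (arbitrary units); \code{marker_intensity} is the on-target intensity
#'   of each identity's own marker channel.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param illumination_gradient amplitude of the multiplicative planar ramp
#'   across each slice, as a fraction (0 = flat field).
#' @param z_attenuation per-slice multiplicative attenuation rate; slice k
#'   is scaled by (1 - z_attenuation)^(k-1).
#' @param ki67_streaks number of 45-degree fibrous streaks added to the
#'   Ki67 channel as classification distractors.
#' @param streak_intensity,streak_width_px streak paint intensity and width.
#' @param seed integer seed; all randomness flows through it.
#' @return A validated recipe object of class \code{stack_recipe}.
#' @export
stack_recipe <- function(n_nuclei = 200L,
                         dim_zyx = c(44L, 256L, 256L),
                         pixel_size_um = 0.5,
                         z_step_um = 1.0,
                         inplane_um = c(2.5, 3.5),
                         axial_um = c(2.0, 3.5),
                         min_spacing_um = 10,
                         composition = c(CM = 0.70, EC = 0.15, CF = 0.15),
                         proliferative_fraction = 0.2,
                         dapi_intensity = 1.0,
                         marker_intensity = 1.0,
                         ki67_intensity = 1.0,
                         noise_sd = 0.1,
                         illumination_gradient = 0.2,
                         z_attenuation = 0.01,
                         ki67_streaks = 0L,
                         streak_intensity = 1.0,
                         streak_width_px = 2L,
                         seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-9)
    stopf("composition fractions must sum to 1 (got %.12g)", sum(composition))
  if (any(composition < 0)) stopf("composition fractions must be >= 0")
  if (min_spacing_um <= 0) stopf("min_spacing_um must be > 0")
  if (any(inplane_um <= 0) || any(axial_um <= 0))
    stopf("semi-axis ranges must be positive")
  if (proliferative_fraction < 0 || proliferative_fraction > 1)
    stopf("proliferative_fraction must be in [0, 1]")
  structure(as.list(environment()), class = "stack_recipe")
}

# Deterministic composition allocation: floor, then remainder one by one to
# the largest fractional part (ties: larger fraction, then earlier name).
allocate_identities <- function(n, composition) {
  f <- composition
  base <- floor(f * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- f * n - base
    ord <- order(-frac, -f, seq_along(f))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  rep(names(f), times = base)
}

#' Generate a synthetic nuclei stack with exact ground truth
#'
#' Renders solid ellipsoids (in-plane orientation only) at rejection-sampled
#' centers with a hard minimum spacing, paints identity markers on nuclear
#' footprints, then applies a multiplicative planar illumination ramp,
#' exponential z-attenuation and additive Gaussian noise.  Ground truth is
#' emitted analytically and never re-measured from the rendering.
#'
#' @param recipe a \code{\link{stack_recipe}}.
#' @return A list with elements \code{stack} (an \code{\link{image_stack}}
#'   with channels dapi, tnni, col1a1, cd31, ki67) and \code{truth} (a
#'   data.frame: id, cx_um, cy_um, cz_um, a_um, b_um, c_um, theta,
#'   identity, proliferative).
#' @export
generate_stack <- function(recipe) {
  stopifnot(inherits(recipe, "stack_recipe"))
  r <- recipe
  with_rng(r$seed, {
    nz <- r$dim_zyx[1]; ny <- r$dim_zyx[2]; nx <- r$dim_zyx[3]
    ext_um <- c(x = nx * r$pixel_size_um, y = ny * r$pixel_size_um,
                z = nz * r$z_step_um)
    a <- runif(r$n_nuclei, r$inplane_um[1], r$inplane_um[2])
    b <- runif(r$n_nuclei, r$inplane_um[1], r$inplane_um[2])
    swap <- b > a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    cc <- runif(r$n_nuclei, r$axial_um[1], r$axial_um[2])
    theta <- runif(r$n_nuclei, -pi / 2, pi / 2)

    # rejection-sampled centers, hard minimum spacing, ellipsoid fully inside
    mx <- max(r$inplane_um); mz <- max(r$axial_um)
    if (2 * mx >= ext_um["x"] || 2 * mx >= ext_um["y"] || 2 * mz >= ext_um["z"])
      stopf("field too small for the requested semi-axes")
    centers <- matrix(NA_real_, r$n_nuclei, 3)  # x, y, z in um
    for (i in seq_len(r$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(10000L)) {
        p <- c(runif(1, mx, ext_um["x"] - mx),
               runif(1, mx, ext_um["y"] - mx),
               runif(1, mz, ext_um["z"] - mz))
        if (i == 1L ||
            min(sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - p)^2))) >=
            r$min_spacing_um) {
          centers[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed)
        stopf("could not place nucleus %d with min spacing %.3g um after 10000 tries",
              i, r$min_spacing_um)
    }

    identity <- allocate_identities(r$n_nuclei, r$composition)
    n_pos <- round(r$proliferative_fraction * r$n_nuclei)
    proliferative <- rep(FALSE, r$n_nuclei)
    proliferative[sample.int(r$n_nuclei, n_pos)] <- TRUE

    channels <- c("dapi", "tnni", "col1a1", "cd31", "ki67")
    marker_of <- c(CM = "tnni", CF = "col1a1", EC = "cd31")
    data <- array(0, c(ny, nx, nz, length(channels)))

    # voxel centers (um): x = (col - 0.5)*px, y = (row - 0.5)*px,
    # z = (slice - 0.5)*dz
    for (i in seq_len(r$n_nuclei)) {
      z_lo <- max(1L, ceiling((centers[i, 3] - cc[i]) / r$z_step_um + 0.5))
      z_hi <- min(nz, floor((centers[i, 3] + cc[i]) / r$z_step_um + 0.5))
      mi <- channel_index_name(channels, marker_of[[identity[i]]])
      for (z in z_lo:z_hi) {
        dz <- (z - 0.5) * r$z_step_um - centers[i, 3]
        s2 <- 1 - (dz / cc[i])^2
        if (s2 <= 0) next
        s <- sqrt(s2)
        cx_px <- centers[i, 1] / r$pixel_size_um + 0.5
        cy_px <- centers[i, 2] / r$pixel_size_um + 0.5
        px <- raster_ellipse(cx_px, cy_px,
                             s * a[i] / r$pixel_size_um,
                             s * b[i] / r$pixel_size_um,
                             theta[i], dim_yx = c(ny, nx))
        if (nrow(px) == 0) next
        idx <- cbind(px, z)
        data[cbind(idx, 1L)] <- pmax(data[cbind(idx, 1L)], r$dapi_intensity)
        data[cbind(idx, mi)] <- pmax(data[cbind(idx, mi)], r$marker_intensity)
        if (proliferative[i]) {
          ki <- channel_index_name(channels, "ki67")
          data[cbind(idx, ki)] <- pmax(data[cbind(idx, ki)], r$ki67_intensity)
        }
      }
    }

    # fibrous streaks at 45 degrees on the Ki67 channel (distractors)
    if (r$ki67_streaks > 0) {
      ki <- channel_index_name(channels, "ki67")
      for (s in seq_len(r$ki67_streaks)) {
        z <- sample.int(nz, 1L)
        offs <- sample.int(nx + ny, 1L)  # anti-diagonal row + col = offs
        for (w in seq_len(r$streak_width_px) - 1L) {
          cols <- seq_len(nx)
          rows <- offs + w - cols
          ok <- rows >= 1 & rows <= ny
          data[cbind(rows[ok], cols[ok], z, ki)] <-
            pmax(data[cbind(rows[ok], cols[ok], z, ki)], r$streak_intensity)
        }
      }
    }

    # illumination ramp (planar, per slice), z-attenuation, noise
    if (r$illumination_gradient != 0) {
      u <- (matrix(seq_len(ny), ny, nx) - 1) / max(ny - 1, 1) +
        (matrix(seq_len(nx), ny, nx, byrow = TRUE) - 1) / max(nx - 1, 1)
      ramp <- 1 + r$illumination_gradient * (u / 2 - 0.5)
    } else ramp <- matrix(1, ny, nx)
    for (z in seq_len(nz)) {
      att <- (1 - r$z_attenuation)^(z - 1)
      for (ch in seq_along(channels))
        data[, , z, ch] <- data[, , z, ch] * ramp * att
    }
    if (r$noise_sd > 0)
      data <- pmax(data + array(rnorm(length(data), 0, r$noise_sd), dim(data)), 0)

    truth <- data.frame(
      id = seq_len(r$n_nuclei),
      cx_um = centers[, 1], cy_um = centers[, 2], cz_um = centers[, 3],
      a_um = a, b_um = b, c_um = cc, theta = theta,
      identity = identity, proliferative = proliferative,
      stringsAsFactors = FALSE)

    list(stack = image_stack(data, channels, r$pixel_size_um, r$z_step_um),
         truth = truth, recipe = r)
  })
}

channel_index_name <- function(channels, name) {
  i <- match(name, channels)
  if (is.na(i)) stopf("channel '%s' missing", name)
  i
}

#' Write ground truth to CSV
#'
#' @param truth ground-truth data.frame from \code{\link{generate_stack}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
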