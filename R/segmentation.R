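#' Segmentation parameters
#'
#' All 2D operators are scaled by a single kernel radius KR, chosen as the
#' minimal radius of the objects of interest (5 px for microtissue nuclei
#' imaged at ~0.5 um/px).
#'
#' @param kr kernel radius in pixels (>= 1).
#' @param split_threshold oversize-split threshold in px^2; an object with
#'   area >= n * split_threshold (n = floor(area / split_threshold) >= 2)
#'   is re-divided into n objects.  \code{NULL} disables splitting; when
#'   set it must exceed kr^2.  Choose relative to the expected section
#'   area (e.g. 2-3x the median object area).
#' @param median_radius,max_radius,gauss_sigma enhancement radii; defaults
#'   kr, kr and kr/2.
#' @param seed_min_sep minimum seed separation in px (default kr).
#' @return An object of class \code{seg_params}.
#' @export
seg_params <- function(kr = 5L, split_threshold = NULL,
                       median_radius = kr, max_radius = kr,
                       gauss_sigma = kr / 2, seed_min_sep = kr) {
  kr <- as.integer(kr)
  if (kr < 1) stopf("kr must be >= 1")
  if (!is.null(split_threshold) && split_threshold <= kr^2)
    stopf("split_threshold must exceed kr^2 = %d", kr^2)
  structure(list(kr = kr, split_threshold = split_threshold,
                 median_radius = as.integer(median_radius),
                 max_radius = as.integer(max_radius),
                 gauss_sigma = gauss_sigma,
                 seed_min_sep = seed_min_sep),
            class = "seg_params")
}

# Foreground of an enhanced slice: above the slice median plus a noise
# allowance of 5 MAD.  On integer images whose background majority is
# exactly zero both terms vanish and this is the plain median-threshold
# rule.  The multiplier is calibrated on background-only (null) slices:
# the enhancement maximum filter right-skews the background so that 3 MAD
# still passes a few noise clusters per slice; 5 MAD is the smallest
# integer multiple with no false objects under the null while remaining
# an order of magnitude below nuclear intensities.
binarize_slice <- function(slice) {
  m <- median(slice)
  slice > m + 5 * mad(slice)
}

check_slice <- function(slice) {
  if (!is.matrix(slice) || !is.numeric(slice))
    stopf("expected a 2D numeric matrix")
  slice
}

# Grayscale morphology on an affinely rescaled copy (EBImage expects
# [0, 1]); erosion/dilation commute with positive affine maps.
scaled_morph <- function(img, fun, brush) {
  lo <- min(img); hi <- max(img)
  if (hi - lo < 1e-300) return(img)
  lo + fun((img - lo) / (hi - lo), brush) * (hi - lo)
}

scaled_median <- function(img, radius) {
  lo <- min(img); hi <- max(img)
  if (hi - lo < 1e-300) return(img)
  lo + EBImage::medianFilter((img - lo) / (hi - lo), radius) * (hi - lo)
}

#' Lighting homogenization by opening subtraction
#'
#' Removes slow lateral illumination differences by subtracting the
#' grayscale morphological opening computed with a large disk (radius
#' 5 KR).  The result is non-negative and a flat image maps to zero.
#'
#' @param slice 2D numeric matrix.
#' @param kr kernel radius (px).
#' @return Matrix of the same size, \code{slice - opening(slice)}.
#' @export
homogenize_lighting <- function(slice, kr = 5L) {
  check_slice(slice)
  op <- scaled_morph(slice, EBImage::opening, disk_brush(5L * as.integer(kr)))
  pmax(slice - op, 0)
}

#' Local background subtraction by local median thresholding
#'
#' Pixels at or below their local median (square window of side 8 KR,
#' clipped to the image with a warning if larger) are zeroed; the rest
#' keep their value minus the local median.
#'
#' @inheritParams homogenize_lighting
#' @return Background-subtracted matrix.
#' @export
subtract_local_background <- function(slice, kr = 5L) {
  check_slice(slice)
  radius <- 4L * as.integer(kr)
  lim <- (min(dim(slice)) - 1L) %/% 2L
  if (radius > lim) {
    warnf("local-median window (side %d) exceeds the image; clipped to %d",
          8L * kr, 2L * lim + 1L)
    radius <- lim
  }
  med <- scaled_median(slice, radius)
  out <- slice - med
  out[slice <= med] <- 0
  out
}

#' Object enhancement filter sequence
#'
#' Applies, in order, a median filter (radius KR), a Gaussian blur
#' (SD KR/2) and a grayscale maximum filter (disk of radius KR) to remove
#' residual noise and consolidate object boundaries before binarization.
#'
#' @param slice 2D numeric matrix (background-subtracted).
#' @param params a \code{\link{seg_params}}.
#' @return Enhanced non-negative matrix.
#' @export
enhance <- function(slice, params = seg_params()) {
  check_slice(slice)
  out <- scaled_median(slice, params$median_radius)
  out <- EBImage::gblur(out, sigma = params$gauss_sigma)
  out <- scaled_morph(out, EBImage::dilate, disk_brush(params$max_radius))
  pmax(out, 0)
}

#' Seed generation from the Euclidean distance transform
#'
#' Binarizes the enhanced slice at its median intensity (robustified by a
#' 3 MAD noise allowance, which reduces to the plain median rule on
#' integer images with a zero background), computes the EDT
#' of the foreground and returns the EDT local maxima, greedily thinned to
#' a minimum mutual separation (default KR).  Candidates are ranked by EDT
#' value (ties broken by column-major pixel order).
#'
#' @inheritParams enhance
#' @return A matrix with columns \code{row}, \code{col}, \code{edt}; zero
#'   rows when the foreground is empty.
#' @export
generate_seeds <- function(slice, params = seg_params()) {
  check_slice(slice)
  fg <- binarize_slice(slice)
  if (!any(fg)) return(cbind(row = integer(0), col = integer(0), edt = numeric(0)))
  edt <- EBImage::distmap(fg)
  edt_maxima(edt, params$seed_min_sep)
}

# Local maxima of a non-negative map with greedy minimum-separation
# thinning; deterministic (value desc, then column-major index).
edt_maxima <- function(edt, min_sep, n_max = Inf) {
  mx <- scaled_morph(edt, EBImage::dilate, disk_brush(ceiling(min_sep)))
  cand <- which(edt >= mx - 1e-9 & edt > 0)
  if (length(cand) == 0)
    return(cbind(row = integer(0), col = integer(0), edt = numeric(0)))
  ord <- cand[order(-edt[cand], cand)]
  rows <- (ord - 1L) %% nrow(edt) + 1L
  cols <- (ord - 1L) %/% nrow(edt) + 1L
  keep <- logical(length(ord))
  kr_ <- integer(0); kc_ <- integer(0)
  for (i in seq_along(ord)) {
    if (length(kr_) >= n_max) break
    if (length(kr_) == 0 ||
        min((kr_ - rows[i])^2 + (kc_ - cols[i])^2) >= min_sep^2) {
      keep[i] <- TRUE
      kr_ <- c(kr_, rows[i]); kc_ <- c(kc_, cols[i])
    }
  }
  cbind(row = rows[keep], col = cols[keep], edt = edt[ord[keep]])
}

#' Segment one slice from seeds by nearest-seed flood fill
#'
#' The binarized foreground (enhanced slice > slice median) is partitioned
#' among the seeds by geodesic nearest-seed region growth constrained to
#' the foreground.  Objects smaller than KR^2 px are discarded; an object
#' with area >= n * split_threshold is re-divided into
#' n = floor(area / split_threshold) objects by re-seeding with the n
#' strongest EDT maxima inside it.
#'
#' @param slice enhanced 2D matrix (see \code{\link{enhance}}).
#' @param seeds seed matrix from \code{\link{generate_seeds}}.
#' @param params a \code{\link{seg_params}}.
#' @param slice_index slice index stored on each object.
#' @return A list of 2D nucleus objects; each has \code{slice},
#'   \code{pixels} (n x 2 matrix row/col), \code{area} and \code{ellipse}
#'   (from \code{\link{fit_ellipse}}).
#' @export
segment_slice <- function(slice, seeds, params = seg_params(),
                          slice_index = 1L) {
  check_slice(slice)
  fg <- binarize_slice(slice)
  if (!any(fg)) return(list())
  if (nrow(seeds) == 0) {
    warnf("no seeds for a non-empty foreground in slice %d; emitting one unseeded object",
          slice_index)
    lab <- matrix(0L, nrow(slice), ncol(slice))
    lab[fg] <- 1L
  } else {
    smat <- matrix(0L, nrow(slice), ncol(slice))
    smat[cbind(seeds[, "row"], seeds[, "col"])] <- seq_len(nrow(seeds))
    lab <- floodfill_partition(smat, fg)
  }
  objs <- label_objects(lab, slice_index, params)
  split_oversize(objs, params, slice_index)
}

# Nearest-seed growth constrained to the mask: EBImage::propagate on a
# constant image reduces to a pure geodesic-distance Voronoi partition.
floodfill_partition <- function(seed_labels, mask) {
  lab <- EBImage::propagate(matrix(0, nrow(mask), ncol(mask)),
                            seed_labels, mask = mask)
  matrix(as.integer(round(as.numeric(lab))), nrow(mask), ncol(mask))
}

label_objects <- function(lab, slice_index, params) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  objs <- list()
  for (id in ids) {
    idx <- which(lab == id)
    if (length(idx) < params$kr^2) next  # KR*KR size filter
    px <- cbind(row = (idx - 1L) %% nrow(lab) + 1L,
                col = (idx - 1L) %/% nrow(lab) + 1L)
    objs[[length(objs) + 1L]] <- nucleus2d(slice_index, px)
  }
  objs
}

nucleus2d <- function(slice_index, pixels) {
  list(slice = slice_index, pixels = pixels, area = nrow(pixels),
       ellipse = fit_ellipse(pixels))
}

split_oversize <- function(objs, params, slice_index) {
  thr <- params$split_threshold
  if (is.null(thr)) return(objs)
  out <- list()
  for (ob in objs) {
    n <- floor(ob$area / thr)
    if (n < 2) { out[[length(out) + 1L]] <- ob; next }
    m <- matrix(FALSE, max(ob$pixels[, "row"]), max(ob$pixels[, "col"]))
    m[ob$pixels] <- TRUE
    edt <- EBImage::distmap(m)
    sds <- edt_maxima(edt, params$seed_min_sep, n_max = n)
    if (nrow(sds) < 2) { out[[length(out) + 1L]] <- ob; next }
    smat <- matrix(0L, nrow(m), ncol(m))
    smat[cbind(sds[, "row"], sds[, "col"])] <- seq_len(nrow(sds))
    lab <- floodfill_partition(smat, m)
    out <- c(out, label_objects(lab, slice_index, params))
  }
  out
}

#' Segment every slice of a stack channel
#'
#' Runs the full per-slice chain (lighting homogenization, local
#' background subtraction, enhancement, seed generation, seeded flood
#' fill, size filter and oversize split) independently on every z-slice.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channel nuclei channel name or index (typically "dapi").
#' @param params a \code{\link{seg_params}}.
#' @return A list (one element per slice, in z order) of lists of 2D
#'   nucleus objects.
#' @export
segment_stack <- function(stack, channel = "dapi", params = seg_params()) {
  ci <- channel_index(stack, channel)
  nz <- dim(stack$data)[3]
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    sl <- stack$data[, , z, ci]
    sl <- homogenize_lighting(sl, params$kr)
    sl <- subtract_local_background(sl, params$kr)
    sl <- enhance(sl, params)
    seeds <- generate_seeds(sl, params)
    out[[z]] <- segment_slice(sl, seeds, params, slice_index = z)
  }
  out
}

#' Tabulate per-slice objects
#'
#' @param slices output of \code{\link{segment_stack}}.
#' @return A data.frame: slice, object, centroid_x, centroid_y, area and
#'   ellipse parameters (px units).
#' @export
objects_table <- function(slices) {
  rows <- list()
  for (z in seq_along(slices)) {
    for (i in seq_along(slices[[z]])) {
      ob <- slices[[z]][[i]]
      e <- ob$ellipse
      rows[[length(rows) + 1L]] <- data.frame(
        slice = ob$slice, object = i,
        centroid_x = e["cx"], centroid_y = e["cy"], area = ob$area,
        a = e["a"], b = e["b"], theta = e["theta"])
    }
  }
  if (length(rows) == 0)
    return(data.frame(slice = integer(0), object = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      area = numeric(0), a = numeric(0), b = numeric(0),
                      theta = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
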