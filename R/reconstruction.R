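#' Fit an ellipse to a pixel set by second central moments
#'
#' The ellipse has the orientation and axis ratio of the principal axes of
#' the pixel scatter, normalized so that pi * a * b equals the pixel area
#' exactly.  Orientation is the major-axis angle versus +x (columns),
#' half-open in (-pi/2, pi/2].
#'
#' @param pixels n x 2 matrix of (row, col) pixel coordinates.
#' @return Named vector \code{c(cx, cy, a, b, theta, area)} in px units.
#' @export
fit_ellipse <- function(pixels) {
  n <- nrow(pixels)
  if (n < 1) stopf("empty pixel set")
  y <- pixels[, 1]; x <- pixels[, 2]
  cx <- mean(x); cy <- mean(y)
  sxx <- mean((x - cx)^2); syy <- mean((y - cy)^2)
  sxy <- mean((x - cx) * (y - cy))
  tr <- sxx + syy
  det_ <- sxx * syy - sxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (abs(sxy) > 1e-12) {
    theta <- atan2(l1 - sxx, sxy)
  } else {
    theta <- if (sxx >= syy) 0 else pi / 2
  }
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  area <- n
  if (l2 < 1e-12) {
    warnf("degenerate (collinear) pixel set; minor semi-axis floored at 0.5 px")
    b <- 0.5
    a <- area / (pi * b)
  } else {
    r <- sqrt(l1 / l2)
    a <- sqrt(area * r / pi)
    b <- sqrt(area / (pi * r))
  }
  c(cx = cx, cy = cy, a = a, b = b, theta = theta, area = area)
}

#' Shared area of two ellipses by pixel rasterization
#'
#' Both ellipses are rasterized on the integer pixel grid and the common
#' pixels counted.  Two 2D objects "interact" when the shared area is at
#' least 1 px.
#'
#' @param e1,e2 ellipses as returned by \code{\link{fit_ellipse}} (named
#'   vectors with cx, cy, a, b, theta).
#' @return Shared area in px^2 (a count).
#' @export
ellipse_overlap <- function(e1, e2) {
  d <- sqrt((e1["cx"] - e2["cx"])^2 + (e1["cy"] - e2["cy"])^2)
  if (d > max(e1["a"], e1["b"]) + max(e2["a"], e2["b"])) return(0)
  p1 <- raster_ellipse(e1["cx"], e1["cy"], e1["a"], e1["b"], e1["theta"])
  p2 <- raster_ellipse(e2["cx"], e2["cy"], e2["a"], e2["b"], e2["theta"])
  if (nrow(p1) == 0 || nrow(p2) == 0) return(0)
  sum(!is.na(match(paste(p1[, 1], p1[, 2]), paste(p2[, 1], p2[, 2]))))
}

#' Link 2D objects across slices into 3D nuclei
#'
#' A 2D object with no interaction (>= 1 px ellipse overlap) in the
#' previous slice starts a new 3D object.  Chains are elongated slice by
#' slice to the interacting candidate of maximal shared area, one-to-one
#' (greedy by descending shared area; ties by smaller object index).  A
#' chain reaching KZ slices is closed; any continuation starts a new
#' object.
#'
#' @param slices per-slice object lists from \code{\link{segment_stack}}.
#' @param kz maximum axial extent in slices (>= 1); see
#'   \code{\link{kz_lookup}} for the condition table.
#' @return A list of 3D nuclei; each has \code{sections} (list of 2D
#'   objects), \code{slices} (z indices) and \code{length}.
#' @export
link_objects <- function(slices, kz = 36L) {
  kz <- as.integer(kz)
  if (kz < 1) stopf("kz must be >= 1")
  chains <- list()        # all chains (lists of section refs)
  active <- integer(0)    # indices of chains whose tail is in previous slice
  prev <- list()
  for (z in seq_along(slices)) {
    cur <- slices[[z]]
    matched_obj <- rep(FALSE, length(cur))
    matched_chain <- rep(FALSE, length(active))
    if (length(active) > 0 && length(cur) > 0) {
      cand <- list()
      for (ai in seq_along(active)) {
        tail_e <- chains[[active[ai]]]$tail_ellipse
        for (oi in seq_along(cur)) {
          ov <- ellipse_overlap(tail_e, cur[[oi]]$ellipse)
          if (ov >= 1) cand[[length(cand) + 1L]] <- c(ai, oi, ov)
        }
      }
      if (length(cand) > 0) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(-cand[, 3], cand[, 2], cand[, 1]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          ai <- cand[k, 1]; oi <- cand[k, 2]
          if (matched_chain[ai] || matched_obj[oi]) next
          ci <- active[ai]
          chains[[ci]]$sections[[length(chains[[ci]]$sections) + 1L]] <- cur[[oi]]
          chains[[ci]]$tail_ellipse <- cur[[oi]]$ellipse
          matched_chain[ai] <- TRUE; matched_obj[oi] <- TRUE
        }
      }
    }
    next_active <- active[matched_chain]
    for (oi in seq_along(cur)) {
      if (matched_obj[oi]) next
      chains[[length(chains) + 1L]] <-
        list(sections = list(cur[[oi]]), tail_ellipse = cur[[oi]]$ellipse)
      next_active <- c(next_active, length(chains))
    }
    # KZ cap: chains that reached full length stop elongating
    keep <- vapply(next_active,
                   function(ci) length(chains[[ci]]$sections) < kz, logical(1))
    active <- next_active[keep]
    prev <- cur
  }
  lapply(chains, function(ch) {
    zs <- vapply(ch$sections, function(s) s$slice, numeric(1))
    structure(list(sections = ch$sections, slices = zs,
                   length = length(zs)), class = "nucleus3d")
  })
}

#' Fit an ellipsoid to a linked 3D nucleus
#'
#' In-plane semi-axes are the section-area-weighted means of the 2D
#' semi-axes converted to micrometres; the axial semi-axis is half the
#' chain extent (chain length x z-step / 2).  Because the area-weighted
#' mean of the section semi-axes of a true ellipsoid equals 9 pi / 32 of
#' its equatorial semi-axis, the in-plane means are divided by that factor
#' when \code{shape_correction} is on (default), recovering the equatorial
#' axes.  \code{dilation_px} optionally subtracts a known systematic
#' boundary dilation (e.g. the KR of the segmentation maximum filter) from
#' the per-section semi-axes before averaging.
#'
#' @param nucleus a 3D nucleus from \code{\link{link_objects}}.
#' @param pixel_size_um,z_step_um calibration.
#' @param shape_correction divide in-plane means by 9 pi / 32 (ellipsoid
#'   cap-profile calibration).
#' @param dilation_px per-section semi-axis reduction in px.
#' @return Named vector \code{c(a, b, c, volume)}; semi-axes in um,
#'   volume (4/3) pi a b c in um^3.
#' @export
fit_ellipsoid <- function(nucleus, pixel_size_um, z_step_um,
                          shape_correction = TRUE, dilation_px = 0) {
  if (missing(pixel_size_um) || missing(z_step_um) ||
      is.null(pixel_size_um) || is.null(z_step_um))
    stopf("calibration (pixel_size_um, z_step_um) is required")
  if (length(nucleus$sections) == 0) stopf("empty chain")
  a_px <- vapply(nucleus$sections, function(s) s$ellipse[["a"]], numeric(1))
  b_px <- vapply(nucleus$sections, function(s) s$ellipse[["b"]], numeric(1))
  w <- vapply(nucleus$sections, function(s) s$area, numeric(1))
  a_px <- pmax(a_px - dilation_px, 0.5)
  b_px <- pmax(b_px - dilation_px, 0.5)
  corr <- if (shape_correction) 9 * pi / 32 else 1
  a <- sum(w * a_px) / sum(w) * pixel_size_um / corr
  b <- sum(w * b_px) / sum(w) * pixel_size_um / corr
  cc <- nucleus$length * z_step_um / 2
  c(a = a, b = b, c = cc, volume = 4 / 3 * pi * a * b * cc)
}

#' Centroid of a 3D nucleus in micrometres
#'
#' Area-weighted mean of the section centroids in-plane; mid-chain in z.
#' Uses the voxel-center convention (pixel i spans (i-1, i] px, center at
#' i - 0.5).
#'
#' @inheritParams fit_ellipsoid
#' @return Named vector \code{c(x, y, z)} in um.
#' @export
nucleus_centroid <- function(nucleus, pixel_size_um, z_step_um) {
  w <- vapply(nucleus$sections, function(s) s$area, numeric(1))
  cx <- vapply(nucleus$sections, function(s) s$ellipse[["cx"]], numeric(1))
  cy <- vapply(nucleus$sections, function(s) s$ellipse[["cy"]], numeric(1))
  zc <- mean(range(nucleus$slices))
  c(x = (sum(w * cx) / sum(w) - 0.5) * pixel_size_um,
    y = (sum(w * cy) / sum(w) - 0.5) * pixel_size_um,
    z = (zc - 0.5) * z_step_um)
}

#' Condition-specific KZ lookup
#'
#' Returns the maximum axial extent (slices) of a 3D object for the named
#' experimental condition: 18 for day 7/21 without fibroblasts, 10 for
#' day 7/21 with fibroblasts, 46 for CMECs, and 36 otherwise (when
#' defaulting is allowed).
#'
#' @param condition condition key, e.g. "cmec", "d7_without_fibroblasts",
#'   "d21_with_fibroblasts".
#' @param allow_default return 36 for unknown keys instead of failing.
#' @return Integer KZ.
#' @export
kz_lookup <- function(condition, allow_default = TRUE) {
  key <- tolower(condition)
  table <- c(
    d7_without_fibroblasts = 18L, d21_without_fibroblasts = 18L,
    d7_with_fibroblasts = 10L, d21_with_fibroblasts = 10L,
    cmec = 46L)
  if (key %in% names(table)) return(unname(table[key]))
  if (allow_default) return(36L)
  stopf("unknown condition '%s' and defaulting disabled", condition)
}

#' Tabulate reconstructed 3D nuclei
#'
#' @param nuclei list from \code{\link{link_objects}}.
#' @param pixel_size_um,z_step_um calibration.
#' @param ... passed to \code{\link{fit_ellipsoid}}.
#' @return Data.frame: id, z range, n_sections, centroid (um), semi-axes
#'   (um) and volume (um^3).
#' @export
nuclei_table <- function(nuclei, pixel_size_um, z_step_um, ...) {
  rows <- lapply(seq_along(nuclei), function(i) {
    n <- nuclei[[i]]
    ctr <- nucleus_centroid(n, pixel_size_um, z_step_um)
    el <- fit_ellipsoid(n, pixel_size_um, z_step_um, ...)
    data.frame(id = i, z_min = min(n$slices), z_max = max(n$slices),
               n_sections = n$length,
               cx_um = ctr[["x"]], cy_um = ctr[["y"]], cz_um = ctr[["z"]],
               a_um = el[["a"]], b_um = el[["b"]], c_um = el[["c"]],
               volume_um3 = el[["volume"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
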