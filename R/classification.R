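#' Prepare identity-marker channels for classification
#'
#' Each marker channel is Gaussian-smoothed per slice (sigma = KR/2) and
#' normalized over the whole volume to (x - median) / (max - median),
#' clipped to [0, 1]: the background level (the volume median, since
#' nuclei occupy a minority of voxels) maps to 0 and the brightest signal
#' to 1.  This keeps classification invariant to per-channel gain while a
#' marker channel containing no positive cell normalizes to small values
#' instead of stretching its noise across [0, 1] as plain min-max would.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channels named character vector mapping identities to channel
#'   names, default \code{c(CM = "tnni", CF = "col1a1", EC = "cd31")}.
#' @param kr kernel radius (px).
#' @return A named list of normalized 3D arrays, one per identity.
#' @export
prepare_markers <- function(stack,
                            channels = c(CM = "tnni", CF = "col1a1",
                                         EC = "cd31"),
                            kr = 5L) {
  out <- list()
  for (id in names(channels)) {
    ci <- channel_index(stack, channels[[id]])
    vol <- stack$data[, , , ci, drop = TRUE]
    if (length(dim(vol)) == 2L) vol <- array(vol, c(dim(vol), 1L))
    for (z in seq_len(dim(vol)[3]))
      vol[, , z] <- EBImage::gblur(vol[, , z], sigma = kr / 2)
    lo <- median(vol); hi <- max(vol)
    out[[id]] <- if (hi > lo) pmin(pmax((vol - lo) / (hi - lo), 0), 1)
                 else vol * 0
  }
  out
}

#' Classify one 3D nucleus from marker intensities
#'
#' For each section, the mean normalized intensity of every marker inside
#' the fitted ellipse is computed; the section identity is the
#' above-threshold marker of highest intensity ("unclassified" if none
#' passes).  The nucleus identity is the modal section identity; ties are
#' broken by the higher mean intensity across the chain.
#'
#' @param nucleus a 3D nucleus from \code{\link{link_objects}}.
#' @param markers normalized channel list from \code{\link{prepare_markers}}.
#' @param thresholds named per-identity thresholds on normalized intensity
#'   in [0, 1] (default 0.25 each).
#' @param erode_px shrinkage of the fitted-ellipse semi-axes before
#'   sampling (px).  The segmentation maximum filter dilates object
#'   boundaries by about KR, so sampling the ellipse eroded by KR reads
#'   the actual nuclear footprint instead of diluting the marker mean
#'   with background; default 5.
#' @return A single identity label ("CM", "EC", "CF" or "unclassified").
#' @export
classify_nucleus <- function(nucleus, markers,
                             thresholds = c(CM = 0.25, CF = 0.25, EC = 0.25),
                             erode_px = 5) {
  ids <- names(markers)
  miss <- setdiff(ids, names(thresholds))
  if (length(miss) > 0) stopf("no threshold for identity '%s'", miss[1])
  dim_yx <- dim(markers[[1]])[1:2]
  sec_id <- character(0)
  mean_int <- setNames(numeric(length(ids)), ids)
  n_used <- 0L
  for (s in nucleus$sections) {
    e <- s$ellipse
    px <- raster_ellipse(e["cx"], e["cy"], max(e["a"] - erode_px, 1),
                         max(e["b"] - erode_px, 1), e["theta"], dim_yx)
    if (nrow(px) == 0) next
    z <- s$slice
    vals <- vapply(ids, function(id)
      mean(markers[[id]][cbind(px, z)]), numeric(1))
    mean_int <- mean_int + vals
    n_used <- n_used + 1L
    pass <- vals >= thresholds[ids]
    sec_id <- c(sec_id,
                if (any(pass)) ids[pass][which.max(vals[pass])]
                else "unclassified")
  }
  if (length(sec_id) == 0) return("unclassified")
  tab <- table(sec_id)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) return(winners)
  winners <- setdiff(winners, "unclassified")
  if (length(winners) == 0) return("unclassified")
  winners[which.max(mean_int[winners] / n_used)]
}

#' Classify all nuclei of a reconstruction
#'
#' @param nuclei list from \code{\link{link_objects}}.
#' @inheritParams classify_nucleus
#' @return Character vector of identity labels, one per nucleus.
#' @export
classify_nuclei <- function(nuclei, markers,
                            thresholds = c(CM = 0.25, CF = 0.25, EC = 0.25),
                            erode_px = 5) {
  vapply(nuclei, classify_nucleus, character(1),
         markers = markers, thresholds = thresholds, erode_px = erode_px)
}

#' Cellular composition from identity labels
#'
#' @param labels character vector of identity labels.
#' @return A list: \code{pct} (percentages per identity over classified
#'   nuclei, summing to 100), \code{n_classified},
#'   \code{pct_unclassified}.
#' @export
composition <- function(labels) {
  if (length(labels) == 0) stopf("no nuclei to summarize")
  cls <- labels[labels != "unclassified"]
  if (length(cls) == 0) stopf("no classified nuclei")
  tab <- table(cls)
  pct <- setNames(100 * as.vector(tab) / length(cls), names(tab))
  list(pct = pct,
       n_classified = length(cls),
       pct_unclassified = 100 * mean(labels == "unclassified"))
}

#' Presence/absence channel processing (Ki67 / COL1A1 pipeline)
#'
#' Per slice: grayscale opening with a 135-degree line element (length
#' 2 KR) to remove fibrous structures, Gaussian blur (sigma KR/2), and
#' lighting homogenization (opening subtraction, disk 5 KR).  All pixels
#' below the channel mean plus SD are then zeroed, and surviving
#' connected specks smaller than KR^2 px (sub-nuclear debris, by the
#' framework's own minimum object size) are removed.  The fiber-removal
#' opening runs before the blur, at native resolution, where thin fibers
#' are still narrower than the line element; the line is no longer than
#' the minimal nuclear diameter (2 KR) so nuclei survive it.  The
#' mean + SD statistic is taken over the whole channel because on slices
#' without any positive cell a per-slice statistic would describe pure
#' background and let a fixed fraction of noise through.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channel channel name or index (e.g. "ki67").
#' @param kr kernel radius (px).
#' @return Processed 3D array with background suppressed to zero.
#' @export
process_presence_channel <- function(stack, channel, kr = 5L) {
  ci <- channel_index(stack, channel)
  vol <- stack$data[, , , ci, drop = TRUE]
  if (length(dim(vol)) == 2L) vol <- array(vol, c(dim(vol), 1L))
  lb <- line_brush(2L * kr, 135)
  for (z in seq_len(dim(vol)[3])) {
    sl <- scaled_morph(vol[, , z], EBImage::opening, lb)
    sl <- EBImage::gblur(sl, sigma = kr / 2)
    vol[, , z] <- homogenize_lighting(sl, kr)
  }
  thr <- mean(vol) + sd(as.vector(vol))
  vol[vol < thr] <- 0
  for (z in seq_len(dim(vol)[3])) {
    sl <- vol[, , z]
    lab <- EBImage::bwlabel(sl > 0)
    if (max(lab) > 0) {
      ar <- tabulate(as.integer(lab))
      sl[matrix(lab %in% which(ar < kr^2), nrow(sl), ncol(sl))] <- 0
      vol[, , z] <- sl
    }
  }
  vol
}

#' Flag nuclei positive for a presence/absence marker
#'
#' A nucleus is positive when the mean processed intensity (see
#' \code{\link{process_presence_channel}}) inside its fitted section
#' ellipses is strictly greater than zero.
#'
#' @param nuclei list from \code{\link{link_objects}}.
#' @param stack an \code{\link{image_stack}}.
#' @param channel marker channel ("ki67" for proliferation, "col1a1" for
#'   fibroblast identity).
#' @param kr kernel radius (px).
#' @param erode_px fitted-ellipse shrinkage before sampling (px), as in
#'   \code{\link{classify_nucleus}}.
#' @return Logical vector, one flag per nucleus.
#' @export
detect_positive <- function(nuclei, stack, channel = "ki67", kr = 5L,
                            erode_px = kr) {
  vol <- process_presence_channel(stack, channel, kr)
  dim_yx <- dim(vol)[1:2]
  vapply(nuclei, function(n) {
    tot <- 0; cnt <- 0
    for (s in n$sections) {
      e <- s$ellipse
      px <- raster_ellipse(e["cx"], e["cy"], max(e["a"] - erode_px, 1),
                           max(e["b"] - erode_px, 1), e["theta"], dim_yx)
      if (nrow(px) == 0) next
      tot <- tot + sum(vol[cbind(px, s$slice)])
      cnt <- cnt + nrow(px)
    }
    cnt > 0 && tot / cnt > 0
  }, logical(1))
}
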