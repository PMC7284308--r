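#' Optical-flow / contraction analysis parameters
#'
#' @param alpha Horn-Schunck regularization weight (> 0).  The weight is
#'   relative to image contrast; 0.05 suits unit-range frames (the
#'   classic value of ~10 was tuned to 8-bit data).
#' @param n_iter number of Jacobi iterations (>= 1).
#' @param pixel_size_um lateral calibration (um/px).
#' @param fps frame rate (default 100 frames/s).
#' @param bin_um vector-binning bin side (um, default 15).
#' @param selection_um analysis-selection side (um, default 300); must be
#'   at least \code{bin_um} and fit inside the frame.
#' @param selection_center optional c(row, col) px center of the selection
#'   (default: frame center).
#' @param bin_position optional c(bin_row, bin_col) for manual bin choice;
#'   \code{NULL} selects the maximum-velocity bin automatically.
#' @return An object of class \code{flow_params}.
#' @export
flow_params <- function(alpha = 0.05, n_iter = 100L, pixel_size_um = 1,
                        fps = 100, bin_um = 15, selection_um = 300,
                        selection_center = NULL, bin_position = NULL) {
  if (alpha <= 0) stopf("alpha must be > 0")
  if (n_iter < 1) stopf("n_iter must be >= 1")
  if (bin_um > selection_um) stopf("bin size must not exceed the selection")
  structure(as.list(environment()), class = "flow_params")
}

#' Horn-Schunck dense optical flow between two frames
#'
#' Classic variational estimate balancing brightness constancy against
#' field smoothness: spatiotemporal derivatives over the 2x2x2 cube,
#' Jacobi updates with the standard 1/6-1/12 neighbor-average kernel,
#' zero initialization.
#'
#' @param f1,f2 same-size grayscale matrices (consecutive frames).
#' @param alpha regularization weight.
#' @param n_iter iteration count.
#' @return A list with matrices \code{u} (flow along +x / columns) and
#'   \code{v} (along +y / rows), in px/frame.
#' @export
horn_schunck <- function(f1, f2, alpha = 0.05, n_iter = 100L) {
  if (!all(dim(f1) == dim(f2)))
    stopf("frame sizes differ: %s vs %s",
          paste(dim(f1), collapse = "x"), paste(dim(f2), collapse = "x"))
  s <- shift_mat
  ex <- 0.25 * (s(f1, 0, 1) - f1 + s(f1, 1, 1) - s(f1, 1, 0) +
                s(f2, 0, 1) - f2 + s(f2, 1, 1) - s(f2, 1, 0))
  ey <- 0.25 * (s(f1, 1, 0) - f1 + s(f1, 1, 1) - s(f1, 0, 1) +
                s(f2, 1, 0) - f2 + s(f2, 1, 1) - s(f2, 0, 1))
  et <- 0.25 * (f2 - f1 + s(f2, 0, 1) - s(f1, 0, 1) +
                s(f2, 1, 0) - s(f1, 1, 0) + s(f2, 1, 1) - s(f1, 1, 1))
  denom <- alpha^2 + ex^2 + ey^2
  u <- v <- matrix(0, nrow(f1), ncol(f1))
  navg <- function(m) {
    (s(m, -1, 0) + s(m, 1, 0) + s(m, 0, -1) + s(m, 0, 1)) / 6 +
      (s(m, -1, -1) + s(m, -1, 1) + s(m, 1, -1) + s(m, 1, 1)) / 12
  }
  for (i in seq_len(n_iter)) {
    ub <- navg(u); vb <- navg(v)
    frac <- (ex * ub + ey * vb + et) / denom
    u <- ub - ex * frac
    v <- vb - ey * frac
  }
  list(u = u, v = v)
}

#' Dense flow for a whole movie
#'
#' Frames are mean-normalized (damping global illumination flicker) and
#' Horn-Schunck flow is computed for every consecutive pair.
#'
#' @param frames array [y, x, t].
#' @param params a \code{\link{flow_params}}.
#' @return List of per-step flow fields (see \code{\link{horn_schunck}}).
#' @export
optical_flow <- function(frames, params = flow_params()) {
  nt <- dim(frames)[3]
  if (nt < 2) stopf("need at least 2 frames")
  gm <- mean(frames)
  norm <- lapply(seq_len(nt), function(t) {
    f <- frames[, , t]
    f / mean(f) * gm
  })
  lapply(seq_len(nt - 1L), function(t)
    horn_schunck(norm[[t]], norm[[t + 1L]], params$alpha, params$n_iter))
}

#' Bin velocity fields and extract the maximum-bin contraction profile
#'
#' Speeds are calibrated to um/s (px/frame x um/px x fps), averaged within
#' square bins over the centered (or user-positioned) selection, with the
#' per-bin SD across vectors retained.  In automatic mode the single bin
#' that is maximal at the recording's global peak frame is fixed for the
#' whole recording and its time course emitted.
#'
#' @param flows per-step flow fields from \code{\link{optical_flow}}.
#' @param params a \code{\link{flow_params}}.
#' @return A \code{contraction_profile}: data.frame with \code{time_s},
#'   \code{speed_um_s}, \code{sd_um_s}; the chosen bin and the full binned
#'   speed array are attached as attributes \code{bin} and \code{bins}.
#' @export
bin_and_select <- function(flows, params = flow_params()) {
  d <- dim(flows[[1]]$u)
  px <- params$pixel_size_um
  sel_px <- round(params$selection_um / px)
  bin_px <- max(1L, round(params$bin_um / px))
  ctr <- if (is.null(params$selection_center)) (d + 1) / 2
         else params$selection_center
  r0 <- round(ctr[1] - sel_px / 2) ; c0 <- round(ctr[2] - sel_px / 2)
  r1 <- r0 + sel_px - 1L; c1 <- c0 + sel_px - 1L
  if (r0 < 1 || c0 < 1 || r1 > d[1] || c1 > d[2])
    stopf("%d px selection does not fit the %d x %d frame", sel_px, d[1], d[2])
  nb <- sel_px %/% bin_px
  if (nb < 1) stopf("selection smaller than one bin")
  nt <- length(flows)
  bins_mean <- array(0, c(nb, nb, nt))
  bins_sd <- array(0, c(nb, nb, nt))
  ri <- r0 + seq_len(nb * bin_px) - 1L
  ci <- c0 + seq_len(nb * bin_px) - 1L
  bin_of <- rep(seq_len(nb), each = bin_px)
  for (t in seq_len(nt)) {
    sp <- sqrt(flows[[t]]$u[ri, ci]^2 + flows[[t]]$v[ri, ci]^2) * px *
      params$fps
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      vals <- sp[bin_of == i, bin_of == j]
      bins_mean[i, j, t] <- mean(vals)
      bins_sd[i, j, t] <- sd(as.vector(vals))
    }
  }
  if (is.null(params$bin_position)) {
    peak <- which(bins_mean == max(bins_mean), arr.ind = TRUE)[1, ]
    bin <- peak[1:2]
  } else bin <- params$bin_position
  profile <- contraction_profile(
    time_s = (seq_len(nt) - 0.5) / params$fps,
    speed_um_s = bins_mean[bin[1], bin[2], ],
    sd_um_s = bins_sd[bin[1], bin[2], ])
  attr(profile, "bin") <- bin
  attr(profile, "bins") <- bins_mean
  profile
}

#' Contraction profile container
#'
#' @param time_s frame-pair midpoint times (s).
#' @param speed_um_s tissue speed of the selected bin (um/s, >= 0).
#' @param sd_um_s per-bin SD across vectors (um/s).
#' @return A data.frame of class \code{contraction_profile}.
#' @export
contraction_profile <- function(time_s, speed_um_s, sd_um_s = NA_real_) {
  if (any(speed_um_s < 0)) stopf("speeds must be non-negative")
  structure(data.frame(time_s = time_s, speed_um_s = speed_um_s,
                       sd_um_s = sd_um_s),
            class = c("contraction_profile", "data.frame"))
}

#' Per-beat kinematic parameters of a contraction profile
#'
#' Beats are the contiguous epochs where speed exceeds
#' \code{threshold_frac} of the profile maximum (onset/offset crossings
#' linearly interpolated).  Within a beat with two speed humps the
#' interior minimum separates the contraction and relaxation phases;
#' single-hump beats split at the peak.  Five parameters are extracted per
#' beat - upstroke velocity and acceleration, relaxation velocity and
#' acceleration, beat duration - and averaged across beats.
#'
#' @param profile a \code{\link{contraction_profile}}.
#' @param min_beats minimum number of beats required (default 5).
#' @param threshold_frac onset/offset threshold as a fraction of the
#'   profile maximum (default 0.1).
#' @return A list: \code{per_beat} data.frame, \code{mean} and \code{sd}
#'   named vectors, \code{n_beats}.
#' @export
profile_parameters <- function(profile, min_beats = 5L,
                               threshold_frac = 0.1) {
  s <- profile$speed_um_s
  t <- profile$time_s
  thr <- threshold_frac * max(s)
  above <- s > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epochs <- cbind(starts[r$values], ends[r$values])
  if (nrow(epochs) < min_beats)
    stopf("found %d beats; at least %d required", nrow(epochs), min_beats)
  cross <- function(i1, i2) {  # interpolated threshold-crossing time
    if (i1 < 1 || i2 > length(s) || s[i1] == s[i2]) return(t[max(i1, 1)])
    t[i1] + (thr - s[i1]) / (s[i2] - s[i1]) * (t[i2] - t[i1])
  }
  beats <- lapply(seq_len(nrow(epochs)), function(k) {
    i0 <- epochs[k, 1]; i1 <- epochs[k, 2]
    t_on <- if (i0 > 1) cross(i0 - 1L, i0) else t[i0]
    t_off <- if (i1 < length(s)) cross(i1 + 1L, i1) else t[i1]
    seg <- s[i0:i1]
    pk <- pracma::findpeaks(seg)
    if (!is.null(pk) && nrow(pk) >= 2) {
      p_first <- min(pk[, 2]); p_last <- max(pk[, 2])
      split <- p_first - 1L + which.min(seg[p_first:p_last])
    } else split <- which.max(seg)
    con <- seg[1:split]; rel <- seg[split:length(seg)]
    dt <- diff(t[i0:i1])
    dcon <- if (split > 1) diff(seg[1:split]) / dt[1:(split - 1)] else 0
    drel <- if (split < length(seg))
      diff(seg[split:length(seg)]) / dt[split:(length(seg) - 1)] else 0
    data.frame(upstroke_velocity = max(con),
               upstroke_acceleration = max(dcon),
               relaxation_velocity = max(rel),
               relaxation_acceleration = max(abs(drel)),
               beat_duration = t_off - t_on,
               peak_time = t[i0 - 1L + which.max(seg)])
  })
  per_beat <- do.call(rbind, beats)
  cols <- c("upstroke_velocity", "upstroke_acceleration",
            "relaxation_velocity", "relaxation_acceleration",
            "beat_duration")
  list(per_beat = per_beat,
       mean = vapply(per_beat[cols], mean, numeric(1)),
       sd = vapply(per_beat[cols], sd, numeric(1)),
       n_beats = nrow(per_beat))
}

#' Contraction direction map
#'
#' Per-vector angle of motion, atan2(v, u) in (-pi, pi]; zero vectors are
#' masked as NA.
#'
#' @param flow a flow field (list with u, v) from
#'   \code{\link{horn_schunck}}.
#' @return Matrix of angles in radians.
#' @export
contraction_direction <- function(flow) {
  ang <- atan2(flow$v, flow$u)
  ang[flow$u == 0 & flow$v == 0] <- NA_real_
  ang
}

#' Normalized contraction duration
#'
#' Contraction duration divided by the square root of the inter-beat
#' interval, removing the rate dependence of the raw duration.
#'
#' @param cd contraction duration (s, > 0).
#' @param ibi inter-beat interval (s, > 0).
#' @return cd / sqrt(ibi), dimensionless.
#' @export
normalized_contraction_duration <- function(cd, ibi) {
  if (any(cd <= 0) || any(ibi <= 0))
    stopf("contraction duration and IBI must be positive")
  cd / sqrt(ibi)
}

#' Pacing rule for the follows-stimulation classifier
#'
#' @param rate_tol relative rate tolerance (default 0.15, i.e. +-15\%).
#' @param cv_cutoff amplitude-CV cutoff (default 0.28, accounting for
#'   random amplitude variation).
#' @return An object of class \code{pacing_rule}.
#' @export
pacing_rule <- function(rate_tol = 0.15, cv_cutoff = 0.28) {
  if (rate_tol <= 0 || rate_tol >= 1 || cv_cutoff <= 0 || cv_cutoff >= 1)
    stopf("rate_tol and cv_cutoff must lie in (0, 1)")
  structure(list(rate_tol = rate_tol, cv_cutoff = cv_cutoff),
            class = "pacing_rule")
}

#' Classify whether a tissue follows the pacing frequency
#'
#' The contraction rate is estimated from the beat intervals,
#' (n - 1) / (t_last - t_first); the tissue follows the stimulation when
#' the rate lies within \code{rate_tol} of the pacing rate and the
#' amplitude CV (SD with n-1 denominator over mean) is below
#' \code{cv_cutoff}.
#'
#' @param beats a \code{\link{beat_series}} (>= 3 beats).
#' @param pacing_hz applied stimulation frequency (Hz).
#' @param rule a \code{\link{pacing_rule}}.
#' @return A list: \code{follows} (logical), \code{rate_hz}, \code{cv}.
#' @export
classify_pacing <- function(beats, pacing_hz, rule = pacing_rule()) {
  n <- length(beats$times_s)
  if (n < 3) stopf("need at least 3 beats (got %d)", n)
  rate <- (n - 1) / (beats$times_s[n] - beats$times_s[1])
  cv <- sd(beats$amplitudes) / mean(beats$amplitudes)
  list(follows = abs(rate - pacing_hz) / pacing_hz <= rule$rate_tol &&
         cv < rule$cv_cutoff,
       rate_hz = rate, cv = cv)
}

#' Extract a beat series from a contraction profile
#'
#' Beat times are the speed-peak times; amplitudes are the peak speeds.
#'
#' @param profile a \code{\link{contraction_profile}}.
#' @param min_height_frac minimum peak height as a fraction of the
#'   profile maximum.
#' @return A \code{\link{beat_series}}.
#' @export
detect_beats <- function(profile, min_height_frac = 0.5) {
  pk <- pracma::findpeaks(profile$speed_um_s,
                          minpeakheight = min_height_frac *
                            max(profile$speed_um_s))
  if (is.null(pk) || nrow(pk) < 1) stopf("no beats detected")
  ord <- order(pk[, 2])
  beat_series(profile$time_s[pk[ord, 2]], pk[ord, 1])
}
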