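# Action-potential and calcium-transient feature extraction.

# Upstroke onset samples: derivative above `thr_v_s` (mV/ms = V/s)
# sustained for `sustained_ms`.
find_upstrokes <- function(v, rate_khz, thr_v_s = 5, sustained_ms = 1) {
  d <- diff(v) * rate_khz
  k <- max(1L, round(sustained_ms * rate_khz))
  r <- rle(d > thr_v_s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values & r$lengths >= k]
}

#' Action-potential features
#'
#' Per beat: RMP is the mean diastolic voltage over the window before the
#' upstroke onset, APA the peak minus RMP, Vmax the maximum upstroke
#' derivative (mV/ms = V/s), and APD90 the time from the Vmax instant to
#' the first crossing of peak - 0.9 APA (linearly interpolated).
#' Features are averaged across beats.
#'
#' @param trace an \code{ap_trace} (see \code{\link{generate_ap_trace}})
#'   or any list with \code{voltage_mv} and \code{rate_khz}.
#' @param diastolic_ms RMP window before the upstroke (default 50 ms).
#' @param upstroke_thr_v_s,sustained_ms upstroke detector: derivative
#'   threshold (V/s) and required duration.
#' @return A list: \code{rmp_mv}, \code{apa_mv}, \code{apd90_ms},
#'   \code{vmax_v_s}, \code{n_beats}, \code{per_beat}.
#' @export
ap_features <- function(trace, diastolic_ms = 50, upstroke_thr_v_s = 5,
                        sustained_ms = 1) {
  v <- trace$voltage_mv
  rk <- trace$rate_khz
  on <- find_upstrokes(v, rk, upstroke_thr_v_s, sustained_ms)
  if (length(on) == 0) stopf("no action potential detected")
  dwin <- max(1L, round(diastolic_ms * rk))
  d <- diff(v) * rk
  rows <- lapply(seq_along(on), function(i) {
    o <- on[i]
    lim <- if (i < length(on)) on[i + 1] - 1L else length(v)
    rmp <- mean(v[max(1L, o - dwin):max(1L, o - 1L)])
    pk <- o - 1L + which.max(v[o:lim])
    apa <- v[pk] - rmp
    dseg <- d[o:max(o, pk - 1L)]
    ties <- which(dseg >= max(dseg) - 1e-9)
    iv <- o - 1L + ties[length(ties)]  # last tie: end of a linear upstroke
    vmax <- max(dseg)
    t_vmax <- (iv - 0.5) / rk
    lvl <- v[pk] - 0.9 * apa
    below <- which(v[pk:lim] <= lvl)
    if (length(below) == 0) return(NULL)  # repolarization incomplete
    ib <- pk - 1L + below[1]
    t_cross <- if (ib > pk && v[ib - 1L] > v[ib]) {
      ((ib - 1L) + (v[ib - 1L] - lvl) / (v[ib - 1L] - v[ib]) - 1) / rk
    } else (ib - 1) / rk
    data.frame(rmp = rmp, apa = apa, vmax = vmax,
               apd90 = t_cross - t_vmax)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stopf("no complete action potential in the record")
  pb <- do.call(rbind, rows)
  list(rmp_mv = mean(pb$rmp), apa_mv = mean(pb$apa),
       apd90_ms = mean(pb$apd90), vmax_v_s = mean(pb$vmax),
       n_beats = nrow(pb), per_beat = pb)
}

#' Notch detection rule
#'
#' @param cutoff derivative cutoff in mV/ms (must be negative; default
#'   -3, set to ignore random trace oscillations).
#' @param window_ms peak-region length after the AP peak (default 50 ms).
#' @param smooth_n moving-mean width in samples applied before
#'   differentiation (default 3).
#' @return An object of class \code{notch_rule}.
#' @export
notch_rule <- function(cutoff = -3, window_ms = 50, smooth_n = 3L) {
  if (cutoff >= 0) stopf("cutoff must be negative")
  structure(list(cutoff = cutoff, window_ms = window_ms,
                 smooth_n = as.integer(smooth_n)), class = "notch_rule")
}

#' Detect the I_to notch of an action potential
#'
#' The voltage is lightly smoothed (moving mean), differentiated
#' (mV/ms), and the minimum derivative within the peak region (peak to
#' peak + window) is compared to the cutoff; derivatives below it flag a
#' notch.  With several beats the minimum over all peak regions is used.
#'
#' @param trace an \code{ap_trace}.
#' @param rule a \code{\link{notch_rule}}.
#' @return A list: \code{notch} (logical), \code{min_derivative} (mV/ms).
#' @export
detect_notch <- function(trace, rule = notch_rule()) {
  v <- trace$voltage_mv
  rk <- trace$rate_khz
  k <- rule$smooth_n
  vs <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  vs[is.na(vs)] <- v[is.na(vs)]
  d <- diff(vs) * rk
  on <- find_upstrokes(v, rk)
  if (length(on) == 0) stopf("no action potential detected")
  win <- round(rule$window_ms * rk)
  mins <- vapply(seq_along(on), function(i) {
    o <- on[i]
    lim <- if (i < length(on)) on[i + 1] - 1L else length(v)
    pk <- o - 1L + which.max(v[o:lim])
    min(d[pk:min(pk + win, length(d), lim - 1L)])
  }, numeric(1))
  list(notch = min(mins) < rule$cutoff, min_derivative = min(mins))
}

#' Fraction of traces exhibiting a notch
#'
#' @param traces list of \code{ap_trace} objects.
#' @param rule a \code{\link{notch_rule}}.
#' @return Percentage of notched traces.
#' @export
notch_fraction <- function(traces, rule = notch_rule()) {
  if (length(traces) == 0) stopf("no traces supplied")
  flags <- vapply(traces, function(tr) detect_notch(tr, rule)$notch,
                  logical(1))
  100 * mean(flags)
}

#' Background-subtracted, baseline-normalized fluorescence (dF/F)
#'
#' For a movie, the tissue mask is the maximum projection thresholded at
#' its overall mean plus SD; F(t) is the in-mask mean minus the mean of
#' the user-selected background region (chosen outside the tissue).  F0
#' is the mean of the lowest-decile frames and dF/F = (F - F0) / F0.
#'
#' @param x movie array [y, x, t], or a numeric raw-fluorescence vector.
#' @param background logical matrix (movie) or numeric vector/scalar
#'   (trace) giving the background signal to subtract.
#' @param rate_hz sampling rate (Hz).
#' @return A \code{calcium_trace} (time_s, dff, rate_hz).
#' @export
compute_dff <- function(x, background, rate_hz) {
  if (is.array(x) && length(dim(x)) == 3L) {
    maxp <- apply(x, c(1, 2), max)
    mask <- maxp > mean(maxp) + sd(as.vector(maxp))
    if (!any(mask)) stopf("empty tissue mask (mean + SD threshold)")
    if (!is.matrix(background) || !is.logical(background))
      stopf("for a movie, `background` must be a logical region mask")
    f <- vapply(seq_len(dim(x)[3]), function(t)
      mean(x[, , t][mask]) - mean(x[, , t][background]), numeric(1))
  } else {
    f <- as.numeric(x) - as.numeric(background)
  }
  f0 <- mean(f[f <= quantile(f, 0.1)])
  if (f0 <= 0) stopf("non-positive baseline F0; check background selection")
  structure(list(time_s = (seq_along(f) - 1) / rate_hz,
                 dff = (f - f0) / f0, rate_hz = rate_hz),
            class = "calcium_trace")
}

#' Calcium transient kinetics
#'
#' Per transient (windows between consecutive stimuli): amplitude from
#' the window-start baseline to the peak; time to peak from the
#' 10\%-of-amplitude onset crossing; decay times from the peak to the
#' first crossings of 50\% and 10\% of the amplitude above baseline.
#' Transients whose 90\% decay is not reached in the record are excluded
#' with a warning.  Results are averaged across transients, in ms.
#'
#' @param trace a \code{calcium_trace}.
#' @param stim_times_s stimulus times (s); defaults to the trace's own.
#' @param onset_frac onset threshold as a fraction of amplitude.
#' @return A list: \code{time_to_peak_ms}, \code{peak_to_50_ms},
#'   \code{peak_to_90_ms}, \code{n_transients}, \code{per_transient}.
#' @export
transient_kinetics <- function(trace, stim_times_s = NULL,
                               onset_frac = 0.1) {
  if (is.null(stim_times_s)) stim_times_s <- trace$stim_times_s
  if (is.null(stim_times_s) || length(stim_times_s) == 0)
    stopf("stimulus times required")
  y <- trace$dff; tt <- trace$time_s
  bounds <- c(stim_times_s, max(tt) + 1 / trace$rate_hz)
  interp_cross <- function(i0, i1, lvl, falling) {
    idx <- i0:i1
    hit <- if (falling) which(y[idx] <= lvl) else which(y[idx] >= lvl)
    if (length(hit) == 0) return(NA_real_)
    j <- idx[hit[1]]
    if (j > i0 && y[j] != y[j - 1])
      tt[j - 1] + (lvl - y[j - 1]) / (y[j] - y[j - 1]) * (tt[j] - tt[j - 1])
    else tt[j]
  }
  rows <- list()
  for (i in seq_along(stim_times_s)) {
    i0 <- which(tt >= bounds[i])[1]
    i1 <- max(which(tt < bounds[i + 1]))
    if (is.na(i0) || i1 <= i0) next
    base <- y[i0]
    pk <- i0 - 1L + which.max(y[i0:i1])
    amp <- y[pk] - base
    if (amp <= 0) next
    t_on <- interp_cross(i0, pk, base + onset_frac * amp, falling = FALSE)
    t50 <- interp_cross(pk, i1, base + 0.5 * amp, falling = TRUE)
    t90 <- interp_cross(pk, i1, base + 0.1 * amp, falling = TRUE)
    if (is.na(t90)) {
      warnf("transient %d: 90%% decay not reached; excluded", i)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      time_to_peak = (tt[pk] - t_on) * 1000,
      peak_to_50 = (t50 - tt[pk]) * 1000,
      peak_to_90 = (t90 - tt[pk]) * 1000)
  }
  if (length(rows) == 0) stopf("no complete transient found")
  pt <- do.call(rbind, rows)
  list(time_to_peak_ms = mean(pt$time_to_peak),
       peak_to_50_ms = mean(pt$peak_to_50),
       peak_to_90_ms = mean(pt$peak_to_90),
       n_transients = nrow(pt), per_transient = pt)
}

#' Caffeine-induced calcium-release amplitude ratio
#'
#' Transient peaks are detected on the lightly smoothed trace; each
#' amplitude is measured from its local baseline (the trace minimum since
#' the previous peak).  The ratio is the amplitude of the first peak
#' after caffeine over the mean amplitude of the four peaks before it - a
#' proxy for sarcoplasmic-reticulum calcium content.
#'
#' @param trace a \code{calcium_trace}.
#' @param caffeine_time_s time of caffeine addition (s).
#' @param min_height_frac peak-detection floor as a fraction of the trace
#'   range above its minimum.
#' @return A list: \code{ratio}, \code{pre_amplitudes},
#'   \code{post_amplitude}.
#' @export
caffeine_ratio <- function(trace, caffeine_time_s, min_height_frac = 0.25) {
  y <- trace$dff; tt <- trace$time_s
  k <- 3L
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  pk <- pracma::findpeaks(ys, minpeakheight = min(ys) +
                            min_height_frac * diff(range(ys)),
                          minpeakdistance = max(3L, round(0.2 * trace$rate_hz)))
  if (is.null(pk)) stopf("no transients detected")
  idx <- sort(pk[, 2])
  local_amps <- function(idx) {
    vapply(seq_along(idx), function(i) {
      from <- if (i == 1) 1L else idx[i - 1]
      y[idx[i]] - min(y[from:idx[i]])
    }, numeric(1))
  }
  # drop minor noise bumps riding on decay tails, then re-measure the
  # surviving peaks from their true local baselines
  amp <- local_amps(idx)
  idx <- idx[amp >= 0.2 * max(amp)]
  amp <- local_amps(idx)
  pre <- which(tt[idx] < caffeine_time_s)
  post <- which(tt[idx] >= caffeine_time_s)
  if (length(pre) < 4 || length(post) < 1)
    stopf("need >= 4 pre-caffeine and >= 1 post-caffeine transients (got %d and %d)",
          length(pre), length(post))
  pre4 <- tail(pre, 4)
  list(ratio = amp[post[1]] / mean(amp[pre4]),
       pre_amplitudes = amp[pre4], post_amplitude = amp[post[1]])
}
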