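#' Generate a piecewise-analytic action-potential trace
#'
#' Each beat is: resting baseline, linear upstroke, optional post-peak
#' notch (linear dip, emulating the fast I_to repolarization), then
#' exponential repolarization whose time constant is solved so that the
#' true APD90 equals the requested value exactly.  Ground-truth features
#' are emitted analytically, never re-measured from the samples.
#'
#' @param rate_khz sampling rate in kHz (default 10, i.e. 0.1 ms/sample).
#' @param rmp_mv resting membrane potential (mV).
#' @param apa_mv action-potential amplitude (mV); peak = rmp + apa.
#' @param apd90_ms action-potential duration at 90\% repolarization (ms),
#'   measured from the end of the upstroke.
#' @param upstroke_ms duration of the linear upstroke (ms); the true
#'   maximum upstroke velocity is \code{apa_mv / upstroke_ms} mV/ms (V/s).
#' @param notch logical; add an I_to-like notch after the peak.
#' @param notch_depth_mv,notch_fall_ms notch dip depth and fall time; the
#'   true minimum derivative in the peak region is
#'   \code{-notch_depth_mv / notch_fall_ms} mV/ms.
#' @param n_beats,period_ms,pre_ms beat count, pacing period and baseline
#'   before the first upstroke.
#' @param noise_sd additive Gaussian noise SD (mV).
#' @param seed integer seed.
#' @return An object of class \code{ap_trace}: \code{time_ms},
#'   \code{voltage_mv}, \code{rate_khz}, \code{stim_times_ms} and a
#'   \code{truth} list (rmp, apa, apd90, vmax, notch,
#'   notch_min_derivative).
#' @export
generate_ap_trace <- function(rate_khz = 10, rmp_mv = -80, apa_mv = 110,
                              apd90_ms = 300, upstroke_ms = 2,
                              notch = FALSE, notch_depth_mv = 10,
                              notch_fall_ms = 2,
                              n_beats = 3L, period_ms = 1000, pre_ms = 100,
                              noise_sd = 0, seed = 1L) {
  if (rate_khz <= 0) stopf("sampling rate must be > 0")
  if (apa_mv <= 0) stopf("APA must be > 0")
  if (notch && notch_depth_mv >= apa_mv)
    stopf("notch depth (%.3g) must be smaller than APA (%.3g)",
          notch_depth_mv, apa_mv)
  if (notch && notch_depth_mv >= 0.9 * apa_mv)
    stopf("notch depth must be < 90%% of APA for a well-defined APD90")
  peak <- rmp_mv + apa_mv
  dt <- 1 / rate_khz
  total_ms <- pre_ms + n_beats * period_ms
  tt <- seq(0, total_ms, by = dt)
  v <- rep(rmp_mv, length(tt))
  stim <- pre_ms + (seq_len(n_beats) - 1) * period_ms
  if (notch) {
    tau <- (apd90_ms - notch_fall_ms) /
      log((apa_mv - notch_depth_mv) / (0.1 * apa_mv))
    v_repol0 <- peak - notch_depth_mv
    t_repol0 <- upstroke_ms + notch_fall_ms
  } else {
    tau <- apd90_ms / log(10)
    v_repol0 <- peak
    t_repol0 <- upstroke_ms
  }
  for (t0 in stim) {
    rel <- tt - t0
    up <- rel >= 0 & rel < upstroke_ms
    v[up] <- rmp_mv + apa_mv * rel[up] / upstroke_ms
    if (notch) {
      fall <- rel >= upstroke_ms & rel < t_repol0
      v[fall] <- peak - notch_depth_mv * (rel[fall] - upstroke_ms) / notch_fall_ms
    }
    dec <- rel >= t_repol0 & rel < period_ms
    v[dec] <- rmp_mv + (v_repol0 - rmp_mv) * exp(-(rel[dec] - t_repol0) / tau)
  }
  if (noise_sd > 0) v <- with_rng(seed, v + rnorm(length(v), 0, noise_sd))
  structure(list(
    time_ms = tt, voltage_mv = v, rate_khz = rate_khz, stim_times_ms = stim,
    truth = list(rmp = rmp_mv, apa = apa_mv, apd90 = apd90_ms,
                 vmax = apa_mv / upstroke_ms, notch = notch,
                 notch_min_derivative =
                   if (notch) -notch_depth_mv / notch_fall_ms else NA_real_)),
    class = "ap_trace")
}

#' Generate a beat series with an exactly controlled amplitude CV
#'
#' Beat times are regular at the requested rate; amplitudes are drawn
#' Gaussian and then affinely rescaled so the sample coefficient of
#' variation (SD with n-1 denominator over mean) equals \code{amp_cv}
#' exactly.
#'
#' @param rate_hz beat rate (Hz).
#' @param n_beats number of beats (>= 3).
#' @param amp_mean,amp_cv amplitude mean (a.u.) and target CV.
#' @param seed integer seed.
#' @return An object of class \code{beat_series} with \code{times_s} and
#'   \code{amplitudes}.
#' @export
generate_beat_series <- function(rate_hz = 1, n_beats = 20L, amp_mean = 1,
                                 amp_cv = 0.1, seed = 1L) {
  if (rate_hz <= 0) stopf("rate must be > 0")
  if (amp_cv < 0) stopf("CV must be >= 0")
  if (n_beats < 3) stopf("need >= 3 beats")
  times <- (seq_len(n_beats) - 1) / rate_hz
  if (amp_cv == 0) {
    amps <- rep(amp_mean, n_beats)
  } else {
    amps <- with_rng(seed, rnorm(n_beats))
    amps <- amp_mean + (amps - mean(amps)) * (amp_cv * amp_mean / sd(amps))
  }
  beat_series(times, amps)
}

#' Beat series container
#'
#' @param times_s strictly increasing beat times (s).
#' @param amplitudes beat amplitudes (a.u.), same length.
#' @return An object of class \code{beat_series}.
#' @export
beat_series <- function(times_s, amplitudes) {
  if (length(times_s) != length(amplitudes))
    stopf("times and amplitudes must have equal length")
  if (any(diff(times_s) <= 0)) stopf("beat times must be strictly increasing")
  structure(list(times_s = times_s, amplitudes = amplitudes),
            class = "beat_series")
}

#' Generate a calcium transient trace with analytic kinetics
#'
#' Each transient rises linearly from its onset and decays exponentially.
#' The \code{time_to_peak_ms} parameter is defined, like the measurement,
#' from the 10\%-of-amplitude crossing to the peak (so the linear rise
#' lasts \code{time_to_peak_ms / 0.9}).  True decay times follow in closed
#' form: peak to 50\% = tau ln 2, peak to 90\% = tau ln 10.
#'
#' @param rate_hz sampling rate (Hz).
#' @param stim_times_s transient onset times (s).
#' @param amplitudes peak dF/F amplitude per transient (recycled).
#' @param time_to_peak_ms 10\%-to-peak rise time (ms).
#' @param tau_decay_ms exponential decay constant (ms).
#' @param baseline baseline dF/F level.
#' @param noise_sd additive Gaussian noise SD.
#' @param duration_s total duration (default: last stimulus + 5 tau).
#' @param seed integer seed.
#' @return An object of class \code{calcium_trace}: \code{time_s},
#'   \code{dff}, \code{rate_hz}, \code{stim_times_s} and a \code{truth}
#'   list (time_to_peak_ms, peak_to_50_ms, peak_to_90_ms, amplitudes).
#' @export
generate_calcium_trace <- function(rate_hz = 100, stim_times_s = c(1, 2, 3),
                                   amplitudes = 1, time_to_peak_ms = 150,
                                   tau_decay_ms = 300, baseline = 0,
                                   noise_sd = 0, duration_s = NULL,
                                   seed = 1L) {
  if (rate_hz <= 0) stopf("sampling rate must be > 0")
  amps <- rep_len(amplitudes, length(stim_times_s))
  rise_s <- time_to_peak_ms / 0.9 / 1000
  tau_s <- tau_decay_ms / 1000
  if (is.null(duration_s)) duration_s <- max(stim_times_s) + rise_s + 5 * tau_s
  tt <- seq(0, duration_s, by = 1 / rate_hz)
  y <- rep(baseline, length(tt))
  for (i in seq_along(stim_times_s)) {
    rel <- tt - stim_times_s[i]
    up <- rel >= 0 & rel < rise_s
    y[up] <- y[up] + amps[i] * rel[up] / rise_s
    dec <- rel >= rise_s
    y[dec] <- y[dec] + amps[i] * exp(-(rel[dec] - rise_s) / tau_s)
  }
  if (noise_sd > 0) y <- with_rng(seed, y + rnorm(length(y), 0, noise_sd))
  structure(list(
    time_s = tt, dff = y, rate_hz = rate_hz, stim_times_s = stim_times_s,
    truth = list(time_to_peak_ms = time_to_peak_ms,
                 peak_to_50_ms = tau_decay_ms * log(2),
                 peak_to_90_ms = tau_decay_ms * log(10),
                 amplitudes = amps)),
    class = "calcium_trace")
}

#' Read / write two-column trace CSVs
#'
#' Traces are stored as plain CSV with columns \code{time} and
#' \code{value}.
#'
#' @param time,value numeric vectors of equal length.
#' @param path CSV path.
#' @return \code{write_trace_csv} returns \code{path} invisibly;
#'   \code{read_trace_csv} returns a data.frame with columns time, value.
#' @export
write_trace_csv <- function(time, value, path) {
  write.csv(data.frame(time = time, value = value), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time", "value") %in% names(df)))
    stopf("trace CSV must have columns 'time' and 'value'")
  df[c("time", "value")]
}
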