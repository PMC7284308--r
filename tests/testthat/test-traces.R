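test_that("AP features recover the analytic generator truth", {
  tr <- generate_ap_trace(rmp_mv = -80, apa_mv = 110, apd90_ms = 300,
                          upstroke_ms = 2, n_beats = 1)
  f <- ap_features(tr)
  expect_lt(abs(f$rmp_mv - (-80)), 1)
  expect_lt(abs(f$apa_mv - 110), 1)
  expect_lt(abs(f$vmax_v_s - 55) / 55, 0.05)
  expect_lt(abs(f$apd90_ms - 300), 2 / tr$rate_khz)  # within 2 samples
  expect_error(ap_features(list(voltage_mv = rep(-80, 1000),
                                rate_khz = 10)), "no action potential")
  # time-offset invariance (features are offsets from the upstroke)
  tr2 <- generate_ap_trace(pre_ms = 400, n_beats = 1)
  f2 <- ap_features(tr2)
  expect_equal(f2$apd90_ms, ap_features(generate_ap_trace(n_beats = 1))$apd90_ms)
  # baseline voltage offset shifts RMP only
  tr3 <- tr
  tr3$voltage_mv <- tr$voltage_mv + 7
  f3 <- ap_features(tr3)
  expect_equal(f3$rmp_mv, f$rmp_mv + 7, tolerance = 1e-9)
  expect_equal(f3$apa_mv, f$apa_mv, tolerance = 1e-9)
})

test_that("notch detection follows the derivative cutoff", {
  n5 <- generate_ap_trace(notch = TRUE, notch_depth_mv = 10,
                          notch_fall_ms = 2, n_beats = 1)
  n1 <- generate_ap_trace(notch = TRUE, notch_depth_mv = 2,
                          notch_fall_ms = 2, n_beats = 1)
  smooth <- generate_ap_trace(n_beats = 1)
  expect_true(detect_notch(n5)$notch)       # min derivative -5 < -3
  expect_false(detect_notch(n1)$notch)      # min derivative -1 > -3
  expect_false(detect_notch(smooth)$notch)
  expect_equal(detect_notch(n5)$min_derivative, -5, tolerance = 0.05)
  # monotone in notch depth
  flags <- vapply(seq(1, 9, by = 2), function(d)
    detect_notch(generate_ap_trace(notch = TRUE, notch_depth_mv = d,
                                   notch_fall_ms = 2,
                                   n_beats = 1))$notch, logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
  # fraction over a set of traces
  traces <- c(replicate(4, n5, simplify = FALSE),
              replicate(6, smooth, simplify = FALSE))
  expect_equal(notch_fraction(traces), 40)
  expect_error(notch_fraction(list()), "no traces")
  expect_error(notch_rule(cutoff = 1), "negative")
})

test_that("dF/F handles movies, offsets and gain as documented", {
  mov <- array(0.2, c(20, 20, 50))
  mov[5:15, 5:15, ] <- 1
  mov[5:15, 5:15, 21:50] <- 1.4     # step of 0.5 x F0 above baseline
  bg <- matrix(FALSE, 20, 20); bg[18:20, 18:20] <- TRUE
  tr <- compute_dff(mov, bg, rate_hz = 10)
  expect_equal(max(tr$dff), 0.5, tolerance = 0.01 * 0.5)
  expect_equal(min(tr$dff), 0, tolerance = 1e-9)
  # constant movie -> flat zero
  expect_error(compute_dff(array(1, c(10, 10, 5)), bg[1:10, 1:10], 10),
               "empty tissue mask")
  flat <- compute_dff(rep(5, 100), 1, rate_hz = 10)
  expect_true(all(abs(flat$dff) < 1e-12))
  # background offset invariance
  tr_off <- compute_dff(mov + 0.3, bg, rate_hz = 10)
  expect_equal(tr_off$dff, tr$dff, tolerance = 1e-9)
  # global gain invariance
  tr_gain <- compute_dff(mov * 4, bg, rate_hz = 10)
  expect_equal(tr_gain$dff, tr$dff, tolerance = 1e-9)
})

test_that("transient kinetics match the closed forms", {
  ca <- generate_calcium_trace(rate_hz = 1000,
                               stim_times_s = c(0.5, 3.5, 6.5),
                               time_to_peak_ms = 150, tau_decay_ms = 300,
                               duration_s = 9.5)
  k <- transient_kinetics(ca)
  expect_equal(k$n_transients, 3)
  expect_lt(abs(k$time_to_peak_ms - 150), 1)          # one sample at 1 kHz
  expect_lt(abs(k$peak_to_50_ms - 300 * log(2)) / (300 * log(2)), 0.02)
  expect_lt(abs(k$peak_to_90_ms - 300 * log(10)) / (300 * log(10)), 0.02)
  expect_gt(k$peak_to_90_ms, k$peak_to_50_ms)
  # truncated decay excluded with a warning
  short <- generate_calcium_trace(rate_hz = 1000, stim_times_s = c(0.5, 4.0),
                                  tau_decay_ms = 300, duration_s = 4.3)
  expect_warning(k2 <- transient_kinetics(short), "excluded")
  expect_equal(k2$n_transients, 1)
})

test_that("caffeine ratio matches arithmetic and generator truth", {
  cf <- generate_calcium_trace(rate_hz = 200,
                               stim_times_s = c(1, 3, 5, 7, 10),
                               amplitudes = c(1, 1, 1, 1, 2),
                               tau_decay_ms = 250, duration_s = 13)
  expect_equal(caffeine_ratio(cf, 9)$ratio, 2, tolerance = 0.01)
  cf2 <- generate_calcium_trace(rate_hz = 200,
                                stim_times_s = c(1, 3, 5, 7, 10),
                                amplitudes = c(0.9, 1.0, 1.1, 1.0, 1.0),
                                tau_decay_ms = 250, duration_s = 13)
  expect_equal(caffeine_ratio(cf2, 9)$ratio, 1, tolerance = 0.01)
  # noisy generator at ratio 1.5
  cf3 <- generate_calcium_trace(rate_hz = 200,
                                stim_times_s = c(1, 3, 5, 7, 10),
                                amplitudes = c(1, 1, 1, 1, 1.5),
                                tau_decay_ms = 250, noise_sd = 0.02,
                                duration_s = 13, seed = 4)
  expect_equal(caffeine_ratio(cf3, 9)$ratio, 1.5, tolerance = 0.05 * 1.5)
  expect_error(caffeine_ratio(generate_calcium_trace(
    rate_hz = 200, stim_times_s = c(1, 3), duration_s = 6), 2),
    "pre-caffeine")
})
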