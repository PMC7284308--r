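test_that("Horn-Schunck flow is exact on trivial cases", {
  set.seed(5)
  f <- EBImage::gblur(matrix(runif(48 * 48), 48, 48), 2)
  z <- horn_schunck(f, f)
  expect_equal(max(abs(z$u)), 0)
  expect_equal(max(abs(z$v)), 0)
  expect_error(horn_schunck(f, f[1:10, ]), "sizes differ")
})

test_that("flow recovers translations linearly and equivariantly", {
  mk <- function(v) generate_movie(movie_recipe(n_frames = 4L,
                                                velocity_px = c(v, 0),
                                                size_px = 96L, seed = 2))
  i <- 20:76
  f5 <- mk(0.5)$frames
  u5 <- mean(horn_schunck(f5[, , 2], f5[, , 3])$u[i, i])
  expect_lt(abs(u5 - 0.5) / 0.5, 0.10)
  f25 <- mk(0.25)$frames
  u25 <- mean(horn_schunck(f25[, , 2], f25[, , 3])$u[i, i])
  expect_lt(abs(u5 / u25 - 2), 0.15 * 2)
  # 90-degree rotation permutes the components (interior means)
  rot90 <- function(m) t(m)[nrow(m):1, ]
  set.seed(6)
  g1 <- EBImage::gblur(matrix(runif(64 * 64), 64, 64), 2)
  g2 <- mtphen:::bilinear_warp(g1, 0.4, 0.2)
  fl <- horn_schunck(g1, g2)
  flr <- horn_schunck(rot90(g1), rot90(g2))
  j <- 10:54
  expect_equal(mean(flr$u[j, j]), mean(fl$v[j, j]), tolerance = 1e-2)
  expect_equal(mean(flr$v[j, j]), -mean(fl$u[j, j]), tolerance = 1e-2)
})

test_that("binning calibrates px/frame to um/s and picks the active bin", {
  mv <- generate_movie(movie_recipe(n_frames = 12L, velocity_px = c(0.5, 0),
                                    size_px = 96L, seed = 2))
  fp <- flow_params(pixel_size_um = 1, fps = 100, selection_um = 60,
                    bin_um = 15)
  pr <- bin_and_select(optical_flow(mv$frames, fp), fp)
  expect_true(all(abs(pr$speed_um_s - 50) / 50 < 0.10))
  expect_true(all(is.finite(pr$sd_um_s)))
  # zero motion: exactly zero profile
  mv0 <- generate_movie(movie_recipe(n_frames = 5L, velocity_px = c(0, 0),
                                     size_px = 64L, seed = 2))
  pr0 <- bin_and_select(optical_flow(mv0$frames, fp), fp)
  expect_equal(max(pr0$speed_um_s), 0)
  # localized patch: the auto-selected bin lies inside the patch
  mreg <- generate_movie(movie_recipe(n_frames = 16L,
                                      velocity_px = c(0.8, 0),
                                      size_px = 128L,
                                      region = list(cx = 40, cy = 40,
                                                    radius = 25), seed = 4))
  fpr <- flow_params(pixel_size_um = 1, fps = 100, selection_um = 120,
                     bin_um = 15)
  bin <- attr(bin_and_select(optical_flow(mreg$frames, fpr), fpr), "bin")
  ctr_px <- (bin - 0.5) * 15 + (128 - 120) / 2
  expect_lt(sqrt(sum((ctr_px - c(40, 40))^2)), 25)
  # selection must fit the frame
  expect_error(bin_and_select(optical_flow(mv0$frames, fp),
                              flow_params(pixel_size_um = 1,
                                          selection_um = 300)),
               "does not fit")
})

test_that("profile parameters recover pulse kinematics", {
  pr <- pulse_profile(n_beats = 6, peak = 30, width_s = 0.4)
  pp <- profile_parameters(pr)
  expect_equal(pp$n_beats, 6)
  expect_lt(abs(pp$mean[["upstroke_velocity"]] - 30) / 30, 0.05)
  # symmetric pulses: contraction and relaxation velocities equal
  expect_lt(abs(pp$mean[["upstroke_velocity"]] -
                pp$mean[["relaxation_velocity"]]) / 30, 0.05)
  # beat duration: raised-cosine crossing of the 10% threshold,
  # 0.4 * (1 - acos(0.8) / pi) analytically
  dur <- 0.4 * (1 - acos(1 - 0.2) / pi)
  expect_lt(abs(pp$mean[["beat_duration"]] - dur), 0.01)
  expect_error(profile_parameters(pulse_profile(n_beats = 3)), "at least 5")
})

test_that("direction, normalized duration and pacing rule are exact", {
  f <- list(u = matrix(c(1, 0, -1, 0), 2, 2),
            v = matrix(c(0, 1, 0, 0), 2, 2))
  ang <- contraction_direction(f)
  expect_equal(ang[1, 1], 0)
  expect_equal(ang[2, 1], pi / 2)
  expect_equal(ang[1, 2], pi)
  expect_true(is.na(ang[2, 2]))
  expect_equal(normalized_contraction_duration(0.4, 1.0), 0.4)
  expect_equal(normalized_contraction_duration(0.4, 0.25), 0.8)
  expect_equal(normalized_contraction_duration(0.3, 2.25), 0.2)
  expect_error(normalized_contraction_duration(0, 1), "positive")

  for (dev in c(0, 0.14, 0.16, 0.20)) for (cv in c(0.10, 0.27, 0.29)) {
    b <- generate_beat_series(rate_hz = 2 * (1 + dev), n_beats = 20,
                              amp_cv = cv, seed = 7)
    res <- classify_pacing(b, 2)
    expect_identical(res$follows, dev <= 0.15 && cv < 0.28)
  }
  expect_error(classify_pacing(beat_series(c(0, 1), c(1, 1)), 1),
               "at least 3")
  expect_error(pacing_rule(rate_tol = 1.2), "lie in")
})

test_that("beat series are extracted from contraction profiles", {
  pr <- pulse_profile(n_beats = 6, peak = 30, width_s = 0.3, period_s = 0.5)
  b <- detect_beats(pr)
  expect_length(b$times_s, 6)
  expect_equal(diff(b$times_s), rep(0.5, 5), tolerance = 0.05)
  res <- classify_pacing(b, 2)
  expect_true(res$follows)
  expect_equal(res$rate_hz, 2, tolerance = 0.02)
})
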