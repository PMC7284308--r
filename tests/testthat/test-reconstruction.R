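test_that("moment ellipse fit matches shape, orientation and area", {
  rect <- as.matrix(expand.grid(row = 1:11, col = 1:21))
  e <- fit_ellipse(rect)
  expect_equal(unname(e["theta"]), 0)
  expect_lt(abs(e[["a"]] / e[["b"]] - 21 / 11), 0.05 * 21 / 11)
  expect_equal(pi * e[["a"]] * e[["b"]], nrow(rect), tolerance = 1e-6)
  disk <- mtphen:::raster_ellipse(30, 30, 10, 10, 0)
  ed <- fit_ellipse(disk)
  expect_lt(abs(ed[["a"]] / ed[["b"]] - 1), 0.02)
  # degenerate (collinear) pixels floor the minor axis
  expect_warning(el <- fit_ellipse(cbind(row = rep(5, 30), col = 1:30)),
                 "degenerate")
  expect_equal(unname(el["b"]), 0.5)
})

test_that("rasterized ellipse overlap matches geometry and an MC oracle", {
  e1 <- c(cx = 20, cy = 20, a = 8, b = 5, theta = 0.4)
  expect_equal(ellipse_overlap(e1, e1),
               nrow(mtphen:::raster_ellipse(20, 20, 8, 5, 0.4)))
  e_far <- c(cx = 50, cy = 20, a = 8, b = 5, theta = 0.4)
  expect_equal(ellipse_overlap(e1, e_far), 0)
  # Monte-Carlo point-sampling oracle on random pairs
  set.seed(10)
  inside <- function(e, p) {
    dx <- p[, 1] - e["cx"]; dy <- p[, 2] - e["cy"]
    u <- (dx * cos(e["theta"]) + dy * sin(e["theta"])) / e["a"]
    v <- (-dx * sin(e["theta"]) + dy * cos(e["theta"])) / e["b"]
    u^2 + v^2 <= 1
  }
  pts <- cbind(runif(2e5, 0, 40), runif(2e5, 0, 40))
  checked <- 0
  for (i in 1:40) {
    ea <- c(cx = runif(1, 12, 28), cy = runif(1, 12, 28),
            a = runif(1, 4, 9), b = runif(1, 3, 6),
            theta = runif(1, -pi / 2, pi / 2))
    eb <- c(cx = runif(1, 12, 28), cy = runif(1, 12, 28),
            a = runif(1, 4, 9), b = runif(1, 3, 6),
            theta = runif(1, -pi / 2, pi / 2))
    mc <- mean(inside(ea, pts) & inside(eb, pts)) * 1600
    if (mc < 25) next    # relative tolerance needs a non-trivial overlap
    checked <- checked + 1
    expect_lt(abs(ellipse_overlap(ea, eb) - mc) / mc, 0.05)
  }
  expect_gte(checked, 15)
})

test_that("chains link by overlap, cap at KZ and partition the sections", {
  ch <- ellipsoid_chain(3, 3, 3.4, 7.2, 0.5, 1, n_slices = 20)
  slices <- lapply(1:20, function(z) {
    s <- Filter(function(x) x$slice == z, ch$sections)
    s
  })
  nuc <- link_objects(slices, kz = 10)
  expect_length(nuc, 1)
  expect_equal(nuc[[1]]$length, length(ch$sections))
  expect_equal(diff(nuc[[1]]$slices), rep(1, nuc[[1]]$length - 1))
  # KZ cap splits the same chain
  nuc4 <- link_objects(slices, kz = 4)
  expect_length(nuc4, 2)
  expect_equal(sort(vapply(nuc4, function(n) n$length, numeric(1))),
               c(length(ch$sections) - 4, 4))
  # laterally separated nuclei never share sections
  ch2 <- ellipsoid_chain(3, 3, 3.4, 7.2, 0.5, 1, cx_px = 160, cy_px = 160,
                         n_slices = 20)
  slices2 <- lapply(1:20, function(z)
    Filter(function(x) x$slice == z, c(ch$sections, ch2$sections)))
  nucs <- link_objects(slices2, kz = 10)
  expect_length(nucs, 2)
  n_secs <- sum(vapply(nucs, function(n) n$length, numeric(1)))
  expect_equal(n_secs, length(ch$sections) + length(ch2$sections))
  expect_length(link_objects(list(), 10), 0)
})

test_that("ellipsoid fitting recovers axes and volume", {
  one <- structure(list(sections = list(list(slice = 1, area = 100,
                                             ellipse = c(cx = 0, cy = 0,
                                                         a = 1, b = 1,
                                                         theta = 0))),
                        slices = 1, length = 1), class = "nucleus3d")
  expect_equal(fit_ellipsoid(one, 1, 1)[["c"]], 0.5)
  expect_equal(4 / 3 * pi * 3 * 4 * 5, 251.3274, tolerance = 1e-6)
  ch <- ellipsoid_chain(3, 4, 5, 7.13, 0.5, 0.5)
  e <- fit_ellipsoid(ch, 0.5, 0.5)
  expect_lt(abs(e[["volume"]] - 251.3274) / 251.3274, 0.10)
  expect_error(fit_ellipsoid(ch), "calibration")
})

test_that("KZ lookup reproduces the condition table", {
  expect_equal(kz_lookup("cmec"), 46)
  expect_equal(kz_lookup("d7_without_fibroblasts"), 18)
  expect_equal(kz_lookup("d21_without_fibroblasts"), 18)
  expect_equal(kz_lookup("d7_with_fibroblasts"), 10)
  expect_equal(kz_lookup("d21_with_fibroblasts"), 10)
  expect_equal(kz_lookup("anything_else"), 36)
  expect_error(kz_lookup("anything_else", allow_default = FALSE), "unknown")
})

test_that("full-stack reconstruction recovers counts and positions", {
  fx <- mt_fixture()
  truth <- fx$g$truth
  expect_lt(abs(length(fx$nuc) - nrow(truth)) / nrow(truth), 0.05)
  m <- match_chains(fx$tab, truth)
  inpl <- sqrt((fx$tab$cx_um - truth$cx_um[m$truth])^2 +
               (fx$tab$cy_um - truth$cy_um[m$truth])^2) /
    fx$g$stack$pixel_size_um
  expect_lt(mean(inpl[m$matched]), 2)
  # partition: every 2D section belongs to exactly one chain
  n_secs <- sum(vapply(fx$nuc, function(n) n$length, numeric(1)))
  expect_equal(n_secs, sum(lengths(fx$segs)))
  # chain contiguity and the KZ cap
  for (n in fx$nuc) {
    expect_true(n$length <= 36)
    if (n$length > 1) expect_equal(diff(n$slices), rep(1, n$length - 1))
  }
})
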