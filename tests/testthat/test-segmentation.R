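test_that("lighting homogenization is opening subtraction", {
  expect_equal(homogenize_lighting(matrix(7, 40, 40), 5),
               matrix(0, 40, 40))
  # definitional identity
  set.seed(1)
  img <- matrix(runif(60 * 60), 60, 60)
  op <- mtphen:::scaled_morph(img, EBImage::opening,
                              mtphen:::disk_brush(25L))
  expect_equal(homogenize_lighting(img, 5), pmax(img - op, 0))
  # bright disk on a ramp: ramp removed, disk preserved
  ramp <- matrix(seq(0, 0.5, length.out = 100), 100, 100)
  disk <- disc_image(c(100, 100), list(c(50, 50)), 5, value = 1)
  h <- homogenize_lighting(ramp + disk, 5)
  expect_lt(max(h[disk == 0]), 0.2)                # background suppressed
  expect_gt(h[50, 50], 0.95)                       # disk peak preserved
  expect_error(homogenize_lighting(array(0, c(3, 3, 3)), 5), "2D")
})

test_that("local background subtraction zeroes at or below local median", {
  expect_equal(subtract_local_background(matrix(3, 50, 50), 5),
               matrix(0, 50, 50))
  # invariance to adding a constant
  set.seed(2)
  img <- matrix(runif(80 * 80), 80, 80)
  expect_equal(subtract_local_background(img, 5),
               subtract_local_background(img + 10, 5), tolerance = 1e-6)
  # window larger than image is clipped with a warning
  expect_warning(subtract_local_background(matrix(runif(100), 10, 10), 5),
                 "clipped")
  # sparse bright spots on a flat floor: background zeroed
  img2 <- matrix(0.1, 120, 120)
  img2[disc_image(c(120, 120), list(c(30, 30), c(80, 90)), 6) > 0] <- 1
  bs <- subtract_local_background(img2, 5)
  bg_mask <- img2 == 0.1
  expect_gte(mean(bs[bg_mask] == 0), 0.95)
})

test_that("enhancement removes impulses and keeps solid objects", {
  p <- seg_params(5)
  imp <- matrix(0, 64, 64); imp[32, 32] <- 1
  e <- enhance(imp, p)
  expect_lt(max(e), 0.1)     # isolated impulse killed by the median stage
  disk <- disc_image(c(100, 100), list(c(50, 50)), 15)
  ed <- enhance(disk, p)
  expect_gt(ed[50, 50], 0.9)
  # boundary dilated by at most KR (plus the Gaussian skirt)
  outside <- disc_image(c(100, 100), list(c(50, 50)), 15 + 9) == 0
  expect_lt(max(ed[outside]), 0.05)
  # stage order is fixed: max-filter-first differs on the impulse fixture
  perm <- mtphen:::scaled_morph(imp, EBImage::dilate, mtphen:::disk_brush(5L))
  perm <- mtphen:::scaled_median(EBImage::gblur(perm, 2.5), 5L)
  expect_false(isTRUE(all.equal(e, perm)))
})

test_that("seeds are EDT maxima with minimum separation", {
  p <- seg_params(5)
  img <- disc_image(c(80, 120), list(c(40, 35), c(40, 78)), 20)
  seeds <- generate_seeds(img, p)
  expect_equal(nrow(seeds), 2)
  d1 <- sqrt((seeds[, "row"] - 40)^2 + (seeds[, "col"] - 35)^2)
  d2 <- sqrt((seeds[, "row"] - 40)^2 + (seeds[, "col"] - 78)^2)
  expect_lt(min(d1), 2); expect_lt(min(d2), 2)
  expect_equal(nrow(generate_seeds(matrix(0, 40, 40), p)), 0)
  one <- disc_image(c(64, 64), list(c(32, 32)), 12)
  s1 <- generate_seeds(one, p)
  expect_equal(nrow(s1), 1)
  expect_lt(sqrt((s1[1, "row"] - 32)^2 + (s1[1, "col"] - 32)^2), 1.5)
})

test_that("flood fill partitions foreground and filters by size", {
  p <- seg_params(5)
  # two touching equal discs with two seeds split into equal halves
  img <- disc_image(c(80, 120), list(c(40, 45), c(40, 75)), 16)
  seeds <- generate_seeds(img, p)
  objs <- segment_slice(img, seeds, p)
  expect_length(objs, 2)
  areas <- vapply(objs, function(o) o$area, numeric(1))
  expect_lt(abs(diff(areas)) / mean(areas), 0.05)
  # pixel conservation: disjoint and within foreground
  allpx <- do.call(rbind, lapply(objs, function(o) o$pixels))
  expect_equal(nrow(allpx), nrow(unique(allpx)))
  expect_true(all(img[allpx] > 0))
  # sub-KR^2 objects are dropped
  expect_true(all(areas >= 25))
  small <- disc_image(c(40, 40), list(c(20, 20)), 2.6)  # ~21 px < 25
  expect_lt(sum(small), 25)
  objs2 <- segment_slice(small, generate_seeds(small, p), p)
  expect_length(objs2, 0)
  # no seeds but non-empty foreground: one object with a warning
  blob <- disc_image(c(60, 60), list(c(30, 30)), 10)
  expect_warning(
    objs3 <- segment_slice(blob, cbind(row = integer(0), col = integer(0),
                                       edt = numeric(0)), p),
    "unseeded")
  expect_length(objs3, 1)
})

test_that("oversize objects split into floor(area / threshold) parts", {
  p24 <- seg_params(5, split_threshold = NULL)
  # two overlapping discs form one connected object; a single seed keeps
  # them merged until the oversize split re-divides them
  img <- disc_image(c(90, 150), list(c(45, 50), c(45, 88)), 22)
  seeds <- generate_seeds(img, p24)
  area2 <- sum(img > 0)
  thr <- floor(area2 / 2.4)   # object area = 2.4x threshold -> n = 2
  p <- seg_params(5, split_threshold = thr)
  objs <- segment_slice(img, seeds[1, , drop = FALSE], p)
  expect_length(objs, 2)
  # below 2x threshold nothing splits
  p_hi <- seg_params(5, split_threshold = area2)
  expect_length(segment_slice(img, seeds[1, , drop = FALSE], p_hi), 1)
})

test_that("segmentation is translation-equivariant and repeatable", {
  set.seed(7)
  img <- matrix(0, 100, 100)
  img[disc_image(c(100, 100), list(c(40, 40), c(70, 65)), 9) > 0] <- 1
  img <- img + matrix(rnorm(1e4, 0, 0.05), 100, 100)
  p <- seg_params(5)
  run <- function(x) {
    objs <- segment_slice(enhance(subtract_local_background(
      homogenize_lighting(x, 5), 5), p), generate_seeds(enhance(
        subtract_local_background(homogenize_lighting(x, 5), 5), p), p), p)
    t(vapply(objs, function(o) o$ellipse[c("cx", "cy")], numeric(2)))
  }
  c0 <- run(img)
  shifted <- matrix(0, 100, 100)
  shifted[11:100, 6:100] <- img[1:90, 1:95]
  c1 <- run(shifted)
  expect_equal(nrow(c0), nrow(c1))
  ord0 <- order(c0[, 1]); ord1 <- order(c1[, 1])
  expect_equal(c1[ord1, 1] - c0[ord0, 1], rep(5, nrow(c0)), tolerance = 0.2)
  expect_equal(c1[ord1, 2] - c0[ord0, 2], rep(10, nrow(c0)), tolerance = 0.2)
  # no hidden randomness
  expect_identical(run(img), c0)
})

test_that("empty and bad inputs are handled", {
  st <- image_stack(array(0, c(32, 32, 2, 1)), "dapi", 0.5, 1)
  expect_length(segment_stack(st, "dapi", seg_params(3))[[1]], 0)
  expect_error(segment_stack(st, "nope"), "channel")
  expect_error(seg_params(5, split_threshold = 20), "exceed")
})
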