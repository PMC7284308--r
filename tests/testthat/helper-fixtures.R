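# Shared fixtures.  Heavy objects are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Full-size synthetic microtissue stack (the package's default study
# conditions) segmented and reconstructed once; reused by the
# recovery-oriented tests.
mt_fixture <- function() {
  if (is.null(.fixtures$mt)) {
    g <- generate_stack(stack_recipe(seed = 11L, ki67_streaks = 30L))
    segs <- segment_stack(g$stack, "dapi", seg_params(5))
    nuc <- link_objects(segs, kz = 36)
    tab <- nuclei_table(nuc, g$stack$pixel_size_um, g$stack$z_step_um)
    .fixtures$mt <- list(g = g, segs = segs, nuc = nuc, tab = tab)
  }
  .fixtures$mt
}

# Match reconstructed chains to ground-truth nuclei by nearest centroid,
# keeping only matches within cap_um.
match_chains <- function(tab, truth, cap_um = 5) {
  M <- sqrt(outer(truth$cx_um, tab$cx_um, "-")^2 +
            outer(truth$cy_um, tab$cy_um, "-")^2 +
            outer(truth$cz_um, tab$cz_um, "-")^2)
  best <- apply(M, 2, which.min)
  dmin <- apply(M, 2, min)
  data.frame(chain = seq_len(nrow(tab)), truth = best, dist_um = dmin,
             matched = dmin <= cap_um)
}

# Binary image with solid discs at the given (row, col) centers.
disc_image <- function(dim_yx, centers, radius, value = 1) {
  img <- matrix(0, dim_yx[1], dim_yx[2])
  for (ctr in centers) {
    px <- mtphen:::raster_ellipse(ctr[2], ctr[1], radius, radius, 0, dim_yx)
    img[px] <- value
  }
  img
}

# Ideal (noise-free, un-dilated) section chain of a true ellipsoid,
# rasterized directly from geometry; bypasses segmentation.
ellipsoid_chain <- function(a_um, b_um, c_um, z0_um, pixel_size_um, z_step_um,
                            cx_px = 100, cy_px = 100, theta = 0.3,
                            n_slices = 60) {
  secs <- list()
  for (zi in seq_len(n_slices)) {
    z <- (zi - 0.5) * z_step_um
    t <- (z - z0_um) / c_um
    if (abs(t) >= 1) next
    s <- sqrt(1 - t^2)
    px <- mtphen:::raster_ellipse(cx_px, cy_px, s * a_um / pixel_size_um,
                                  s * b_um / pixel_size_um, theta)
    if (nrow(px) < 5) next
    secs[[length(secs) + 1L]] <- list(slice = zi, pixels = px,
                                      area = nrow(px),
                                      ellipse = fit_ellipse(px))
  }
  structure(list(sections = secs,
                 slices = vapply(secs, function(s) s$slice, numeric(1)),
                 length = length(secs)),
            class = "nucleus3d")
}

# Analytic raised-cosine contraction pulse train (speed profile).
pulse_profile <- function(n_beats = 6, peak = 30, width_s = 0.4,
                          period_s = 1, fps = 100) {
  tt <- seq(0, n_beats * period_s, by = 1 / fps)
  ph <- tt %% period_s
  sp <- ifelse(ph < width_s, peak * 0.5 * (1 - cos(2 * pi * ph / width_s)), 0)
  contraction_profile(tt, sp)
}
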