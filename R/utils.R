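# Shared internal helpers: seeded RNG scoping, brushes, rasterization.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit, so generators never leak global state.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Disk structuring element of the given pixel radius (odd-sized brush).
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Digital line structuring element at `angle_deg` from the +x (column)
# axis with y pointing up; 8-connected, odd extent of at most `length` px.
line_brush <- function(length, angle_deg) {
  half <- (as.integer(length) - 1L) %/% 2L
  t <- -half:half
  dx <- round(t * cos(angle_deg * pi / 180))
  dy <- round(t * sin(angle_deg * pi / 180))
  n <- 2L * half + 1L
  b <- matrix(0L, n, n)
  # y up -> row = center - dy
  b[cbind(half + 1L - dy, half + 1L + dx)] <- 1L
  b
}

# Integer pixel set (row, col) of an ellipse on the pixel grid.
# Coordinates: x = column, y = row, orientation measured from +x toward +y.
raster_ellipse <- function(cx, cy, a, b, theta, dim_yx = NULL) {
  r <- max(a, b)
  x0 <- floor(cx - r); x1 <- ceiling(cx + r)
  y0 <- floor(cy - r); y1 <- ceiling(cy + r)
  if (!is.null(dim_yx)) {
    y0 <- max(y0, 1L); x0 <- max(x0, 1L)
    y1 <- min(y1, dim_yx[1]); x1 <- min(x1, dim_yx[2])
  }
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(0), col = integer(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- which(u * u + v * v <= 1, arr.ind = TRUE)
  cbind(row = ys[keep[, 1]], col = xs[keep[, 2]])
}

# Bilinear sampling of `img` at (row - dy, col - dx); replicate borders.
bilinear_warp <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc) - dy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  rr <- pmin(pmax(rr, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(rr), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- rr - r0; fc <- cc - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i10 <- cbind(as.vector(r0) + 1L, as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c0) + 1L)
  i11 <- cbind(as.vector(r0) + 1L, as.vector(c0) + 1L)
  out <- (1 - as.vector(fr)) * (1 - as.vector(fc)) * img[i00] +
    as.vector(fr) * (1 - as.vector(fc)) * img[i10] +
    (1 - as.vector(fr)) * as.vector(fc) * img[i01] +
    as.vector(fr) * as.vector(fc) * img[i11]
  matrix(out, nr, nc)
}

# Shift a matrix by (dr, dc) with edge replication.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
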