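#' Per-nucleus median distance to the k nearest neighbors
#'
#' For each centroid, Euclidean distances (in calibrated micrometres, so
#' axial anisotropy must already be applied) to its k nearest neighbors
#' are collected and their median is returned as the nucleus's most
#' probable inter-nuclear distance.
#'
#' @param centroids n x d numeric matrix of centroid coordinates (um).
#' @param k number of neighbors (default 12; capped at n - 1).
#' @return Numeric vector of per-nucleus median neighbor distances (um).
#' @export
knn_median_distance <- function(centroids, k = 12L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stopf("need at least 2 centroids (got %d)", n)
  k <- min(as.integer(k), n - 1L)
  out <- numeric(n)
  tc <- t(centroids)
  for (i in seq_len(n)) {
    d2 <- colSums((tc - centroids[i, ])^2)
    d <- sqrt(sort.int(d2[-i], partial = k)[seq_len(k)])
    out[i] <- median(d)
  }
  if (any(out == 0))
    warnf("duplicate centroids: %d nuclei have a zero median neighbor distance",
          sum(out == 0))
  out
}

#' Microtissue-level average inter-nuclear distance
#'
#' Arithmetic mean and SD (n - 1 denominator) of the per-nucleus median
#' neighbor distances.
#'
#' @param medians numeric vector from \code{\link{knn_median_distance}}.
#' @return Named vector \code{c(mean, sd, n)}; sd is NA for a single value.
#' @export
mt_average_distance <- function(medians) {
  if (length(medians) == 0) stopf("no medians supplied")
  c(mean = mean(medians),
    sd = if (length(medians) > 1) sd(medians) else NA_real_,
    n = length(medians))
}
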