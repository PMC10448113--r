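#' Density-based clustering of 3D points (DBSCAN)
#'
#' Canonical DBSCAN with the Euclidean metric: a core point has at least
#' `min_points` neighbours (itself included) within radius `eps`; clusters
#' grow by density-reachability from core points; non-core points within
#' `eps` of a core point are border points and join the first core cluster
#' that reaches them (scan order fixed by row index, for determinism);
#' everything else is noise. Defaults (`eps = 15` um, `min_points = 5`)
#' implement the tuft-detection rule of at least five end/branch points
#' within a 15 um radius.
#'
#' @param points n x 3 coordinate matrix.
#' @param eps Neighbourhood radius, um.
#' @param min_points Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster ids (0 = noise).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(18, 0, 2), 6), matrix(rnorm(18, 100, 2), 6))
#' table(dbscan_points(pts))
dbscan_points <- function(points, eps = 15, min_points = 5) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n) return(integer(0))
  d <- as.matrix(dist(points))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbours, length, 0L) >= min_points
  labels <- rep(NA_integer_, n)  # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!core[i]) { labels[i] <- 0L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbours[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[j]) && labels[j] == 0L) labels[j] <- cl  # border
      if (!is.na(labels[j])) next
      labels[j] <- cl
      if (core[j]) {
        # noise points stay eligible: they may still be adopted as border
        done <- which(!is.na(labels) & labels > 0L)
        queue <- c(queue, setdiff(neighbours[[j]], done))
      }
    }
  }
  labels
}
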