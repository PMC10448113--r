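#' Normalize ROI positions to the glomerular cluster axes
#'
#' Affine map of micrometre coordinates to `[0, 1]^3` along the
#' medio-lateral (x), caudo-rostral (y) and ventro-dorsal (z) axes, using
#' manually defined boundary coordinates of the glomerular cluster /
#' mitral cell layer.
#'
#' @param centroids n x 3 matrix (um), optionally with rownames as ROI
#'   ids.
#' @param boundaries List or matrix with per-axis `(min, max)` in um.
#' @param tolerance Allowed overshoot beyond the boundaries, as a fraction
#'   of the axis span, before a point is rejected.
#' @return n x 3 matrix of normalized positions (clipped into `[0, 1]`
#'   within tolerance).
#' @export
#' @examples
#' b <- rbind(x = c(0, 100), y = c(0, 200), z = c(0, 50))
#' normalize_positions(rbind(c(50, 100, 25)), b)  # 0.5 0.5 0.5
normalize_positions <- function(centroids, boundaries, tolerance = 0.02) {
  centroids <- as.matrix(centroids)
  b <- as.matrix(boundaries)
  if (ncol(centroids) != 3 || nrow(b) != 3) {
    stop("need 3D centroids and 3 axis boundaries")
  }
  if (any(b[, 2] <= b[, 1])) stop("boundary max must exceed min per axis")
  out <- sweep(sweep(centroids, 2, b[, 1]), 2, b[, 2] - b[, 1], `/`)
  bad <- which(out < -tolerance | out > 1 + tolerance, arr.ind = TRUE)
  if (nrow(bad)) {
    ids <- rownames(centroids) %||% as.character(seq_len(nrow(centroids)))
    stop("position(s) outside the declared boundaries: ",
         paste(unique(ids[bad[, 1]]), collapse = ", "))
  }
  out <- pmin(pmax(out, 0), 1)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Spatial territories of glomerular species
#'
#' One territory per observed tuning label: the centroid (per-axis mean of
#' member positions) and the per-axis SD, which defines the 1-SD ellipsoid
#' used to visualize the territory. Single-member species have zero SD.
#'
#' @param positions n x 3 matrix of normalized positions.
#' @param classifications List of [classify_tuning()] results, same order.
#' @param tuning `"dominant"` or `"default"` labels.
#' @param drop_untuned Exclude the empty label.
#' @return data.frame: species, n, cx, cy, cz, sx, sy, sz.
#' @export
species_territories <- function(positions, classifications,
                                tuning = c("dominant", "default"),
                                drop_untuned = TRUE) {
  tuning <- match.arg(tuning)
  if (nrow(positions) != length(classifications)) {
    stop("every ROI needs both a position and a classification")
  }
  labs <- vapply(classifications, `[[`, "", paste0(tuning, "_label"))
  keep <- if (drop_untuned) nzchar(labs) else rep(TRUE, length(labs))
  labs <- labs[keep]; pos <- positions[keep, , drop = FALSE]
  rows <- lapply(split(seq_along(labs), labs), function(idx) {
    p <- pos[idx, , drop = FALSE]
    data.frame(species = labs[idx[1]], n = length(idx),
               cx = mean(p[, 1]), cy = mean(p[, 2]), cz = mean(p[, 3]),
               sx = if (length(idx) > 1) sd(p[, 1]) else 0,
               sy = if (length(idx) > 1) sd(p[, 2]) else 0,
               sz = if (length(idx) > 1) sd(p[, 3]) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# the three structural-similarity groups of the panel
SIMILAR_GROUPS <- list(HFW = c("H", "F", "W"), KR = c("K", "R"),
                       MLI = c("M", "L", "I"))

# TRUE when every stimulus of every label falls inside one similarity group
labels_similar <- function(a, b, groups = SIMILAR_GROUPS) {
  letters_ab <- unique(unlist(strsplit(c(a, b), "")))
  any(vapply(groups, function(g) all(letters_ab %in% g), TRUE))
}

#' Inter-centroid distances between glomerular species
#'
#' Euclidean distances between all species-pair centroids, partitioned by
#' whether both labels are combinations of one structural-similarity group
#' (H/F/W, K/R, or M/L/I: "similar" pairs) or not ("dissimilar"), compared
#' by Mann-Whitney U. Under chemotopy similar pairs lie closer.
#'
#' @param territories A [species_territories()] table (>= 2 rows).
#' @return List with `pairs` (data.frame: species_a, species_b, distance,
#'   similar) and `test` (NULL when either partition is empty).
#' @export
intercentroid_distances <- function(territories) {
  if (nrow(territories) < 2) stop("need at least two species territories")
  cent <- as.matrix(territories[, c("cx", "cy", "cz")])
  rows <- lapply(utils::combn(nrow(territories), 2, simplify = FALSE),
                 function(ij) {
    data.frame(
      species_a = territories$species[ij[1]],
      species_b = territories$species[ij[2]],
      distance = sqrt(sum((cent[ij[1], ] - cent[ij[2], ])^2)),
      similar = labels_similar(territories$species[ij[1]],
                               territories$species[ij[2]]))
  })
  pairs <- do.call(rbind, rows)
  test <- if (any(pairs$similar) && any(!pairs$similar)) {
    two_group(pairs$distance[pairs$similar],
              pairs$distance[!pairs$similar])
  }
  list(pairs = pairs, test = test)
}

#' Centroid deviation of compound-profile species
#'
#' For every species with a 2- or 3-stimulus label (compound profile, e.g.
#' `"HFW"`), the deviation is the Euclidean distance between that species'
#' centroid and the unweighted mean of the centroids of the constituent
#' single-stimulus species (e.g. H, F and W). Small deviations mean the
#' compound species sits centered between its constituents. Deviations of
#' structurally-similar compounds are compared with all remaining
#' compounds by Mann-Whitney U.
#'
#' @param territories A [species_territories()] table.
#' @return List with `deviations` (data.frame: species, deviation,
#'   similar), `test` (NULL when a cohort is empty) and `log` (compounds
#'   skipped for missing constituents).
#' @export
compound_centroid_deviation <- function(territories) {
  cent <- as.matrix(territories[, c("cx", "cy", "cz")])
  rownames(cent) <- territories$species
  labels <- territories$species
  compounds <- labels[nchar(labels) %in% 2:3]
  log <- character(0)
  rows <- list()
  for (cp in compounds) {
    singles <- strsplit(cp, "")[[1]]
    if (!all(singles %in% labels)) {
      log <- c(log, paste0("compound ", cp, " skipped: missing single species ",
                           paste(setdiff(singles, labels), collapse = ",")))
      next
    }
    target <- colMeans(cent[singles, , drop = FALSE])
    rows[[cp]] <- data.frame(
      species = cp,
      deviation = sqrt(sum((cent[cp, ] - target)^2)),
      similar = labels_similar(cp, cp))
  }
  deviations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), deviation = numeric(0),
               similar = logical(0))
  rownames(deviations) <- NULL
  test <- if (any(deviations$similar) && any(!deviations$similar)) {
    two_group(deviations$deviation[deviations$similar],
              deviations$deviation[!deviations$similar])
  }
  list(deviations = deviations, test = test, log = log)
}

#' Interglomerular distance versus time-trace correlation
#'
#' For all unordered ROI pairs, the Euclidean distance between positions
#' is plotted against the Pearson correlation of the raw fluorescence
#' traces, and the relation is assessed by OLS (H0: slope = 0). Degenerate
#' (constant) traces are excluded pairwise and flagged.
#'
#' @param positions n x 3 position matrix (normalized or um space).
#' @param traces n-column matrix of fluorescence traces.
#' @return List with `pairs` (data.frame: distance, correlation), `fit`
#'   (the [ols_slope_test()]) and `flagged` (excluded trace columns).
#' @export
distance_vs_trace_correlation <- function(positions, traces) {
  n <- nrow(positions)
  if (n < 3) stop("need at least three ROIs")
  if (ncol(traces) != n) stop("one trace column per ROI required")
  sds <- apply(traces, 2, sd)
  flagged <- which(sds == 0)
  rows <- lapply(utils::combn(n, 2, simplify = FALSE), function(ij) {
    if (ij[1] %in% flagged || ij[2] %in% flagged) return(NULL)
    data.frame(
      distance = sqrt(sum((positions[ij[1], ] - positions[ij[2], ])^2)),
      correlation = cor(traces[, ij[1]], traces[, ij[2]]))
  })
  pairs <- do.call(rbind, rows)
  fit <- ols_slope_test(pairs$distance, pairs$correlation)
  list(pairs = pairs, fit = fit, flagged = flagged)
}

#' Pairwise glomerular distance by shared dominant tuning
#'
#' Bins all pairwise ROI distances by the overlap of the two dominant
#' stimulus sets: no common stimulus, at least one common, or all stimuli
#' in common (identical sets), then runs Kruskal-Wallis across the
#' non-empty categories and Dunn post-hoc tests. Untuned ROI pairs (both
#' sets empty) count as "all common" only if both are empty-by-empty and
#' are excluded by default.
#'
#' @param positions n x 3 matrix.
#' @param classifications List of [classify_tuning()] results.
#' @return List with `distances` (named list per category), `omnibus`,
#'   `posthoc` and `log` (empty categories).
#' @export
shared_tuning_distance <- function(positions, classifications) {
  n <- nrow(positions)
  if (n != length(classifications)) stop("positions/classifications mismatch")
  sets <- lapply(classifications, `[[`, "dominant_set")
  cats <- c("no_common", "some_common", "all_common")
  out <- setNames(vector("list", 3), cats)
  for (ij in utils::combn(n, 2, simplify = FALSE)) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    if (!length(a) || !length(b)) next  # untuned ROIs carry no category
    shared <- length(intersect(a, b))
    cat_k <- if (shared == 0) "no_common" else
      if (shared == length(a) && shared == length(b)) "all_common" else
        "some_common"
    d <- sqrt(sum((positions[ij[1], ] - positions[ij[2], ])^2))
    out[[cat_k]] <- c(out[[cat_k]], d)
  }
  empty <- cats[vapply(out, is.null, TRUE)]
  log <- if (length(empty)) paste("empty category:", empty) else character(0)
  nonempty <- out[!vapply(out, is.null, TRUE)]
  omnibus <- if (length(nonempty) >= 2) omnibus_kw(nonempty)
  posthoc <- if (length(nonempty) >= 2) posthoc_dunn(nonempty)
  list(distances = out, omnibus = omnibus, posthoc = posthoc, log = log)
}
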