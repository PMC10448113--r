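#' End points and branch points of a neuron tree
#'
#' An end point is a node without children; a branch point has at least
#' two children. The soma (root) is excluded from both sets even when it
#' carries multiple stems.
#'
#' @param tree A `neuron_tree`.
#' @return List with `ids`, `coords` (matrix), `kind`
#'   (`"end"`/`"branch"`) of the critical points.
#' @export
critical_points <- function(tree) {
  nd <- tree$nodes
  n_children <- table(factor(nd$parent, levels = nd$id))
  kind <- rep(NA_character_, nrow(nd))
  kind[n_children[as.character(nd$id)] == 0] <- "end"
  kind[n_children[as.character(nd$id)] >= 2] <- "branch"
  keep <- !is.na(kind) & nd$id != tree$root
  list(ids = nd$id[keep],
       coords = as.matrix(nd[keep, c("x", "y", "z")]),
       kind = kind[keep])
}

#' Detect dendritic tufts by density clustering
#'
#' Applies DBSCAN (`eps = 15` um, `min_points = 5`) to the end and branch
#' points of a tree: clusters of at least five critical points within a
#' 15 um radius are dendritic tufts; end points outside any cluster are
#' blunt neurite endings.
#'
#' @param tree A `neuron_tree`.
#' @param eps Clustering radius, um.
#' @param min_points Minimum critical points per tuft.
#' @return List of class `tuft_detection`: `clusters` (list of
#'   `tuft_cluster`s, each with `member_ids`, `coords`, `center`,
#'   `volume`, `degenerate`), `blunt_endings` (ids), `labels`,
#'   `critical` (the [critical_points()] result).
#' @export
detect_tufts <- function(tree, eps = 15, min_points = 5) {
  cp <- critical_points(tree)
  labels <- dbscan_points(cp$coords, eps = eps, min_points = min_points)
  clusters <- lapply(sort(unique(labels[labels > 0])), function(cl) {
    idx <- which(labels == cl)
    hull <- convex_hull_volume(cp$coords[idx, , drop = FALSE])
    structure(list(member_ids = cp$ids[idx],
                   coords = cp$coords[idx, , drop = FALSE],
                   center = colMeans(cp$coords[idx, , drop = FALSE]),
                   volume = hull$volume,
                   degenerate = hull$degenerate),
              class = "tuft_cluster")
  })
  blunt <- cp$ids[labels == 0 & cp$kind == "end"]
  structure(list(clusters = clusters, blunt_endings = blunt,
                 labels = labels, critical = cp),
            class = "tuft_detection")
}

#' Convex-hull volume of one tuft cluster
#'
#' @param cluster A `tuft_cluster`.
#' @return List with `volume` (um^3) and `degenerate` flag; coplanar or
#'   collinear member points give volume 0 with the flag set.
#' @export
tuft_volume <- function(cluster) {
  convex_hull_volume(cluster$coords)
}

# path distance from the root to every node (um along the tree)
root_path_distances <- function(tree) {
  nd <- tree$nodes
  idx <- match(nd$parent, nd$id)
  seg <- rep(0, nrow(nd))
  has_par <- !is.na(idx)
  seg[has_par] <- sqrt((nd$x[has_par] - nd$x[idx[has_par]])^2 +
                       (nd$y[has_par] - nd$y[idx[has_par]])^2 +
                       (nd$z[has_par] - nd$z[idx[has_par]])^2)
  # accumulate by walking from each node to the root (trees are small)
  dist <- rep(NA_real_, nrow(nd))
  dist[is.na(idx)] <- 0
  order_by_depth <- function() {
    depth <- rep(0L, nrow(nd)); j <- idx
    repeat {
      deeper <- !is.na(j)
      if (!any(deeper)) break
      depth[deeper] <- depth[deeper] + 1L
      j[deeper] <- idx[j[deeper]]
    }
    order(depth)
  }
  for (i in order_by_depth()) {
    if (is.na(dist[i])) dist[i] <- dist[idx[i]] + seg[i]
  }
  setNames(dist, nd$id)
}

#' Soma-tuft path distances and inter-tuft distances
#'
#' The distance between soma and a tuft is measured along the dendritic
#' branches, to the cluster member with the smallest path distance;
#' distances between tuft clusters are Euclidean distances of their
#' center points.
#'
#' @param tree A `neuron_tree`.
#' @param detection A [detect_tufts()] result for this tree.
#' @return List with `path_distance` (per cluster, um) and
#'   `intercluster` (symmetric Euclidean distance matrix of centers).
#' @export
tuft_distances <- function(tree, detection) {
  rp <- root_path_distances(tree)
  path_distance <- vapply(detection$clusters, function(cl) {
    min(rp[as.character(cl$member_ids)])
  }, numeric(1))
  k <- length(detection$clusters)
  centers <- t(vapply(detection$clusters, `[[`, numeric(3), "center"))
  intercluster <- if (k) as.matrix(dist(centers)) else
    matrix(0, 0, 0)
  list(path_distance = path_distance, intercluster = intercluster)
}

#' Nine-feature morphometric vector of an MTC
#'
#' Features: number of tufts; number of primary dendritic stems (root
#' children whose subtree contains at least one tuft member); mean tuft
#' volume; mean number of branch points per tuft; number of secondary
#' dendrites (children of primary stems); number of primary basal
#' neurites (root children without tufts in their subtree); number of
#' secondary basal neurites (their children); mean soma-to-tuft path
#' distance; mean inter-tuft Euclidean distance. Tuft-dependent means are
#' 0 for tuftless cells, with `no_tufts` flagged in the attribute.
#'
#' @param tree A `neuron_tree`.
#' @param eps,min_points Tuft detection parameters.
#' @return Named numeric vector of 9 features (attribute `no_tufts`).
#' @export
extract_features <- function(tree, eps = 15, min_points = 5) {
  det <- detect_tufts(tree, eps = eps, min_points = min_points)
  nd <- tree$nodes
  k <- length(det$clusters)

  # subtree membership per root child
  idx <- match(nd$parent, nd$id)
  root_child_of <- rep(NA_integer_, nrow(nd))
  for (i in seq_len(nrow(nd))) {
    j <- i
    while (!is.na(idx[j]) && nd$parent[j] != tree$root) j <- idx[j]
    if (!is.na(idx[j])) root_child_of[i] <- nd$id[j]
  }
  root_children <- nd$id[nd$parent == tree$root]
  tuft_ids <- unlist(lapply(det$clusters, `[[`, "member_ids"))
  stems <- root_children[vapply(root_children, function(ch) {
    any(tuft_ids %in% nd$id[!is.na(root_child_of) & root_child_of == ch])
  }, TRUE)]
  basals <- setdiff(root_children, stems)
  n_secondary_dendrites <- sum(nd$parent %in% stems)
  n_secondary_basal <- sum(nd$parent %in% basals)

  branch_per_tuft <- vapply(det$clusters, function(cl) {
    sum(det$critical$kind[det$critical$ids %in% cl$member_ids] == "branch")
  }, numeric(1))
  dists <- tuft_distances(tree, det)
  mean_intertuft <- if (k >= 2) {
    mean(dists$intercluster[upper.tri(dists$intercluster)])
  } else 0

  out <- c(
    n_tufts = k,
    n_primary_stems = length(stems),
    mean_tuft_volume = if (k) mean(vapply(det$clusters, `[[`, 0, "volume"))
                       else 0,
    mean_branch_per_tuft = if (k) mean(branch_per_tuft) else 0,
    n_secondary_dendrites = n_secondary_dendrites,
    n_primary_basal = length(basals),
    n_secondary_basal = n_secondary_basal,
    mean_soma_tuft_path = if (k) mean(dists$path_distance) else 0,
    mean_intertuft_dist = mean_intertuft)
  attr(out, "no_tufts") <- k == 0
  out
}

#' Standardized PCA over a cell population
#'
#' Principal component analysis of the per-cell morphometric vectors,
#' each feature standardized to zero mean and unit variance. Constant
#' features carry no information and are dropped with a log entry.
#'
#' @param features Matrix (cells x features) or list of
#'   [extract_features()] vectors; >= 3 cells.
#' @return List with `scores`, `loadings`, `explained` (variance ratios
#'   summing to 1), `dropped` (constant features).
#' @export
population_pca <- function(features) {
  m <- if (is.matrix(features)) features else do.call(rbind, features)
  if (nrow(m) < 3) stop("PCA needs at least 3 cells")
  const <- apply(m, 2, sd) == 0
  dropped <- colnames(m)[const]
  m <- m[, !const, drop = FALSE]
  if (!ncol(m)) stop("all features constant")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2), dropped = dropped)
}

#' Distribution of tuft counts across a population
#'
#' @param trees List of `neuron_tree`s, or an integer vector of tuft
#'   counts.
#' @param eps,min_points Tuft detection parameters.
#' @return Named numeric vector of fractions per tuft count (sums to 1).
#' @export
classify_tuft_count_distribution <- function(trees, eps = 15,
                                             min_points = 5) {
  counts <- if (is.numeric(trees)) trees else
    vapply(trees, function(tr) length(detect_tufts(tr, eps, min_points)$clusters),
           0L)
  if (!length(counts)) stop("need at least one cell")
  tab <- table(counts)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
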