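#' Construct a neuron tree
#'
#' A neuron reconstruction as a rooted tree: one node per sample point, the
#' soma as root, every other node pointing at exactly one parent. Structure
#' is validated on construction (single root, existing parents, no cycles).
#'
#' @param nodes data.frame with columns `id`, `parent` (-1 or NA for the
#'   root), `x`, `y`, `z` (um) and optionally `radius`, `type`.
#' @return Object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes) {
  need <- c("id", "parent", "x", "y", "z")
  if (!all(need %in% names(nodes))) {
    stop("nodes needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    stop("non-finite node coordinates")
  }
  nodes$parent[is.na(nodes$parent)] <- -1L
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) {
    stop("tree must have exactly one root (parent = -1), found ",
         length(roots))
  }
  dangling <- setdiff(nodes$parent, c(-1L, nodes$id))
  if (length(dangling)) {
    stop("dangling parent id(s): ", paste(dangling, collapse = ", "))
  }
  # cycle check: walk each node to the root
  idx <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0); j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("cycle detected at node ", nodes$id[i])
      seen <- c(seen, j); j <- idx[j]
      if (length(seen) > nrow(nodes)) stop("cycle detected")
    }
  }
  if (is.null(nodes$radius)) nodes$radius <- 1
  if (is.null(nodes$type)) nodes$type <- ifelse(nodes$parent == -1L, 1L, 3L)
  structure(list(nodes = nodes, root = nodes$id[roots]),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat("Neuron tree:", nrow(x$nodes), "nodes, root id", x$root, "\n")
  invisible(x)
}

#' Read / write SWC neuron reconstructions
#'
#' Standard SWC: one line per node with `id type x y z radius parent`,
#' `#` comments allowed; parent -1 marks the soma/root. Structural errors
#' (multiple roots, dangling parents, cycles) are rejected with messages.
#'
#' @param path File path.
#' @param tree A `neuron_tree`.
#' @return `read_swc`: a `neuron_tree`. `write_swc`: `path`, invisibly.
#' @export
read_swc <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  neuron_tree(tab[, c("id", "parent", "x", "y", "z", "radius", "type")])
}

#' @rdname read_swc
#' @export
write_swc <- function(tree, path) {
  n <- tree$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   n$id, n$type, n$x, n$y, n$z, n$radius, n$parent)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a mitral/tufted cell reconstruction with planted tufts
#'
#' Builds a rooted tree emulating an MTC: a soma, apical dendrite stems
#' leading to `n_tufts` terminal tufts, and a few basal neurites ending in
#' blunt (non-clustered) endings. Each planted tuft contributes at least
#' five end/branch points within `tuft_spread` um of its center, and tuft
#' centers are separated by more than twice the 15 um detection radius, so
#' density-based tuft detection recovers the planted count exactly.
#'
#' @param n_tufts Number of planted tufts (>= 0).
#' @param nodes_per_tuft End/branch points per tuft (>= 5 for a detectable
#'   tuft).
#' @param tuft_spread Radius of the tuft point cloud, um; must be < 15 so
#'   a planted tuft satisfies the detection rule, and small enough that
#'   separate tufts never chain together.
#' @param n_basal Number of basal neurites (unbranched, blunt-ended).
#' @param stem_length Soma-to-tuft dendrite length scale, um.
#' @param seed Integer seed; identical seeds give identical SWC output.
#' @return A `neuron_tree` whose `ground_truth` attribute records planted
#'   tuft centers and member node ids.
#' @export
#' @examples
#' tr <- simulate_neuron_tree(2, seed = 1)
#' attr(tr, "ground_truth")$n_tufts
simulate_neuron_tree <- function(n_tufts, nodes_per_tuft = 8,
                                 tuft_spread = 6, n_basal = 2,
                                 stem_length = 80, seed = NULL) {
  if (n_tufts < 0) stop("n_tufts must be >= 0")
  if (n_tufts > 0 && nodes_per_tuft < 5) {
    stop("a detectable tuft needs >= 5 end/branch points")
  }
  min_sep <- 2 * 15 + 2 * tuft_spread  # cluster centers can never merge
  if (tuft_spread >= 15) stop("tuft_spread must be < 15 um")
  local_rng(seed)

  nodes <- data.frame(id = 1L, parent = -1L, x = 0, y = 0, z = 0,
                      radius = 5, type = 1L)
  nid <- 1L
  add_node <- function(parent, p, type = 3L) {
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(id = nid, parent = parent,
                                      x = p[1], y = p[2], z = p[3],
                                      radius = 1, type = type))
    nid
  }

  # well-separated tuft centers: spherical directions spread around the soma
  centers <- matrix(0, nrow = max(n_tufts, 0), ncol = 3)
  if (n_tufts > 0) {
    for (k in seq_len(n_tufts)) {
      repeat {
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- dir * (stem_length + runif(1, 0, 20))
        if (k == 1 || all(sqrt(rowSums(sweep(centers[seq_len(k - 1), ,
              drop = FALSE], 2, cand)^2)) > min_sep)) break
      }
      centers[k, ] <- cand
    }
  }

  gt_members <- vector("list", max(n_tufts, 0))
  for (k in seq_len(n_tufts)) {
    ctr <- centers[k, ]
    # stem: soma -> midpoint -> tuft entry (entry is a branch point)
    mid <- add_node(1L, ctr * 0.5)
    entry <- add_node(mid, ctr)
    # entry branches straight into terminal twigs: every tuft node is then
    # an end or branch point, so the planted critical-point count is exact
    members <- entry
    for (j in seq_len(nodes_per_tuft - 1L)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p <- ctr + u * runif(1, 0.2, 1) * tuft_spread
      members <- c(members, add_node(entry, p))
    }
    gt_members[[k]] <- members
  }

  for (b in seq_len(n_basal)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    last <- 1L
    for (s in 1:3) {
      last <- add_node(last, dir * s * 15 + rnorm(3, 0, 1))
    }
  }

  tr <- neuron_tree(nodes)
  attr(tr, "ground_truth") <- list(
    n_tufts = n_tufts,
    centers = centers,
    members = gt_members)
  tr
}
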