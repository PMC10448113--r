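# Independent brute-force oracles used to validate the implementation.

# Average-linkage agglomeration computed directly from the definition:
# repeatedly merge the two clusters with the smallest mean pairwise
# distance. Returns the merge heights and the cophenetic distance matrix.
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL; best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# DBSCAN oracle from the density-reachability definition: core points are
# connected when within eps of each other; clusters are the connected
# components of the core graph; border points attach to any reachable
# component; everything else is noise. Returns a canonical partition
# signature independent of cluster numbering.
oracle_dbscan_partition <- function(points, eps = 15, min_points = 5) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  core <- which(colSums(d <= eps) >= min_points)
  comp <- rep(0L, n)
  cl <- 0L
  for (s in core) {
    if (comp[s]) next
    cl <- cl + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (comp[v]) next
      comp[v] <- cl
      stack <- c(stack, intersect(which(d[v, ] <= eps), core))
    }
  }
  # border points: non-core within eps of some core; ambiguous multi-
  # assignment resolved like the scan-order convention is irrelevant for
  # the partition *count*; for the signature we record reachable sets
  border <- setdiff(which(colSums(d <= eps) < min_points), core)
  border_reach <- lapply(border, function(b) {
    sort(unique(comp[intersect(which(d[b, ] <= eps), core)]))
  })
  list(core_labels = comp, n_clusters = cl,
       border = border, border_reach = border_reach)
}

# Exhaustive MCS oracle: enumerate every connected induced subgraph of the
# smaller graph (by atom subset), and test element-preserving induced
# subgraph isomorphism into the other graph. Exponential; for tiny
# fixtures only.
oracle_mcs_size <- function(a, b) {
  if (a$n > b$n) { tmp <- a; a <- b; b <- tmp }
  connected_subsets <- function(adj, n) {
    out <- list()
    grow <- function(set, frontier) {
      key <- paste(sort(set), collapse = ",")
      if (!is.null(out[[key]])) return()
      out[[key]] <<- sort(set)
      for (v in frontier) {
        if (v %in% set) next
        grow(c(set, v), union(frontier, which(adj[v, ])))
      }
    }
    for (s in seq_len(n)) grow(s, which(adj[s, ]))
    out
  }
  embeds <- function(sub_el, sub_adj, g) {
    k <- length(sub_el)
    rec <- function(map) {
      i <- length(map) + 1L
      if (i > k) return(TRUE)
      for (cand in seq_len(g$n)) {
        if (cand %in% map || g$el[cand] != sub_el[i]) next
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          if (sub_adj[i, j] != g$adj[cand, map[j]]) { ok <- FALSE; break }
        }
        if (ok && rec(c(map, cand))) return(TRUE)
      }
      FALSE
    }
    rec(integer(0))
  }
  best <- 0L
  for (set in connected_subsets(a$adj, a$n)) {
    if (length(set) <= best) next
    sub_el <- a$el[set]
    sub_adj <- a$adj[set, set, drop = FALSE]
    if (embeds(sub_el, sub_adj, b)) best <- length(set)
  }
  best
}
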