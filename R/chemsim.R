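#' Tanimoto similarity from the maximum common substructure
#'
#' Exhaustive search for the largest connected common induced subgraph of
#' two heavy-atom molecule graphs: atom mappings must preserve element
#' labels and agree on the presence/absence of every bond between mapped
#' atoms (bond orders ignored), and the common subgraph must be connected.
#' The score is atom-counted Tanimoto,
#' `|MCS| / (|A| + |B| - |MCS|)`, in `[0, 1]`, equal to 1 iff the graphs
#' are isomorphic.
#'
#' The branch-and-bound search is exact; when the node budget is exceeded
#' the call fails explicitly rather than returning an approximation.
#' Panel molecules have at most 15 heavy atoms, well within the budget.
#'
#' @param a,b `molecule_graph`s.
#' @param max_nodes Search budget (expanded search-tree nodes).
#' @return List of class `mcs_result`: `score`, `size` (atoms in the MCS),
#'   `mapping` (two-column matrix of matched atom labels).
#' @export
#' @examples
#' mols <- aa_molecules()
#' mcs_tanimoto(mols$K, mols$R)$score  # 8/14
mcs_tanimoto <- function(a, b, max_nodes = 5e6) {
  stopifnot(inherits(a, "molecule_graph"), inherits(b, "molecule_graph"))
  best <- list(size = 0L, mapA = integer(0), mapB = integer(0))
  nodes <- 0L

  recurse <- function(mapA, mapB, forb) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) {
      stop("MCS search budget exceeded (", max_nodes,
           " nodes); no approximation is returned")
    }
    k <- length(mapA)
    if (k > best$size) best <<- list(size = k, mapA = mapA, mapB = mapB)
    if (k + min(a$n - k, b$n - k) <= best$size) return()
    # candidate extensions: unmapped same-element pairs adjacent to the
    # mapped core with fully consistent adjacency (induced matching)
    cand <- list()
    for (i in seq_len(a$n)) {
      if (i %in% mapA || !any(a$adj[i, mapA])) next
      for (j in seq_len(b$n)) {
        if (j %in% mapB || a$el[i] != b$el[j]) next
        if (all(a$adj[i, mapA] == b$adj[j, mapB])) {
          key <- i * 1000L + j
          if (!(key %in% forb)) cand[[length(cand) + 1L]] <- c(i, j, key)
        }
      }
    }
    if (!length(cand)) return()
    f2 <- forb
    for (cc in cand) {
      recurse(c(mapA, cc[1]), c(mapB, cc[2]), f2)
      # exclude this pair from sibling branches so each mapped set is
      # enumerated once
      f2 <- c(f2, cc[3])
    }
  }

  seeds <- expand.grid(i = seq_len(a$n), j = seq_len(b$n))
  seeds <- seeds[a$el[seeds$i] == b$el[seeds$j], , drop = FALSE]
  for (s in seq_len(nrow(seeds))) {
    recurse(seeds$i[s], seeds$j[s], integer(0))
  }

  mapping <- cbind(a = a$labels[best$mapA], b = b$labels[best$mapB])
  structure(list(score = best$size / (a$n + b$n - best$size),
                 size = best$size, mapping = mapping),
            class = "mcs_result")
}

#' Carhart atom-pair descriptors of a molecule
#'
#' Each heavy atom is typed by (element, heavy-neighbor count, pi-electron
#' count), with pi electrons counted from bond orders as
#' `sum(order - 1)` over the atom's bonds. An atom pair is the unordered
#' pair of endpoint types together with their topological distance (bond
#' count along the shortest path); a molecule of n heavy atoms yields the
#' multiset of all n(n-1)/2 pairs.
#'
#' @param g A `molecule_graph` (connected).
#' @return Character vector of descriptors (one per atom pair); the atom
#'   typing lives entirely in [carhart_atom_types()].
#' @export
ap_descriptors <- function(g) {
  stopifnot(inherits(g, "molecule_graph"))
  typ <- carhart_atom_types(g)
  d <- topological_distances(g)
  if (any(!is.finite(d))) stop("molecule graph is disconnected")
  out <- character(g$n * (g$n - 1) / 2)
  k <- 0L
  for (i in seq_len(g$n - 1)) {
    for (j in (i + 1):g$n) {
      tt <- sort(c(typ[i], typ[j]))
      k <- k + 1L
      out[k] <- paste(tt[1], tt[2], d[i, j], sep = "|")
    }
  }
  out
}

#' @rdname ap_descriptors
#' @export
carhart_atom_types <- function(g) {
  pi_e <- rowSums(g$ord - (g$ord > 0))
  paste0(g$el, rowSums(g$adj), ".", pi_e)
}

# all-pairs shortest path lengths (unit bond lengths) by BFS
topological_distances <- function(g) {
  D <- matrix(Inf, g$n, g$n)
  for (s in seq_len(g$n)) {
    d <- rep(Inf, g$n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(g$adj[v, ] & d > d[v] + 1)
      d[nb] <- d[v] + 1
      q <- c(q, nb)
    }
    D[s, ] <- d
  }
  D
}

#' Atom-pair Tanimoto similarity
#'
#' Multiset Tanimoto coefficient of the two molecules' Carhart atom-pair
#' descriptor multisets:
#' `sum(min(count_a, count_b)) / sum(max(count_a, count_b))`.
#'
#' @param a,b `molecule_graph`s.
#' @return Score in `[0, 1]`; 1 for identical descriptor multisets, 0 for
#'   disjoint ones.
#' @export
#' @examples
#' mols <- aa_molecules()
#' round(atom_pair_tanimoto(mols$R, mols$K), 2)  # 0.41
atom_pair_tanimoto <- function(a, b) {
  ta <- table(ap_descriptors(a))
  tb <- table(ap_descriptors(b))
  keys <- union(names(ta), names(tb))
  ca <- as.numeric(ta[keys]); ca[is.na(ca)] <- 0
  cb <- as.numeric(tb[keys]); cb[is.na(cb)] <- 0
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

#' Pairwise similarity matrix of the stimulus panel
#'
#' Symmetric 8 x 8 matrix of Tanimoto scores between all panel amino
#' acids, by exhaustive MCS or atom pairs. Errors in individual pairs are
#' re-signalled with the pair identity.
#'
#' @param molecules Named list of `molecule_graph`s (default the panel).
#' @param method `"mcs"` or `"ap"`.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(molecules = aa_molecules(),
                              method = c("mcs", "ap")) {
  method <- match.arg(method)
  fun <- switch(method,
                mcs = function(a, b) mcs_tanimoto(a, b)$score,
                ap = atom_pair_tanimoto)
  nm <- names(molecules)
  m <- diag(1, length(molecules))
  dimnames(m) <- list(nm, nm)
  for (ij in utils::combn(length(molecules), 2, simplify = FALSE)) {
    s <- tryCatch(fun(molecules[[ij[1]]], molecules[[ij[2]]]),
                  error = function(e) {
                    stop("similarity failed for pair ", nm[ij[1]], "/",
                         nm[ij[2]], ": ", conditionMessage(e))
                  })
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- s
  }
  m
}

#' Report atom-pair scores under both reference-number readings
#'
#' The printed reference-number list transposes the leucine/isoleucine
#' accessions (see [aa_molecules()]). This report computes the three
#' structurally-similar pair scores (R/K, W/F, M/L) under both the
#' identity assignment and the as-printed assignment, making any
#' divergence between the two conventions explicit.
#'
#' @return data.frame with columns `pair`, `mcs_identity`,
#'   `mcs_as_printed`, `ap_identity`, `ap_as_printed`, `diverges`.
#' @export
ap_reference_report <- function() {
  ident <- aa_molecules("identity")
  printed <- aa_molecules("as_printed")
  pairs <- list(c("R", "K"), c("W", "F"), c("M", "L"))
  rows <- lapply(pairs, function(p) {
    data.frame(
      pair = paste(p, collapse = "/"),
      mcs_identity = mcs_tanimoto(ident[[p[1]]], ident[[p[2]]])$score,
      mcs_as_printed = mcs_tanimoto(printed[[p[1]]], printed[[p[2]]])$score,
      ap_identity = atom_pair_tanimoto(ident[[p[1]]], ident[[p[2]]]),
      ap_as_printed = atom_pair_tanimoto(printed[[p[1]]], printed[[p[2]]]))
  })
  out <- do.call(rbind, rows)
  out$diverges <- round(out$ap_identity, 2) != round(out$ap_as_printed, 2) |
    round(out$mcs_identity, 2) != round(out$mcs_as_printed, 2)
  out
}

#' Regress cluster distances on molecular similarity
#'
#' Tests whether stimulus pairs with higher structural similarity cluster
#' at lower dendrogram distances: ordinary least squares of the normalized
#' cluster distance on the Tanimoto score over all stimulus pairings, with
#' the two-sided t test of H0: slope = 0.
#'
#' @param cluster_distance Symmetric matrix from [stimulus_cluster()].
#' @param scores Symmetric similarity matrix from [similarity_matrix()]
#'   (same stimulus order).
#' @return The [ols_slope_test()] result plus `pairs` (the underlying
#'   data.frame).
#' @export
cluster_distance_vs_similarity <- function(cluster_distance, scores) {
  stopifnot(all(rownames(cluster_distance) %in% rownames(scores)))
  scores <- scores[rownames(cluster_distance), colnames(cluster_distance)]
  ut <- upper.tri(cluster_distance)
  if (sum(ut) < 3) stop("need at least three stimulus pairs")
  df <- data.frame(
    pair = paste(rownames(cluster_distance)[row(cluster_distance)[ut]],
                 colnames(cluster_distance)[col(cluster_distance)[ut]],
                 sep = "/"),
    similarity = scores[ut],
    cluster_distance = cluster_distance[ut])
  fit <- ols_slope_test(df$similarity, df$cluster_distance)
  fit$pairs <- df
  fit
}
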