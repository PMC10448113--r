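test_that("SWC round trip and structural validation", {
  tr <- simulate_neuron_tree(2, seed = 3)
  f <- tempfile(fileext = ".swc")
  write_swc(tr, f)
  back <- read_swc(f)
  expect_equal(back$nodes$x, tr$nodes$x, tolerance = 1e-6)
  expect_equal(back$nodes$parent, tr$nodes$parent)
  # a second write of the re-read tree is byte-identical
  f2 <- tempfile(fileext = ".swc")
  write_swc(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # two roots
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 -1"), f)
  expect_error(read_swc(f), "exactly one root")
  # dangling parent
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 9"), f)
  expect_error(read_swc(f), "dangling")
  # cycle (no root at all)
  writeLines(c("1 1 0 0 0 1 2", "2 3 1 0 0 1 1"), f)
  expect_error(read_swc(f), "root")
})

test_that("critical points are ends and branches, soma excluded", {
  # unbranched chain: one end point, no branch points
  chain <- neuron_tree(data.frame(id = 1:4, parent = c(-1, 1, 2, 3),
                                  x = 0:3, y = 0, z = 0))
  cp <- critical_points(chain)
  expect_equal(cp$kind, "end")
  expect_equal(cp$ids, 4)
  # full binary tree of depth 2 below the soma: 4 ends + 2 branches
  # (the soma itself has 2 children but is excluded)
  bt <- neuron_tree(data.frame(
    id = 1:7, parent = c(-1, 1, 1, 2, 2, 3, 3),
    x = c(0, -1, 1, -2, -1.5, 1.5, 2), y = c(0, 1, 1, 2, 2, 2, 2), z = 0))
  cp2 <- critical_points(bt)
  expect_equal(sum(cp2$kind == "end"), 4)
  expect_equal(sum(cp2$kind == "branch"), 2)
  expect_false(1 %in% cp2$ids)
})

test_that("DBSCAN matches hand-derived cluster rules", {
  # 6 points inside a 10 um ball: one cluster, no blunt points
  set.seed(4)
  ball <- matrix(rnorm(18, 0, 2), 6)
  expect_equal(max(dbscan_points(ball)), 1)
  expect_true(all(dbscan_points(ball) == 1))
  # 4 points anywhere: below min_points, all noise
  expect_true(all(dbscan_points(ball[1:4, ]) == 0))
  # two 6-point balls 100 um apart: two clusters
  two <- rbind(ball, sweep(ball, 2, c(100, 0, 0), `+`))
  expect_equal(max(dbscan_points(two)), 2)
})

test_that("DBSCAN equals the density-reachability oracle", {
  set.seed(15)
  for (rep in 1:40) {
    n <- sample(5:30, 1)
    # mixture of tight clumps and scattered points
    k <- sample(1:3, 1)
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      ctr <- runif(3, 0, 120)
      matrix(rnorm(3 * sample(3:8, 1), rep(ctr, each = 1), 4), ncol = 3,
             byrow = TRUE)
    }))
    pts <- rbind(pts, matrix(runif(3 * (n %% 5 + 1), 0, 150), ncol = 3))
    lab <- dbscan_points(pts)
    orc <- oracle_dbscan_partition(pts)
    # cluster count and core-point partition must agree exactly
    expect_equal(max(lab, 0), orc$n_clusters)
    core_idx <- which(orc$core_labels > 0)
    if (length(core_idx)) {
      expect_true(all(lab[core_idx] > 0))
      # same partition up to relabeling
      expect_equal(length(unique(paste(lab[core_idx],
                                       orc$core_labels[core_idx]))),
                   orc$n_clusters)
    }
    # border points must be assigned to one of their reachable clusters
    for (bi in seq_along(orc$border)) {
      b <- orc$border[bi]
      reach <- orc$border_reach[[bi]]
      if (!length(reach)) {
        expect_equal(lab[b], 0)
      } else {
        expect_true(lab[b] %in% reach)
      }
    }
  }
})

test_that("planted tuft counts are recovered exactly on random trees", {
  set.seed(50)
  counts <- integer(200)
  planted <- integer(200)
  for (i in 1:200) {
    planted[i] <- sample(0:4, 1)
    tr <- simulate_neuron_tree(planted[i], nodes_per_tuft = sample(5:9, 1),
                               tuft_spread = runif(1, 3, 7),
                               seed = 1000 + i)
    counts[i] <- length(detect_tufts(tr)$clusters)
  }
  expect_equal(counts, planted)
})

test_that("convex hull volumes match closed forms", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube)$volume, 1, tolerance = 1e-9)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tet)$volume, 1 / 6, tolerance = 1e-9)
  # interior points do not change the hull
  cube2 <- rbind(cube, c(0.5, 0.5, 0.5), c(0.2, 0.8, 0.4))
  expect_equal(convex_hull_volume(cube2)$volume, 1, tolerance = 1e-9)
  # degenerate configurations are flagged, not errors
  flat <- cbind(matrix(runif(12), 6), 0)[, c(1, 3, 2)]
  flat <- cbind(runif(6), runif(6), 0)
  expect_true(convex_hull_volume(flat)$degenerate)
  expect_equal(convex_hull_volume(flat)$volume, 0)
  expect_true(convex_hull_volume(rbind(c(0, 0, 0), c(1, 1, 1)))$degenerate)
  # scaling: volume scales with the cube of the linear factor
  expect_equal(convex_hull_volume(3 * tet)$volume, 27 / 6,
               tolerance = 1e-9)
})

test_that("tuft distances use path metric to soma and Euclidean between", {
  # straight dendrite: soma at 0, tuft entry at 50 um
  nodes <- data.frame(
    id = 1:8, parent = c(-1, 1, 2, 3, 3, 3, 3, 3),
    x = c(0, 25, 50, 52, 54, 50, 48, 51),
    y = c(0, 0, 0, 2, -1, 3, 1, -2), z = 0)
  tr <- neuron_tree(nodes)
  det <- detect_tufts(tr)
  expect_length(det$clusters, 1)
  d <- tuft_distances(tr, det)
  expect_equal(unname(d$path_distance), 50)
  # path distance always >= Euclidean soma-center distance
  tr2 <- simulate_neuron_tree(3, seed = 9)
  det2 <- detect_tufts(tr2)
  d2 <- tuft_distances(tr2, det2)
  for (k in seq_along(det2$clusters)) {
    eu <- sqrt(sum((det2$clusters[[k]]$center -
                    as.numeric(tr2$nodes[1, c("x", "y", "z")]))^2))
    expect_gte(d2$path_distance[k] + 1e-9,
               eu - max(dist(det2$clusters[[k]]$coords)))
  }
  # two clusters with centres 30 um apart
  nodes2 <- nodes
  extra <- data.frame(id = 9:15, parent = c(1, 9, rep(10, 5)),
                      x = c(40, 80, 82, 84, 80, 78, 81) ,
                      y = c(0, 30, 32, 29, 33, 31, 28), z = 0)
  tr3 <- neuron_tree(rbind(nodes, extra))
  det3 <- detect_tufts(tr3)
  expect_length(det3$clusters, 2)
  cc <- sqrt(sum((det3$clusters[[1]]$center - det3$clusters[[2]]$center)^2))
  d3 <- tuft_distances(tr3, det3)
  expect_equal(unname(d3$intercluster[1, 2]), cc)
})

test_that("nine-feature vectors read out the planted morphology", {
  tr1 <- simulate_neuron_tree(1, seed = 31)
  f1 <- extract_features(tr1)
  expect_length(f1, 9)
  expect_equal(unname(f1["n_tufts"]), 1)
  expect_equal(unname(f1["n_primary_stems"]), 1)
  expect_equal(unname(f1["mean_intertuft_dist"]), 0)
  tr3 <- simulate_neuron_tree(3, seed = 32, n_basal = 2)
  f3 <- extract_features(tr3)
  expect_equal(unname(f3["n_tufts"]), 3)
  expect_equal(unname(f3["n_primary_stems"]), 3)
  expect_equal(unname(f3["n_primary_basal"]), 2)
  expect_gt(f3["mean_tuft_volume"], 0)
  # bare chain: all tuft features 0 with the flag set
  chain <- neuron_tree(data.frame(id = 1:12, parent = c(-1, 1:11),
                                  x = seq(0, 110, 10), y = 0, z = 0))
  fc <- extract_features(chain)
  expect_true(attr(fc, "no_tufts"))
  expect_equal(unname(fc["n_tufts"]), 0)
  expect_equal(unname(fc["mean_tuft_volume"]), 0)
})

test_that("population PCA standardizes and explains planted structure", {
  set.seed(33)
  # two informative dimensions replicated across nine features
  u <- rnorm(30); v <- rnorm(30)
  feats <- cbind(u, u * 2, u - v, v, v * 3, u + v, -u, -v, u + 2 * v)
  colnames(feats) <- paste0("f", 1:9)
  pc <- population_pca(feats + matrix(rnorm(270, 0, 1e-6), 30))
  expect_gt(sum(pc$explained[1:2]), 0.999)
  expect_equal(sum(pc$explained), 1)
  # duplicated cells land on identical scores
  feats2 <- rbind(feats, feats[1, , drop = FALSE])
  pc2 <- population_pca(feats2 + 0)
  expect_equal(unname(pc2$scores[31, ]), unname(pc2$scores[1, ]))
  # constant features are dropped with a record
  feats3 <- cbind(feats, constant = 1)
  pc3 <- population_pca(feats3)
  expect_equal(pc3$dropped, "constant")
  expect_error(population_pca(feats[1:2, ]), "3 cells")
})

test_that("tuft count distributions are normalized frequencies", {
  expect_equal(unname(classify_tuft_count_distribution(rep(1L, 5))),
               1)
  d <- classify_tuft_count_distribution(c(1, 1, 2, 2, 2, 3))
  expect_equal(sum(d), 1)
  expect_equal(unname(d["2"]), 0.5)
})
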