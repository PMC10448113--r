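test_that("threshold classification yields nested default/dominant sets", {
  pr <- fixture_profile(c(H = 0.9, F = 0.5, W = 0.4,
                          M = 0.05, L = 0.05, I = 0.05, K = 0.05,
                          R = 0.05), baseline_sd = 0.1)
  cl <- classify_tuning(pr)
  expect_equal(cl$default_set, c("H", "F", "W"))
  expect_equal(cl$dominant_set, c("H", "F", "W"))
  expect_equal(cl$dominant_label, "HFW")

  # borderline case: between 2x and 3x SD is default-only
  pr2 <- fixture_profile(c(H = 0.9, K = 0.25), baseline_sd = 0.1)
  cl2 <- classify_tuning(pr2)
  expect_equal(cl2$default_set, c("H", "K"))
  expect_equal(cl2$dominant_set, "H")
  expect_true(all(cl2$dominant_set %in% cl2$default_set))

  # untuned and degenerate-threshold cases
  expect_equal(classify_tuning(fixture_profile(c(), 0.1))$default_label, "")
  cl0 <- classify_tuning(fixture_profile(c(W = 0.2), baseline_sd = 0))
  expect_equal(cl0$default_label, "W")
  expect_equal(cl0$dominant_label, "W")
})

test_that("dominant is a subset of default for random profiles", {
  set.seed(11)
  for (i in 1:50) {
    amps <- setNames(runif(8, 0, 1), aa_panel())
    pr <- fixture_profile(amps, baseline_sd = runif(1, 0, 0.4))
    cl <- classify_tuning(pr)
    expect_true(all(cl$dominant_set %in% cl$default_set))
  }
})

test_that("lifetime sparseness matches its defining values", {
  expect_equal(lifetime_sparseness(rep(0.37, 8)), 0)
  expect_equal(lifetime_sparseness(c(1, rep(0, 7))), 1)
  expect_equal(lifetime_sparseness(c(1, 0.5)), 0.2)
  # invariant under positive rescaling
  set.seed(2)
  r <- runif(8)
  expect_equal(lifetime_sparseness(r), lifetime_sparseness(13 * r))
  # strictly decreasing as mass spreads from one-hot toward uniform
  path <- seq(0, 1, by = 0.1)
  vals <- vapply(path, function(a) {
    lifetime_sparseness((1 - a) * c(1, rep(0, 7)) + a * rep(1 / 8, 8))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(lifetime_sparseness(rep(0, 8)), "all-zero")
  expect_error(lifetime_sparseness(c(-1, 1)), "non-negative")
  expect_error(lifetime_sparseness(1), "two")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  profs <- list(
    fixture_profile(c(M = 1, L = 0.8), roi_id = "a"),
    fixture_profile(c(M = 0.5, L = 0.4), roi_id = "b"),
    fixture_profile(c(W = 1), roi_id = "c"))
  cm <- correlation_matrix(profs, by = "roi")
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["a", "b"], 1)  # proportional vectors
  # independent long random vectors correlate near zero
  set.seed(3)
  n <- 2000
  x <- rnorm(n); y <- rnorm(n)
  expect_lt(abs(cor(x, y)), 3 / sqrt(n))
})

test_that("average-linkage clustering equals the brute-force oracle", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(runif(5 * 6), 5)
    d <- dist(m)
    hc <- hclust(d, method = "average")
    orc <- oracle_average_linkage(d)
    expect_equal(sort(hc$height), sort(orc$heights), tolerance = 1e-10)
    expect_equal(as.matrix(cophenetic(hc)), orc$cophenetic,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("stimulus clustering normalizes cluster distances to [0, 1]", {
  set.seed(7)
  profs <- lapply(1:12, function(i) {
    fixture_profile(setNames(runif(8), aa_panel()), roi_id = paste0("r", i))
  })
  sc <- stimulus_cluster(profs)
  cd <- sc$cluster_distance
  expect_equal(max(cd), 1)
  expect_true(all(cd >= 0 & cd <= 1))
  expect_equal(cd, t(cd))
  # stimuli with identical pooled vectors merge first at distance 0
  profs2 <- lapply(profs, function(p) {
    p$panel_amplitudes["L"] <- p$panel_amplitudes["M"]
    p$amplitudes <- p$panel_amplitudes
    p
  })
  sc2 <- stimulus_cluster(profs2)
  expect_equal(sc2$cluster_distance["M", "L"], 0)
  expect_equal(min(sc2$hclust$height), 0)
})

test_that("tuning broadness histograms count selected stimuli", {
  cls <- list(
    classify_tuning(fixture_profile(c(W = 0.9), 0.1)),
    classify_tuning(fixture_profile(c(R = 0.8), 0.1)),
    classify_tuning(fixture_profile(c(H = 0.9, F = 0.8, W = 0.7), 0.1)))
  tb <- tuning_broadness(cls)
  expect_equal(unname(tb$dominant["1"]), 2)
  expect_equal(unname(tb$dominant["3"]), 1)
  expect_equal(sum(tb$default), sum(tb$dominant))
  # dominant breadth never exceeds default breadth
  expect_true(all(cumsum(tb$dominant) >= cumsum(tb$default)))
})

test_that("species tables summarize counts across animals", {
  mk <- function(labels) {
    lapply(labels, function(l) {
      amps <- setNames(rep(0.9, nchar(l)), strsplit(l, "")[[1]])
      classify_tuning(fixture_profile(amps, 0.1))
    })
  }
  st <- species_table(list(a1 = mk(c("W", "W", "R")),
                           a2 = mk(c("R", "HK"))))
  expect_equal(st$counts["a1", "W"], 2)
  expect_equal(st$counts["a1", "R"], 1)
  expect_equal(st$summary$lacking_ratio[st$summary$species == "W"], 0.5)
  expect_equal(st$summary$lacking_ratio[st$summary$species == "R"], 0)
  # per-animal counts sum to the animal's classified ROI count
  expect_equal(unname(rowSums(st$counts)), c(3, 2))
})

test_that("planted species frequencies are recovered across a cohort", {
  spec <- data.frame(label = c("W", "HK"), freq = c(0.75, 0.25))
  p <- make_protocol(repeats = 2, seed = 20)
  labs <- unlist(lapply(1:3, function(a) {
    ds <- simulate_roi_dataset(60, p, tuning_spec = spec, snr = 50,
                               seed = 30 + a)
    ds$ground_truth$label
  }))
  frac_w <- mean(labs == "W")
  expect_equal(frac_w, 0.75, tolerance = 3 * sqrt(0.75 * 0.25 / 180))
})

test_that("odor space coordinates are bounded pairwise differences", {
  pr <- fixture_profile(c(R = 1, W = 0, K = 0.5, H = 0.5, M = 0.3,
                          I = 0.3))
  xyz <- odor_space_coordinates(pr)
  expect_equal(unname(xyz["R-W"]), 1)
  expect_equal(unname(xyz["K-H"]), 0)
  expect_equal(unname(xyz["M-I"]), 0)
  expect_true(all(abs(xyz) <= 1))
  expect_error(odor_space_coordinates(pr, list(c("R", "Z"), c("K", "H"),
                                               c("M", "I"))),
               "unknown")
})

test_that("correlation distributions separate archetype from noise groups", {
  set.seed(9)
  arch <- runif(8)
  grp_arch <- t(vapply(1:12, function(i) arch + rnorm(8, 0, 0.05),
                       numeric(8)))
  grp_rand <- matrix(runif(12 * 8), 12)
  res <- correlation_distribution_compare(
    list(linked = grp_arch, independent = grp_rand))
  expect_gt(median(res$distributions$linked),
            median(res$distributions$independent))
  expect_gt(res$fraction_above["linked"], 0.9)
  # identical vectors: all coefficients 1, fraction 1
  same <- matrix(rep(arch, 5), 5, byrow = TRUE) +
    matrix(rep(seq(0, 0.004, 0.001), 8), 5)  # tiny offsets keep sd > 0
  res2 <- correlation_distribution_compare(list(same = same,
                                                other = grp_rand))
  expect_gt(min(res2$distributions$same), 0.999)
  expect_equal(unname(res2$fraction_above["same"]), 1)
})
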