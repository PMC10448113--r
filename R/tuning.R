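#' Classify default and dominant odor tuning
#'
#' The default (dominant) odor tuning of an ROI is the set of panel stimuli
#' whose response peak amplitude exceeds 2x (3x) the standard deviation of
#' the averaged baseline fluorescence of the stimulation sequence. The
#' dominant set is always a subset of the default set; both may be empty
#' (untuned ROI). Labels concatenate the selected single-letter codes in
#' fixed panel order, e.g. `"HFW"`.
#'
#' @param profile A [extract_response_profile()] result.
#' @param default_factor Threshold multiple for the default tuning (2).
#' @param dominant_factor Threshold multiple for the dominant tuning (3).
#' @return Object of class `tuning_classification` with `roi_id`,
#'   `default_set`, `dominant_set`, `default_label`, `dominant_label`.
#' @export
#' @examples
#' pr <- structure(list(roi_id = "r1", baseline_sd = 0.1,
#'   panel_amplitudes = c(M = 0, L = 0, I = 0, H = .9, K = 0, R = 0,
#'                        F = .5, W = .4)), class = "response_profile")
#' classify_tuning(pr)$dominant_label  # "HFW"
classify_tuning <- function(profile, default_factor = 2,
                            dominant_factor = 3) {
  r <- profile$panel_amplitudes
  sdv <- profile$baseline_sd
  def <- names(r)[r > default_factor * sdv]
  dom <- names(r)[r > dominant_factor * sdv]
  structure(list(roi_id = profile$roi_id,
                 default_set = GLOMAP_PANEL[GLOMAP_PANEL %in% def],
                 dominant_set = GLOMAP_PANEL[GLOMAP_PANEL %in% dom],
                 default_label = tuning_label(def),
                 dominant_label = tuning_label(dom)),
            class = "tuning_classification")
}

#' Lifetime sparseness of a response amplitude vector
#'
#' `S = (1 - (sum(r)/N)^2 / (sum(r^2)/N)) / (1 - 1/N)` for non-negative
#' responses r over N stimuli. S equals 0 when a region responds equally
#' strongly to all stimuli and 1 when it responds exclusively to one; it is
#' invariant under positive rescaling of r.
#'
#' @param r Non-negative amplitude vector, not all zero.
#' @param n Panel size N (default `length(r)`).
#' @return Sparseness in `[0, 1]`.
#' @export
#' @examples
#' lifetime_sparseness(rep(0.3, 8))      # 0
#' lifetime_sparseness(c(1, rep(0, 7)))  # 1
lifetime_sparseness <- function(r, n = length(r)) {
  if (n < 2) stop("sparseness needs at least two stimuli")
  if (any(r < 0)) stop("amplitudes must be non-negative")
  if (all(r == 0)) stop("sparseness undefined for an all-zero response vector")
  (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
}

# amplitude matrix (ROI x stimulus) from a list of profiles
amplitude_matrix <- function(profiles) {
  m <- t(vapply(profiles, panel_amplitude_vector,
                numeric(length(GLOMAP_PANEL))))
  colnames(m) <- GLOMAP_PANEL
  rownames(m) <- vapply(profiles, `[[`, "", "roi_id")
  m
}

#' Pearson correlation matrix of response amplitude vectors
#'
#' Correlates pooled response peak amplitude vectors either between
#' stimuli (columns of the ROI x stimulus amplitude matrix) or between
#' ROIs (rows). Zero-variance vectors make the corresponding entries
#' undefined; they are set to NA and flagged.
#'
#' @param profiles List of `response_profile`s (>= 2 vectors).
#' @param by `"stimulus"` or `"roi"`.
#' @return List with `r` (symmetric correlation matrix, unit diagonal)
#'   and `flagged` (names of zero-variance vectors).
#' @export
correlation_matrix <- function(profiles, by = c("stimulus", "roi")) {
  by <- match.arg(by)
  m <- amplitude_matrix(profiles)
  if (by == "roi") m <- t(m)
  if (ncol(m) < 2) stop("need at least two vectors to correlate")
  sds <- apply(m, 2, sd)
  flagged <- colnames(m)[sds == 0]
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  list(r = r, flagged = flagged)
}

#' Average-linkage clustering of stimuli on correlation distance
#'
#' Agglomerative hierarchical clustering of the eight stimuli using the
#' correlation distance `d = 1 - Pearson r` between pooled amplitude
#' vectors and the average linkage method. The pairwise cluster distance
#' of two stimuli is their cophenetic merge height normalized to `[0, 1]`
#' by the maximum merge height of the dendrogram.
#'
#' @param profiles List of `response_profile`s (>= 3 stimuli required).
#' @return List with `hclust` (the dendrogram), `cluster_distance`
#'   (symmetric matrix of normalized cophenetic distances) and `cor` (the
#'   stimulus correlation matrix).
#' @export
stimulus_cluster <- function(profiles) {
  cm <- correlation_matrix(profiles, by = "stimulus")
  r <- cm$r
  if (nrow(r) < 3) stop("need at least three stimuli to cluster")
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  coph <- as.matrix(cophenetic(hc))
  mx <- max(coph)
  if (mx > 0) coph <- coph / mx
  list(hclust = hc, cluster_distance = coph, cor = r)
}

#' Histogram of odor tuning broadness
#'
#' Tuning broadness is the number of stimuli in an ROI's default or
#' dominant set. Returns counts per breadth 0..8 for both thresholds;
#' the two histograms always contain the same total count.
#'
#' @param classifications List of [classify_tuning()] results.
#' @return List with `default` and `dominant` count vectors (names 0..8).
#' @export
tuning_broadness <- function(classifications) {
  if (!length(classifications)) stop("no classifications supplied")
  n_max <- length(GLOMAP_PANEL)
  count <- function(sets) {
    b <- vapply(sets, length, 0L)
    table(factor(b, levels = 0:n_max))
  }
  list(default = count(lapply(classifications, `[[`, "default_set")),
       dominant = count(lapply(classifications, `[[`, "dominant_set")))
}

#' Glomerular species frequency table across animals
#'
#' A glomerular species is the set of ROIs sharing one tuning label. Given
#' per-animal classification lists, counts each species per animal and
#' summarizes the mean and SD of counts across animals together with the
#' fraction of animals lacking the species entirely.
#'
#' @param classifications_by_animal Named list; one list of
#'   [classify_tuning()] results per animal.
#' @param tuning `"dominant"` or `"default"` labels.
#' @param drop_untuned Exclude the empty label (default TRUE).
#' @return List with `counts` (animal x species matrix) and `summary`
#'   (data.frame: species, mean, sd, lacking_ratio, total), species ordered
#'   by decreasing total occurrence.
#' @export
species_table <- function(classifications_by_animal,
                          tuning = c("dominant", "default"),
                          drop_untuned = TRUE) {
  tuning <- match.arg(tuning)
  if (!length(classifications_by_animal)) stop("need at least one animal")
  fld <- paste0(tuning, "_label")
  labs <- lapply(classifications_by_animal, function(cls) {
    vapply(cls, `[[`, "", fld)
  })
  all_species <- sort(unique(unlist(labs)))
  if (drop_untuned) all_species <- setdiff(all_species, "")
  counts <- t(vapply(labs, function(l) {
    table(factor(l, levels = all_species))
  }, numeric(length(all_species))))
  if (length(all_species) == 1L) {
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(labs), all_species))
  }
  totals <- colSums(counts)
  ord <- order(totals, decreasing = TRUE)
  counts <- counts[, ord, drop = FALSE]
  summary <- data.frame(
    species = colnames(counts),
    mean = colMeans(counts),
    sd = apply(counts, 2, sd),
    lacking_ratio = colMeans(counts == 0),
    total = colSums(counts),
    row.names = NULL)
  list(counts = counts, summary = summary)
}

#' Odor-space coordinates of an ROI
#'
#' Represents an ROI in a simplified 3D odor space whose axes are pairwise
#' differences between normalized response peak amplitudes (each in
#' `[-1, 1]`). The default axes include the R-W difference that separates
#' arginine- from tryptophan-biased profiles.
#'
#' @param profile A `response_profile`.
#' @param axis_pairs List of 3 two-letter code pairs, e.g.
#'   `list(c("R","W"), c("K","H"), c("M","I"))`.
#' @return Named numeric vector of 3 coordinates (`"R-W"` etc.).
#' @export
odor_space_coordinates <- function(profile,
                                   axis_pairs = list(c("R", "W"),
                                                     c("K", "H"),
                                                     c("M", "I"))) {
  r <- panel_amplitude_vector(profile)
  out <- vapply(axis_pairs, function(p) {
    if (!all(p %in% names(r))) {
      stop("unknown stimulus code in axis pair: ", paste(p, collapse = "-"))
    }
    r[[p[1]]] - r[[p[2]]]
  }, numeric(1))
  names(out) <- vapply(axis_pairs, paste, "", collapse = "-")
  out
}

#' Compare correlation-coefficient distributions across populations
#'
#' For each named group of amplitude vectors, computes Pearson correlation
#' coefficients between all vector pairings, ranks them, and reports the
#' fraction exceeding `threshold` (0.7 marks high tuning similarity).
#' Groups are compared pairwise by Mann-Whitney U via the stats module.
#'
#' @param groups Named list; each element a list of `response_profile`s or
#'   an amplitude matrix (rows = ROIs), >= 2 vectors each.
#' @param threshold High-similarity cutoff on Pearson r.
#' @return List with `distributions` (named list of sorted coefficient
#'   vectors), `fraction_above` (named numeric), `tests` (data.frame of
#'   pairwise group comparisons) and `flagged` (degenerate vectors).
#' @export
correlation_distribution_compare <- function(groups, threshold = 0.7) {
  flagged <- character(0)
  dists <- lapply(names(groups), function(g) {
    m <- groups[[g]]
    if (!is.matrix(m)) m <- amplitude_matrix(m)
    if (nrow(m) < 2) stop("group '", g, "' has fewer than 2 vectors")
    keep <- apply(m, 1, sd) > 0
    if (any(!keep)) {
      flagged <<- c(flagged, paste0(g, ":", rownames(m)[!keep]))
    }
    m <- m[keep, , drop = FALSE]
    r <- cor(t(m))
    sort(r[upper.tri(r)], decreasing = TRUE)
  })
  names(dists) <- names(groups)
  frac <- vapply(dists, function(d) mean(d > threshold), numeric(1))
  tests <- list()
  gn <- names(groups)
  if (length(gn) >= 2) {
    for (ij in utils::combn(length(gn), 2, simplify = FALSE)) {
      tt <- two_group(dists[[ij[1]]], dists[[ij[2]]])
      tests[[length(tests) + 1L]] <- data.frame(
        group_a = gn[ij[1]], group_b = gn[ij[2]],
        statistic = tt$statistic, p = tt$p)
    }
  }
  list(distributions = dists, fraction_above = frac,
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       flagged = flagged)
}
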