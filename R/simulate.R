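#' Default glomerular species frequency table
#'
#' Frequencies used by [simulate_roi_dataset()] when no `tuning_spec` is
#' given. Single-letter species for each panel stimulus are most frequent,
#' followed by compound profiles of structurally similar amino acids (KR,
#' HW, HFW, ML, MLI) and a few dissimilar compounds, loosely mirroring the
#' observed ranking in which W, R, KR and M glomeruli are present in most
#' animals while many compound profiles are rare.
#'
#' @return data.frame with columns `label` and `freq` (relative weights).
#' @export
default_tuning_spec <- function() {
  data.frame(
    label = c("W", "R", "KR", "M", "K", "H", "F", "L", "I",
              "HW", "HFW", "ML", "MLI", "RW", "HK"),
    freq  = c(10, 9, 8, 8, 6, 6, 5, 5, 5, 4, 3, 3, 2, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulate an ROI-level calcium imaging dataset with known ground truth
#'
#' Generates stimulus-locked calcium transients for every ROI of a recording:
#' a slowly drifting baseline, single-exponential decay transients
#' (instantaneous rise, decay time constant `tau`, the order of GCaMP6s
#' kinetics) whose amplitudes follow a planted tuning vector, and Gaussian
#' noise with SD = `peak_scale / snr`. ROI footprint areas and 3D centroids
#' inside the unit glomerular-cluster box are drawn alongside, and the full
#' ground truth (tuning vectors, noise SD, positions, species labels) is
#' returned for parameter-recovery testing.
#'
#' Each ROI is assigned a glomerular species label drawn from `tuning_spec`.
#' Member stimuli of the label receive true response amplitudes in
#' `amp_range` (as a fraction of the baseline fluorescence); non-members
#' respond with 0. The mixture stimulus evokes the maximum member amplitude
#' so that filtering's two-response rule is exercised.
#'
#' @param n_rois Number of ROIs (>= 1).
#' @param protocol An [make_protocol()] object.
#' @param tuning_spec data.frame with `label` and `freq` columns; see
#'   [default_tuning_spec()].
#' @param snr Peak signal-to-noise ratio; noise SD = max planted amplitude
#'   divided by `snr`.
#' @param seed Integer seed; fixed seeds give identical datasets.
#' @param layout `"random"` (positions uniform in the unit box) or
#'   `"chemotopic"` (species territories arranged by structural similarity,
#'   see [chemotopic_layout()]).
#' @param amp_range Range of true member response amplitudes (dF/F units).
#' @param baseline_f Mean baseline fluorescence, a.u.
#' @param tau Transient decay time constant, s.
#' @param drift_amp Peak-to-peak relative amplitude of the slow polynomial
#'   baseline drift; 0 disables drift.
#' @param area_floor Minimum footprint area, um^2.
#' @param small_area_fraction Fraction of ROIs drawn with areas below the
#'   25 um^2 exclusion threshold, to exercise filtering.
#' @param untuned_fraction Fraction of ROIs with an all-zero tuning vector.
#'
#' @return A list of class `roi_dataset`: `records` (list of `roi_record`,
#'   each with `roi_id`, `level`, `footprint_area`, `centroid`,
#'   `raw_trace`), `protocol`, and `ground_truth` (data.frame of planted
#'   parameters plus a `amplitudes` matrix attribute).
#' @export
#' @examples
#' p <- make_protocol(repeats = 2, seed = 1)
#' ds <- simulate_roi_dataset(20, p, snr = 10, seed = 1)
#' ds$ground_truth$label[1:5]
simulate_roi_dataset <- function(n_rois, protocol,
                                 tuning_spec = default_tuning_spec(),
                                 snr = 10, seed = NULL,
                                 layout = c("random", "chemotopic"),
                                 amp_range = c(0.6, 1), baseline_f = 100,
                                 tau = 4, drift_amp = 0.05,
                                 area_floor = 10, small_area_fraction = 0,
                                 untuned_fraction = 0) {
  if (n_rois < 1L) stop("n_rois must be >= 1: an empty ROI set is not a dataset")
  if (snr <= 0) stop("snr must be > 0")
  layout <- match.arg(layout)
  local_rng(seed)

  labels <- sample(tuning_spec$label, n_rois, replace = TRUE,
                   prob = tuning_spec$freq)
  # ground-truth labels in canonical panel order, matching classify_tuning
  labels <- vapply(strsplit(labels, ""), tuning_label, "")
  if (untuned_fraction > 0) {
    labels[runif(n_rois) < untuned_fraction] <- ""
  }

  panel <- protocol$panel
  amps <- matrix(0, n_rois, length(panel), dimnames = list(NULL, panel))
  for (i in seq_len(n_rois)) {
    members <- strsplit(labels[i], "")[[1]]
    if (length(members)) {
      amps[i, members] <- runif(length(members), amp_range[1], amp_range[2])
    }
  }

  pos <- switch(layout,
    random = matrix(runif(3 * n_rois), n_rois, 3),
    chemotopic = chemotopic_layout(labels))
  colnames(pos) <- c("x", "y", "z")

  areas <- area_floor + stats::rgamma(n_rois, shape = 2.5, scale = 25)
  if (small_area_fraction > 0) {
    small <- runif(n_rois) < small_area_fraction
    areas[small] <- runif(sum(small), 5, 24)
  }

  peak_scale <- max(amps, if (any(nzchar(labels))) amp_range[2] else 1)
  noise_sd <- peak_scale / snr

  records <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    tr <- synth_trace(protocol, amps[i, ], baseline_f = baseline_f,
                      tau = tau, drift_amp = drift_amp,
                      noise_sd = noise_sd * baseline_f)
    records[[i]] <- structure(
      list(roi_id = sprintf("roi%04d", i), level = "glomerular_input",
           footprint_area = areas[i], centroid = pos[i, ],
           raw_trace = tr, manual_flag = FALSE),
      class = "roi_record")
  }

  gt <- data.frame(roi_id = sprintf("roi%04d", seq_len(n_rois)),
                   label = labels, noise_sd = noise_sd,
                   footprint_area = areas,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   stringsAsFactors = FALSE)
  attr(gt, "amplitudes") <- amps

  structure(list(records = records, protocol = protocol, ground_truth = gt),
            class = "roi_dataset")
}

# One raw fluorescence trace: baseline x (1 + drift) x (1 + transients) + noise.
# Transient onsets snap to the first frame at/after the stimulus onset so the
# planted peak amplitude is realized exactly at that frame (up to noise).
synth_trace <- function(protocol, amp_by_code, baseline_f = 100, tau = 4,
                        drift_amp = 0.05, noise_sd = 0) {
  t <- protocol$times
  n <- protocol$n_frames
  drift <- if (drift_amp > 0) {
    u <- t / max(t)
    cf <- runif(3, -1, 1)
    d <- cf[1] * u + cf[2] * u^2 + cf[3] * u^3
    drift_amp * (d - min(d)) / max(1e-12, diff(range(d)))
  } else rep(0, n)

  resp <- rep(0, n)
  for (k in seq_len(nrow(protocol$events))) {
    code <- protocol$events$code[k]
    a <- if (code %in% names(amp_by_code)) {
      amp_by_code[[code]]
    } else if (code == protocol$mixture_code) {
      max(amp_by_code, 0)
    } else 0
    if (a <= 0) next
    i0 <- which(t >= protocol$events$onset[k])[1]
    idx <- i0:n
    resp[idx] <- resp[idx] + a * exp(-(t[idx] - t[i0]) / tau)
  }

  base <- baseline_f * (1 + drift)
  base * (1 + resp) + rnorm(n, 0, noise_sd)
}

#' Chemotopic species layout
#'
#' Places species territories so that structurally similar amino acids
#' (groups M/L/I, K/R, H/F/W) occupy neighbouring regions of the normalized
#' glomerular cluster: each similarity group is anchored at a distinct,
#' well-separated location, single-letter species sit near their group
#' anchor, and compound profiles within one similarity group sit at the
#' mean of their constituents' centers. A compound species spanning
#' several groups has no central home under chemotopy -- its constituents'
#' territories are far apart -- so it is placed inside the territory of
#' its first constituent (panel order). Individual glomeruli scatter
#' around the species center with isotropic Gaussian jitter.
#'
#' The geometry (anchor separation ~0.6, within-group offset 0.12, member
#' jitter SD 0.06) represents a strong chemotopic map and is the planted
#' alternative for power analyses of the chemotopy tests; `"random"`
#' layouts are the matching null.
#'
#' @param labels Character vector of species labels, one per ROI.
#' @param jitter_sd Member scatter around the species center.
#' @return n x 3 matrix of positions clipped to the unit box.
#' @export
chemotopic_layout <- function(labels, jitter_sd = 0.06) {
  groups <- list(MLI = c("M", "L", "I"), KR = c("K", "R"),
                 HFW = c("H", "F", "W"))
  anchors <- rbind(MLI = c(0.2, 0.2, 0.5), KR = c(0.8, 0.2, 0.5),
                   HFW = c(0.5, 0.8, 0.5))
  # deterministic within-group offsets on a small circle around the anchor
  centers <- list()
  for (g in names(groups)) {
    mem <- groups[[g]]
    ang <- 2 * pi * (seq_along(mem) - 1) / length(mem)
    for (j in seq_along(mem)) {
      centers[[mem[j]]] <- anchors[g, ] +
        0.12 * c(cos(ang[j]), sin(ang[j]), 0)
    }
  }
  one_group <- function(m) {
    any(vapply(groups, function(g) all(m %in% g), TRUE))
  }
  species_center <- function(lab) {
    if (!nzchar(lab)) return(runif(3))
    m <- strsplit(lab, "")[[1]]
    if (one_group(m)) colMeans(do.call(rbind, centers[m]))
    else centers[[m[1]]]
  }
  pos <- t(vapply(labels, function(l) {
    species_center(l) + rnorm(3, 0, jitter_sd)
  }, numeric(3)))
  pmin(pmax(pos, 0), 1)
}

#' Write / read an ROI dataset as CSV + JSON sidecar
#'
#' Traces go to `<stem>_traces.csv` (one column per ROI, one row per frame),
#' ROI metadata to `<stem>_rois.csv`, and the protocol plus ground truth to
#' `<stem>.json`. The same schema is accepted for real exports.
#'
#' @param dataset An `roi_dataset`.
#' @param stem Path stem (no extension).
#' @return `write_roi_dataset`: the stem, invisibly. `read_roi_dataset`:
#'   an `roi_dataset`.
#' @export
write_roi_dataset <- function(dataset, stem) {
  traces <- vapply(dataset$records, function(r) r$raw_trace,
                   numeric(dataset$protocol$n_frames))
  colnames(traces) <- vapply(dataset$records, `[[`, "", "roi_id")
  write.csv(traces, paste0(stem, "_traces.csv"), row.names = FALSE)

  meta <- data.frame(
    roi_id = colnames(traces),
    level = vapply(dataset$records, `[[`, "", "level"),
    footprint_area = vapply(dataset$records, `[[`, 0, "footprint_area"),
    x = vapply(dataset$records, function(r) r$centroid[[1]], 0),
    y = vapply(dataset$records, function(r) r$centroid[[2]], 0),
    z = vapply(dataset$records, function(r) r$centroid[[3]], 0),
    manual_flag = vapply(dataset$records, `[[`, FALSE, "manual_flag"))
  write.csv(meta, paste0(stem, "_rois.csv"), row.names = FALSE)

  side <- list(
    protocol = list(events = dataset$protocol$events,
                    frame_rate = dataset$protocol$frame_rate,
                    pre_record = dataset$protocol$pre_record,
                    inter_stimulus = dataset$protocol$inter_stimulus,
                    stim_duration = dataset$protocol$stim_duration,
                    panel = dataset$protocol$panel,
                    mixture_code = dataset$protocol$mixture_code,
                    n_frames = dataset$protocol$n_frames),
    ground_truth = dataset$ground_truth,
    true_amplitudes = attr(dataset$ground_truth, "amplitudes"))
  jsonlite::write_json(side, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(stem)
}

#' @rdname write_roi_dataset
#' @export
read_roi_dataset <- function(stem) {
  traces <- read.csv(paste0(stem, "_traces.csv"), check.names = FALSE)
  meta <- read.csv(paste0(stem, "_rois.csv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)

  pr <- side$protocol
  events <- as.data.frame(pr$events, stringsAsFactors = FALSE)
  protocol <- structure(list(
    events = events, frame_rate = pr$frame_rate, pre_record = pr$pre_record,
    inter_stimulus = pr$inter_stimulus, stim_duration = pr$stim_duration,
    n_frames = pr$n_frames,
    times = (seq_len(pr$n_frames) - 1L) / pr$frame_rate,
    panel = pr$panel, mixture_code = pr$mixture_code),
    class = "acq_protocol")

  records <- lapply(seq_len(nrow(meta)), function(i) {
    structure(list(
      roi_id = meta$roi_id[i], level = meta$level[i],
      footprint_area = meta$footprint_area[i],
      centroid = c(x = meta$x[i], y = meta$y[i], z = meta$z[i]),
      raw_trace = traces[[meta$roi_id[i]]],
      manual_flag = isTRUE(meta$manual_flag[i])), class = "roi_record")
  })

  gt <- as.data.frame(side$ground_truth, stringsAsFactors = FALSE)
  if (!is.null(side$true_amplitudes)) {
    attr(gt, "amplitudes") <- as.matrix(side$true_amplitudes)
  }
  structure(list(records = records, protocol = protocol, ground_truth = gt),
            class = "roi_dataset")
}
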