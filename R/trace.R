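#' Asymmetric least squares baseline estimation
#'
#' Estimates the slowly varying baseline of a fluorescence trace by
#' asymmetric least squares smoothing: the baseline z minimizes
#' `sum w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2` where points above the
#' baseline get weight `p` and points below weight `1 - p`. With small `p`
#' the sparse positive calcium transients are ignored while drift is
#' followed. Defaults (`lambda = 1e4` frames^2, `p = 0.01`) are the
#' standard regime for slow drift under sparse transients.
#'
#' @param y Numeric trace (>= 10 finite samples).
#' @param lambda Second-difference penalty weight.
#' @param p Asymmetry weight applied above the baseline.
#' @param max_iter Reweighting iterations (converges in a few).
#' @return Numeric baseline of the same length.
#' @export
als_baseline <- function(y, lambda = 1e4, p = 0.01, max_iter = 12) {
  n <- length(y)
  if (n < 10) stop("trace too short for baseline estimation (need >= 10 frames)")
  if (any(!is.finite(y))) stop("trace contains non-finite samples")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, w)
    z_new <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z_new, p, 1 - p)
    if (all(w_new == w) && it > 1) { z <- z_new; break }
    w <- w_new
    z <- z_new
  }
  z
}

#' Baseline-correct a raw trace into dF/F
#'
#' Runs [als_baseline()] and converts the trace to relative fluorescence
#' change `dff = (raw - baseline) / baseline`.
#'
#' @inheritParams als_baseline
#' @param raw Raw fluorescence trace, a.u.
#' @return List with `baseline` and `dff`.
#' @export
#' @examples
#' correct_baseline(rep(100, 50))$dff  # ~0 everywhere
correct_baseline <- function(raw, lambda = 1e4, p = 0.01) {
  base <- als_baseline(raw, lambda = lambda, p = p)
  if (any(base <= 0)) {
    stop("estimated baseline is non-positive; dF/F undefined")
  }
  list(baseline = base, dff = (raw - base) / base)
}

#' Normalize a dF/F trace to its maximum response amplitude
#'
#' Scales the trace so its maximum equals 1 (range 0-1 for non-negative
#' responses). Idempotent: normalizing an already-normalized trace is the
#' identity. An all-zero (or non-positive) trace is returned unchanged.
#'
#' @param dff dF/F trace.
#' @return Normalized trace.
#' @export
normalize_trace <- function(dff) {
  m <- max(dff)
  if (m <= 0) return(dff)
  dff / m
}

#' Extract a response profile from a processed trace
#'
#' For every stimulus event, the response peak amplitude is the maximum of
#' the normalized dF/F trace in the 15 s window from stimulus application
#' start (ties broken by the earliest frame), measured relative to the
#' mean dF/F level of the non-stimulus intervals: asymmetric baseline
#' smoothing leaves the corrected trace with a small positive offset
#' proportional to the noise level, and referencing peaks to the
#' non-stimulus level removes it. Amplitudes of repeated stimuli are
#' averaged per stimulus code. The baseline SD is the standard deviation
#' over the non-stimulus intervals of the whole stimulation sequence
#' (15 s windows starting 25 s after each onset), and per-code
#' signal-to-background ratios are attached.
#'
#' @param dff Normalized dF/F trace (see [normalize_trace()]).
#' @param protocol An [make_protocol()] object whose windows must lie
#'   inside the trace.
#' @param roi_id Optional identifier carried through.
#' @return Object of class `response_profile`: `amplitudes` (named vector
#'   over all stimulus codes seen), `panel_amplitudes` (the 8 single
#'   amino-acid entries), `baseline_sd`, `sbr` (named vector), `n_stimuli`,
#'   `roi_id`.
#' @export
extract_response_profile <- function(dff, protocol, roi_id = NA_character_) {
  if (length(dff) < protocol$n_frames) {
    stop("trace (", length(dff), " frames) shorter than protocol (",
         protocol$n_frames, " frames)")
  }
  ns_idx <- unlist(nonstim_windows(protocol))
  ns_idx <- ns_idx[ns_idx <= length(dff)]
  ns_mean <- if (length(ns_idx)) mean(dff[ns_idx]) else 0
  baseline_sd <- if (length(ns_idx) > 1) sd(dff[ns_idx]) else 0

  ev <- protocol$events
  peaks <- numeric(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    w <- response_window(protocol, ev$onset[k])
    peaks[k] <- max(dff[w]) - ns_mean
  }
  amplitudes <- tapply(peaks, ev$code, mean)
  amplitudes <- amplitudes[unique(ev$code)]

  sbr <- vapply(unique(ev$code), function(code) {
    compute_sbr(dff, protocol, code)
  }, numeric(1))

  structure(list(roi_id = roi_id,
                 amplitudes = amplitudes,
                 panel_amplitudes = amplitudes[intersect(protocol$panel,
                                                         names(amplitudes))],
                 baseline_sd = baseline_sd,
                 sbr = sbr,
                 n_stimuli = length(protocol$panel)),
            class = "response_profile")
}

#' Renormalize panel amplitudes to the strongest single amino-acid response
#'
#' Amplitude-vector analyses (correlation matrices, clustering, sparseness,
#' odor-space coordinates) use amplitudes normalized to the maximum response
#' among the eight single amino acids (range 0-1), whereas tuning-threshold
#' classification normalizes to the whole-series maximum including
#' mixtures. This helper converts the former from a profile extracted on a
#' whole-series-normalized trace.
#'
#' @param profile A `response_profile`.
#' @return Named numeric vector over the panel, maximum 1 (all zeros when
#'   the ROI never responded).
#' @export
panel_amplitude_vector <- function(profile) {
  r <- profile$panel_amplitudes
  r[r < 0] <- 0
  m <- max(r)
  if (m > 0) r / m else r
}

#' Apply the automatic ROI exclusion rules
#'
#' An ROI is kept iff (1) its spatial footprint is at least `min_area`
#' (default 25 um^2, from minimum observed glomerular diameters), (2) at
#' least one stimulus-evoked peak exceeds `sd_factor` (default 3) times the
#' SD of the non-stimulus response intervals, and (3) at least
#' `min_responses` (default 2, i.e. mix plus a single amino acid)
#' supra-threshold responses are present. The exclusion log lists every
#' violated rule per excluded ROI; ROIs carrying a manual exclusion flag
#' are removed last and logged separately.
#'
#' @param records List of `roi_record`s.
#' @param profiles List of matching `response_profile`s.
#' @param min_area Minimum footprint area, um^2.
#' @param sd_factor Peak threshold in units of non-stimulus-interval SD.
#' @param min_responses Minimum number of supra-threshold responses.
#' @return List with `kept` (indices into `records`), `records`,
#'   `profiles` (the kept subsets) and `log` (data.frame: roi_id, rule,
#'   detail).
#' @export
filter_rois <- function(records, profiles, min_area = 25, sd_factor = 3,
                        min_responses = 2) {
  if (length(records) != length(profiles)) {
    stop("records and profiles must match one-to-one")
  }
  log <- list()
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]; pr <- profiles[[i]]
    thr <- sd_factor * pr$baseline_sd
    n_supra <- sum(pr$amplitudes > thr)
    rules <- character(0)
    if (rec$footprint_area < min_area) {
      rules <- c(rules, sprintf("area %.1f um^2 < %g um^2",
                                rec$footprint_area, min_area))
    }
    if (!any(pr$amplitudes > thr)) {
      rules <- c(rules, sprintf("no peak > %g x non-stimulus SD", sd_factor))
    }
    if (n_supra < min_responses) {
      rules <- c(rules, sprintf("%d supra-threshold response(s) < %g",
                                n_supra, min_responses))
    }
    keep[i] <- length(rules) == 0L
    if (length(rules)) {
      log[[length(log) + 1L]] <- data.frame(
        roi_id = rec$roi_id, rule = rules, stage = "automatic")
    }
  }
  for (i in which(keep)) {
    if (isTRUE(records[[i]]$manual_flag)) {
      keep[i] <- FALSE
      log[[length(log) + 1L]] <- data.frame(
        roi_id = records[[i]]$roi_id, rule = "manual exclusion flag",
        stage = "manual")
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(roi_id = character(0), rule = character(0),
               stage = character(0))
  list(kept = which(keep), records = records[keep],
       profiles = profiles[keep], log = log)
}

#' Signal-to-background ratio of a stimulus response
#'
#' `SBR = (mean_s - mean_ns) / sqrt(0.5 * (var_s + var_ns))` where the
#' signal window is the 15 s after stimulus application and the background
#' windows are the 15 s non-stimulus intervals starting 25 s after each
#' onset. The pooled-SD radical makes the measure a discriminability index,
#' invariant under affine rescaling of the trace; `radical = FALSE`
#' switches to the plain non-radical denominator reading.
#'
#' @param dff dF/F trace.
#' @param protocol An [make_protocol()] object.
#' @param code Stimulus code with at least one event.
#' @param radical Use the square-root pooled denominator (default TRUE).
#' @return SBR value; `NaN` with a warning when the denominator vanishes
#'   while the window means differ.
#' @export
compute_sbr <- function(dff, protocol, code, radical = TRUE) {
  ev <- protocol$events[protocol$events$code == code, , drop = FALSE]
  if (!nrow(ev)) stop("no event with code '", code, "' in the protocol")
  sig <- unlist(lapply(ev$onset, function(on) {
    dff[response_window(protocol, on)]
  }))
  bg_idx <- unlist(nonstim_windows(protocol))
  bg_idx <- bg_idx[bg_idx <= length(dff)]
  if (!length(bg_idx)) stop("no non-stimulus interval inside the trace")
  sbr_from_samples(sig, dff[bg_idx], radical = radical)
}

#' @rdname compute_sbr
#' @param signal,background Sample vectors of the two interval populations.
#' @export
sbr_from_samples <- function(signal, background, radical = TRUE) {
  num <- mean(signal) - mean(background)
  v <- 0.5 * (pop_var(signal) + pop_var(background))
  den <- if (radical) sqrt(v) else v
  if (den == 0) {
    if (num == 0) return(0)
    warning("SBR undefined: zero denominator with unequal window means")
    return(NaN)
  }
  num / den
}

# population variance (denominator n), so single-sample windows are defined
pop_var <- function(x) mean((x - mean(x))^2)

#' Fluorescence intensity difference map
#'
#' Per pixel: mean of the peak frame within 8 s after stimulus onset and
#' its two neighbouring frames, minus the mean of the five frames covering
#' the 5 s before the stimulus. Neighbours falling outside the stack are
#' truncated and noted in the log. Used to visualize stimulus-evoked
#' activity in a qualitative manner.
#'
#' @param stack 3-d array (x, y, frame) or (x, y, frame) slices of a
#'   recording.
#' @param protocol An [make_protocol()] object.
#' @param code Stimulus code (first matching event is used unless `event`
#'   given).
#' @param event Optional event row index overriding `code`.
#' @return List with `map` (2-d matrix) and `log`.
#' @export
intensity_difference_map <- function(stack, protocol, code, event = NULL) {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be an x,y,frame array")
  k <- event %||% which(protocol$events$code == code)[1]
  if (is.na(k)) stop("no event with code '", code, "'")
  onset <- protocol$events$onset[k]
  fr <- protocol$frame_rate
  log <- character(0)

  post <- frames_in_window(protocol, onset, onset + 8)
  post <- post[post <= d[3]]
  if (!length(post)) stop("post-stimulus window outside the stack")
  # mean over frames of the global-mean peak frame and its two neighbours
  tser <- apply(stack[, , post, drop = FALSE], 3, mean)
  pk <- post[which.max(tser)]
  nb <- intersect((pk - 1):(pk + 1), intersect(post, seq_len(d[3])))
  if (length(nb) < 3) log <- c(log, "peak frame at window boundary; neighbours truncated")

  pre <- frames_in_window(protocol, onset - 5, onset)
  pre <- utils::tail(pre, 5)
  if (!length(pre)) stop("pre-stimulus window outside the stack")

  peak_img <- apply(stack[, , nb, drop = FALSE], c(1, 2), mean)
  base_img <- apply(stack[, , pre, drop = FALSE], c(1, 2), mean)
  list(map = peak_img - base_img, log = log)
}
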