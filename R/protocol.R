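#' Build a stimulus application protocol
#'
#' Constructs the acquisition protocol used by all analysis windows: a 15 s
#' lead-in recording, then stimuli applied for 5 s each at 1 min
#' inter-stimulus intervals. Each repeat (one "stimulus sequence") starts
#' with the all-odorant mixture followed by the single amino acids of the
#' panel; the single-stimulus order is shuffled per repeat when a seed is
#' given, mirroring the varied sequences used across recordings.
#'
#' @param panel Character vector of single-letter amino-acid codes
#'   (default [aa_panel()]).
#' @param repeats Number of stimulus sequences; every single stimulus occurs
#'   once per repeat.
#' @param frame_rate Acquisition rate in Hz; volumetric recordings run at
#'   0.25-2 Hz (default 1).
#' @param pre_record Lead-in recording before the first stimulus, s.
#' @param inter_stimulus Spacing between consecutive stimulus onsets, s
#'   (default 60, chosen to avoid desensitization).
#' @param stim_duration Odorant application time, s (default 5).
#' @param mixture_code Lowercase code of the mixture opening each sequence
#'   (default `"o"`, the all-odorant mix).
#' @param final_mix Append one closing mixture application after the last
#'   sequence.
#' @param shuffle Shuffle single-stimulus order within each repeat.
#' @param seed Integer seed controlling the shuffle; identical seeds give
#'   byte-identical protocols.
#'
#' @return An object of class `acq_protocol`: a list with `events`
#'   (data.frame of `code`, `onset`, `duration`), `frame_rate`,
#'   `pre_record`, `inter_stimulus`, `n_frames`, and `times` (frame time
#'   stamps in s).
#' @export
#' @examples
#' p <- make_protocol(repeats = 1, seed = 1)
#' nrow(p$events)  # 9: mixture + 8 single amino acids
make_protocol <- function(panel = aa_panel(), repeats = 1L, frame_rate = 1,
                          pre_record = 15, inter_stimulus = 60,
                          stim_duration = 5, mixture_code = "o",
                          final_mix = FALSE, shuffle = TRUE, seed = NULL) {
  if (length(panel) < 1L) stop("panel must contain at least one stimulus")
  if (!is.numeric(frame_rate) || frame_rate < 0.25 || frame_rate > 2) {
    stop("frame_rate must lie in [0.25, 2] Hz, got ", frame_rate)
  }
  if (repeats < 1L) stop("repeats must be >= 1")
  if (stim_duration <= 0) stop("stim_duration must be > 0")
  local_rng(seed)

  codes <- character(0)
  for (r in seq_len(repeats)) {
    ord <- if (shuffle) sample.int(length(panel)) else seq_along(panel)
    codes <- c(codes, mixture_code, panel[ord])
  }
  if (final_mix) codes <- c(codes, mixture_code)

  onsets <- pre_record + inter_stimulus * (seq_along(codes) - 1L)
  events <- data.frame(code = codes, onset = onsets,
                       duration = stim_duration, stringsAsFactors = FALSE)

  # cover the last event's full inter-stimulus window
  total_t <- onsets[length(onsets)] + inter_stimulus
  n_frames <- as.integer(ceiling(total_t * frame_rate)) + 1L
  times <- (seq_len(n_frames) - 1L) / frame_rate

  structure(list(events = events, frame_rate = frame_rate,
                 pre_record = pre_record, inter_stimulus = inter_stimulus,
                 stim_duration = stim_duration, n_frames = n_frames,
                 times = times, panel = panel, mixture_code = mixture_code),
            class = "acq_protocol")
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("Acquisition protocol: ", nrow(x$events), " stimulus events, ",
      x$frame_rate, " Hz, ", x$n_frames, " frames (",
      round(x$times[x$n_frames] / 60, 1), " min)\n", sep = "")
  cat("  sequence:", paste(x$events$code, collapse = " "), "\n")
  invisible(x)
}

# Frame indices (1-based) whose time stamps fall in [from, to).
frames_in_window <- function(protocol, from, to) {
  which(protocol$times >= from & protocol$times < to)
}

# Response window: 15 s from stimulus application start.
response_window <- function(protocol, onset, length_s = 15) {
  w <- frames_in_window(protocol, onset, onset + length_s)
  if (!length(w) || max(w) > protocol$n_frames) {
    stop("response window at onset ", onset, " s exceeds the trace")
  }
  w
}

# Non-stimulus intervals: one 15 s interval per event, starting 25 s after
# stimulus onset, clipped to the end of the trace.
nonstim_windows <- function(protocol, start_after = 25, length_s = 15) {
  lapply(protocol$events$onset, function(on) {
    frames_in_window(protocol, on + start_after, on + start_after + length_s)
  })
}

# Apply a generator seed; NULL leaves the current RNG stream untouched.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
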