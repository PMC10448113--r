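# Shared fixture builders (all generated in code; nothing on disk).

# A minimal response profile with chosen amplitudes and baseline SD.
fixture_profile <- function(amplitudes, baseline_sd = 0.1,
                            roi_id = "roi1") {
  amps <- setNames(rep(0, 8), aa_panel())
  amps[names(amplitudes)] <- amplitudes
  structure(list(roi_id = roi_id, amplitudes = amps,
                 panel_amplitudes = amps, baseline_sd = baseline_sd,
                 sbr = amps, n_stimuli = 8),
            class = "response_profile")
}

# A minimal ROI record.
fixture_record <- function(roi_id = "roi1", area = 50,
                           centroid = c(0.5, 0.5, 0.5), trace = rep(1, 10),
                           manual_flag = FALSE) {
  structure(list(roi_id = roi_id, level = "glomerular_input",
                 footprint_area = area, centroid = centroid,
                 raw_trace = trace, manual_flag = manual_flag),
            class = "roi_record")
}

# Profiles for a set of ROIs from simulated data, returning everything
# needed downstream.
fixture_processed_dataset <- function(n_rois = 40, snr = 20, seed = 42,
                                      layout = "random", ...) {
  protocol <- make_protocol(repeats = 2, seed = seed)
  ds <- simulate_roi_dataset(n_rois, protocol, snr = snr, seed = seed + 1,
                             layout = layout, ...)
  profiles <- lapply(ds$records, function(r) {
    dff <- normalize_trace(correct_baseline(r$raw_trace)$dff)
    extract_response_profile(dff, protocol, roi_id = r$roi_id)
  })
  list(dataset = ds, protocol = protocol, profiles = profiles,
       classifications = lapply(profiles, classify_tuning))
}

# Small molecule fixtures for chem tests.
mol_methane <- function() molecule_graph(c(C1 = "C"), list())
mol_ethane <- function() {
  molecule_graph(c(C1 = "C", C2 = "C"), list(c("C1", "C2", 1)))
}
mol_propane <- function() {
  molecule_graph(c(C1 = "C", C2 = "C", C3 = "C"),
                 list(c("C1", "C2", 1), c("C2", "C3", 1)))
}
mol_ethanol <- function() {
  molecule_graph(c(C1 = "C", C2 = "C", O1 = "O"),
                 list(c("C1", "C2", 1), c("C2", "O1", 1)))
}
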