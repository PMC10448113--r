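#' Default pipeline configuration
#'
#' All thresholds of the analysis in one serializable list: ROI filtering
#' (25 um^2 area floor, 3x SD peak rule, 2 responses), tuning thresholds
#' (2x/3x baseline SD), ALS baseline parameters, tuft detection (15 um,
#' 5 points), the 2:1 color ratio, and the synthetic-data settings.
#'
#' @param seed Root seed; every stage derives its own stream from it.
#' @param out_dir Output directory (NULL: nothing is written).
#' @param ... Overrides for any default entry.
#' @return Named list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    n_rois = 200L, snr = 10, layout = "random", repeats = 2L,
    n_animals = 4L, untuned_fraction = 0.05, small_area_fraction = 0.05,
    min_area = 25, sd_factor = 3, min_responses = 2,
    default_factor = 2, dominant_factor = 3,
    als_lambda = 1e4, als_p = 0.01,
    eps = 15, min_points = 5, n_trees = 10L,
    color_ratio = 2, min_intensity = 0,
    axes = list(c("R", "W"), c("K", "H"), c("M", "I")),
    stages = c("simulate", "process", "tuning", "chemsim", "spatial",
               "morpho", "color"))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Validate pipeline input files
#'
#' Checks that an ROI dataset (CSV + JSON sidecar) and/or SWC
#' reconstructions are structurally sound before analysis: schema columns
#' present, trace lengths matching the protocol, trees acyclic with a
#' single root. Failures name the offending record.
#'
#' @param roi_stem Optional path stem of a dataset written by
#'   [write_roi_dataset()].
#' @param swc_paths Optional character vector of SWC files.
#' @return List with `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(roi_stem = NULL, swc_paths = NULL) {
  problems <- character(0)
  if (!is.null(roi_stem)) {
    ds <- tryCatch(read_roi_dataset(roi_stem), error = function(e) {
      problems <<- c(problems, paste("dataset unreadable:",
                                     conditionMessage(e)))
      NULL
    })
    if (!is.null(ds)) {
      for (r in ds$records) {
        if (length(r$raw_trace) != ds$protocol$n_frames) {
          problems <- c(problems, sprintf(
            "ROI %s: trace length %d != protocol %d frames",
            r$roi_id, length(r$raw_trace), ds$protocol$n_frames))
        }
        if (!is.finite(r$footprint_area) || r$footprint_area <= 0) {
          problems <- c(problems,
                        sprintf("ROI %s: invalid footprint area", r$roi_id))
        }
      }
    }
  }
  for (p in swc_paths %||% character(0)) {
    err <- tryCatch({ read_swc(p); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) problems <- c(problems, paste0(p, ": ", err))
  }
  list(ok = !length(problems), problems = problems)
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in dependency order on synthetic data:
#' simulate ROI recordings, process traces (ALS baseline, dF/F, response
#' profiles, automatic filtering), classify tuning and compute sparseness
#' and stimulus clustering, score molecular similarity and regress cluster
#' distances on it, run the spatial chemotopy tests, analyze simulated
#' MTC reconstructions, and classify a multicolor projection volume.
#' Per-stage logs count every filter boundary. With `out_dir` set, tables
#' are written as CSV and the report as JSON.
#'
#' @param config A [pipeline_config()] list.
#' @return List of per-stage results plus `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  res <- list(config = config)
  log <- list()
  stages <- config$stages
  stage_seed <- function(i) (config$seed * 101L + i * 7919L) %% .Machine$integer.max

  if ("simulate" %in% stages) {
    protocol <- make_protocol(repeats = config$repeats, seed = stage_seed(1))
    res$dataset <- simulate_roi_dataset(
      config$n_rois, protocol, snr = config$snr, seed = stage_seed(2),
      layout = config$layout,
      untuned_fraction = config$untuned_fraction,
      small_area_fraction = config$small_area_fraction)
    log$simulate <- sprintf("simulated %d ROIs (%d frames, snr %g)",
                            config$n_rois, protocol$n_frames, config$snr)
  }

  if ("process" %in% stages) {
    ds <- res$dataset %||% stop("process stage needs the simulate stage ",
                                "(or a dataset loaded beforehand)")
    profs <- lapply(ds$records, function(r) {
      dff <- normalize_trace(correct_baseline(r$raw_trace,
                                              lambda = config$als_lambda,
                                              p = config$als_p)$dff)
      extract_response_profile(dff, ds$protocol, roi_id = r$roi_id)
    })
    flt <- filter_rois(ds$records, profs, min_area = config$min_area,
                       sd_factor = config$sd_factor,
                       min_responses = config$min_responses)
    res$profiles <- flt$profiles
    res$filter <- flt
    log$process <- sprintf("ROIs in: %d, kept: %d, excluded: %d",
                           length(ds$records), length(flt$kept),
                           length(ds$records) - length(flt$kept))
  }

  if ("tuning" %in% stages) {
    prof <- res$profiles %||% stop("tuning stage needs processed profiles")
    res$classifications <- lapply(prof, classify_tuning,
                                  default_factor = config$default_factor,
                                  dominant_factor = config$dominant_factor)
    amp <- amplitude_matrix(prof)
    responsive <- rowSums(amp) > 0
    res$sparseness <- apply(amp[responsive, , drop = FALSE], 1,
                            lifetime_sparseness)
    res$cluster <- stimulus_cluster(prof)
    res$broadness <- tuning_broadness(res$classifications)
    log$tuning <- sprintf("classified %d ROIs; %d responsive",
                          length(prof), sum(responsive))
  }

  if ("chemsim" %in% stages) {
    mols <- aa_molecules()
    res$similarity <- list(mcs = similarity_matrix(mols, "mcs"),
                           ap = similarity_matrix(mols, "ap"))
    if (!is.null(res$cluster)) {
      res$structure_regression <- list(
        mcs = cluster_distance_vs_similarity(res$cluster$cluster_distance,
                                             res$similarity$mcs),
        ap = cluster_distance_vs_similarity(res$cluster$cluster_distance,
                                            res$similarity$ap))
    }
    log$chemsim <- "similarity matrices computed (mcs, ap)"
  }

  if ("spatial" %in% stages) {
    ds <- res$dataset; cls <- res$classifications
    if (!is.null(ds) && !is.null(cls)) {
      pos <- do.call(rbind, lapply(res$filter$records,
                                   function(r) r$centroid))
      terr <- species_territories(pos, cls)
      res$territories <- terr
      if (nrow(terr) >= 2) {
        res$intercentroid <- intercentroid_distances(terr)
        res$compound_deviation <- compound_centroid_deviation(terr)
      }
      res$shared_tuning <- shared_tuning_distance(pos, cls)
      log$spatial <- sprintf("%d species territories", nrow(terr))
    }
  }

  if ("morpho" %in% stages) {
    trees <- lapply(seq_len(config$n_trees), function(i) {
      simulate_neuron_tree(sample(1:3, 1), seed = stage_seed(100 + i))
    })
    feats <- do.call(rbind, lapply(trees, extract_features,
                                   eps = config$eps,
                                   min_points = config$min_points))
    res$trees <- trees
    res$morpho_features <- feats
    res$morpho_pca <- population_pca(feats)
    res$tuft_distribution <- classify_tuft_count_distribution(
      feats[, "n_tufts"])
    log$morpho <- sprintf("%d trees analyzed", length(trees))
  }

  if ("color" %in% stages) {
    blobs <- data.frame(x = c(10, 30, 10, 30), y = c(10, 30, 12, 28),
                        z = c(8, 8, 24, 24), channel = c(1, 2, 1, 2),
                        intensity = 100,
                        region = c("GL", "GL", "MCL", "MCL"))
    vol <- simulate_channel_volume(c(40, 40, 32), blobs, noise_sd = 1,
                                   seed = stage_seed(200))
    cls <- classify_voxels(vol, ratio = config$color_ratio,
                           min_intensity = config$min_intensity)
    res$color <- list(volume = vol, classification = cls,
                      distributions = layer_distributions(cls),
                      correspondence = layer_correspondence(cls))
    log$color <- "projection volume classified"
  }

  res$log <- log
  if (!is.null(config$out_dir)) write_pipeline_report(res, config$out_dir)
  res
}

# serialize the main tables of a pipeline run
write_pipeline_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.csv(df, file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(res$territories)) w(res$territories, "territories")
  if (!is.null(res$filter)) w(res$filter$log, "exclusion_log")
  if (!is.null(res$classifications)) {
    w(data.frame(
      roi_id = vapply(res$classifications, `[[`, "", "roi_id"),
      default = vapply(res$classifications, `[[`, "", "default_label"),
      dominant = vapply(res$classifications, `[[`, "", "dominant_label")),
      "classifications")
  }
  if (!is.null(res$morpho_features)) {
    w(as.data.frame(res$morpho_features), "morpho_features")
  }
  report <- list(
    config = res$config[setdiff(names(res$config), "out_dir")],
    log = res$log,
    sparseness_median = if (!is.null(res$sparseness))
      median(res$sparseness),
    structure_regression = if (!is.null(res$structure_regression)) list(
      mcs = res$structure_regression$mcs[c("slope", "r_squared", "p")],
      ap = res$structure_regression$ap[c("slope", "r_squared", "p")]))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
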