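#' Simulate a 3-channel voxel volume with colored blobs
#'
#' Emulates a multicolor dye-injection stack: Gaussian intensity blobs on a
#' zero background, each assigned to one of the three color channels and to
#' a region (glomerular layer GL or mitral cell layer MCL), plus optional
#' Gaussian noise. The returned ground truth records each blob's dominant
#' channel, center and region for downstream checks of the color-ratio
#' classification.
#'
#' @param shape Integer vector of grid dimensions `c(nx, ny, nz)`.
#' @param blobs data.frame with columns `x`, `y`, `z` (voxel centers),
#'   `channel` (1, 2 or 3), `intensity` (> 0), optional `sigma` (voxel SD,
#'   default 2) and `region` (`"GL"` or `"MCL"`, default `"GL"`). An empty
#'   data.frame yields an all-zero volume.
#' @param noise_sd Additive Gaussian noise SD.
#' @param bleed Fractional intensity leaked into the two other channels
#'   (default 0.1; keeps the blob classifiable at a 2:1 ratio).
#' @param seed Integer seed.
#' @return List of class `channel_volume`: `intensity` (4-d array
#'   x,y,z,channel), `region` (character array, `"GL"`/`"MCL"`/`"other"`),
#'   `ground_truth` (the blob table).
#' @export
simulate_channel_volume <- function(shape, blobs = NULL, noise_sd = 0,
                                    bleed = 0.1, seed = NULL) {
  stopifnot(length(shape) == 3)
  local_rng(seed)
  vol <- array(0, dim = c(shape, 3L))
  region <- array("other", dim = shape)
  # default region split along z: lower half GL, upper half MCL
  zmid <- shape[3] / 2
  region[, , seq_len(floor(zmid))] <- "GL"
  region[, , (floor(zmid) + 1):shape[3]] <- "MCL"

  if (!is.null(blobs) && nrow(blobs)) {
    if (any(!blobs$channel %in% 1:3)) {
      stop("blob channel index must be 1, 2 or 3")
    }
    if (any(blobs$intensity < 0)) stop("blob intensities must be >= 0")
    if (is.null(blobs$sigma)) blobs$sigma <- 2
    if (is.null(blobs$region)) blobs$region <- "GL"
    ax <- lapply(shape, seq_len)
    for (b in seq_len(nrow(blobs))) {
      gx <- exp(-(ax[[1]] - blobs$x[b])^2 / (2 * blobs$sigma[b]^2))
      gy <- exp(-(ax[[2]] - blobs$y[b])^2 / (2 * blobs$sigma[b]^2))
      gz <- exp(-(ax[[3]] - blobs$z[b])^2 / (2 * blobs$sigma[b]^2))
      blob <- blobs$intensity[b] * (gx %o% gy %o% gz)
      for (ch in 1:3) {
        w <- if (ch == blobs$channel[b]) 1 else bleed
        vol[, , , ch] <- vol[, , , ch] + w * blob
      }
    }
  }
  if (noise_sd > 0) vol <- vol + array(abs(rnorm(length(vol), 0, noise_sd)),
                                       dim = dim(vol))
  structure(list(intensity = vol, region = region,
                 ground_truth = blobs %||% data.frame()),
            class = "channel_volume")
}

#' Classify voxels by the 2:1 dominant-color rule
#'
#' A voxel is assigned to a primary color channel iff that channel's
#' intensity is at least `ratio` times the intensity of *both* other
#' channels (ties at exactly 2:1 count as satisfying the rule) and reaches
#' `min_intensity`; otherwise it stays unclassified. For `ratio >= 1` at
#' most one channel can win, so the categories are exclusive.
#'
#' @param volume A `channel_volume` (or plain 4-d array x,y,z,channel).
#' @param ratio Required dominance ratio (default 2).
#' @param min_intensity Intensity floor below which voxels are never
#'   classified (default 0; the floor suppresses pure-noise voxels).
#' @return List of class `color_classification`: `category` (character
#'   array `"red"`/`"green"`/`"blue"`/`"unclassified"`), `region`
#'   (carried over), `counts` (table by category x region).
#' @export
classify_voxels <- function(volume, ratio = 2, min_intensity = 0) {
  arr <- if (inherits(volume, "channel_volume")) volume$intensity else volume
  if (length(dim(arr)) != 4 || dim(arr)[4] != 3) {
    stop("expected an x,y,z,channel array with 3 channels")
  }
  region <- if (inherits(volume, "channel_volume")) volume$region else
    array("other", dim = dim(arr)[1:3])
  cols <- c("red", "green", "blue")
  category <- array("unclassified", dim = dim(arr)[1:3])
  for (ch in 1:3) {
    others <- setdiff(1:3, ch)
    win <- (arr[, , , ch] >= ratio * arr[, , , others[1]]) &
           (arr[, , , ch] >= ratio * arr[, , , others[2]]) &
           (arr[, , , ch] >= min_intensity) &
           (arr[, , , ch] > 0)
    category[win] <- cols[ch]
  }
  counts <- table(category = factor(category, c(cols, "unclassified")),
                  region = factor(region, c("GL", "MCL", "other")))
  structure(list(category = category, region = region, counts = counts),
            class = "color_classification")
}

#' Spatial distributions of color categories per layer
#'
#' Summarizes, per color category and region (GL / MCL), the voxel
#' coordinate distributions along x, y and z (quartiles) and the x-y
#' centroid. Empty category-region combinations yield empty summaries and
#' are listed in the log.
#'
#' @param classification A [classify_voxels()] result.
#' @return List with `summary` (data.frame: category, region, n, per-axis
#'   quartiles), `coords` (list of coordinate matrices) and `log`.
#' @export
layer_distributions <- function(classification) {
  cols <- c("red", "green", "blue")
  regions <- c("GL", "MCL")
  out <- list(); coords <- list(); log <- character(0)
  for (cc in cols) for (rr in regions) {
    idx <- which(classification$category == cc & classification$region == rr,
                 arr.ind = TRUE)
    key <- paste(cc, rr, sep = "_")
    if (!nrow(idx)) {
      log <- c(log, paste0("empty category: ", key))
      next
    }
    coords[[key]] <- idx
    qs <- apply(idx, 2, quantile, probs = c(0.25, 0.5, 0.75))
    out[[key]] <- data.frame(
      category = cc, region = rr, n = nrow(idx),
      x_q1 = qs[1, 1], x_med = qs[2, 1], x_q3 = qs[3, 1],
      y_q1 = qs[1, 2], y_med = qs[2, 2], y_q3 = qs[3, 2],
      z_q1 = qs[1, 3], z_med = qs[2, 3], z_q3 = qs[3, 3])
  }
  list(summary = do.call(rbind, out), coords = coords, log = log)
}

#' Topological correspondence of colors between layers
#'
#' For each color present in both the glomerular and mitral cell layer,
#' computes the distance between the GL and MCL centroids of that color
#' (same-color offsets) and compares them with the offsets between
#' different colors across layers (cross-color offsets) by Mann-Whitney U.
#' Small same-color offsets indicate that somata and their glomerular
#' projections of one dye category colocalize laterally.
#'
#' Offsets are measured in the x-y plane (the axial z spacing separates
#' the two layers by construction).
#'
#' @param classification A [classify_voxels()] result.
#' @return List with `offsets` (data.frame: color_gl, color_mcl, offset,
#'   same), `test` (a `glomap_test` or NULL when fewer than two colors are
#'   present) and `log`.
#' @export
layer_correspondence <- function(classification) {
  cols <- c("red", "green", "blue")
  cent <- function(cc, rr) {
    idx <- which(classification$category == cc &
                 classification$region == rr, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    colMeans(idx)[1:2]
  }
  log <- character(0)
  gl <- lapply(setNames(cols, cols), cent, rr = "GL")
  mcl <- lapply(setNames(cols, cols), cent, rr = "MCL")
  have <- cols[!vapply(gl, is.null, TRUE) & !vapply(mcl, is.null, TRUE)]
  missing <- setdiff(cols, have)
  if (length(missing)) {
    log <- c(log, paste0("color missing in one layer, skipped: ",
                         paste(missing, collapse = ", ")))
  }
  if (!length(have)) {
    return(list(offsets = NULL, test = NULL, log = log))
  }
  rows <- list()
  for (a in have) for (b in have) {
    rows[[paste(a, b)]] <- data.frame(
      color_gl = a, color_mcl = b,
      offset = sqrt(sum((gl[[a]] - mcl[[b]])^2)),
      same = a == b)
  }
  offsets <- do.call(rbind, rows)
  test <- NULL
  if (length(have) >= 2) {
    test <- two_group(offsets$offset[offsets$same],
                      offsets$offset[!offsets$same])
  } else {
    log <- c(log, "single color present: cross-color comparison skipped")
  }
  list(offsets = offsets, test = test, log = log)
}
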