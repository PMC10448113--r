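test_that("ALS baseline fixes constant traces and follows drift", {
  # constant trace: baseline equals the constant, dF/F is zero
  cb <- correct_baseline(rep(100, 60))
  expect_equal(cb$baseline, rep(100, 60), tolerance = 1e-6)
  expect_equal(cb$dff, rep(0, 60), tolerance = 1e-8)

  # linear drift plus one planted transient (relative amplitude 0.5 of
  # the local baseline): recovered dF/F peak within 5%
  t <- 0:299
  drift <- 100 + 0.05 * t
  transient <- 0.5 * drift * exp(-pmax(t - 150, 0) / 4) * (t >= 150)
  cb <- correct_baseline(drift + transient)
  expect_equal(max(cb$dff), 0.5, tolerance = 0.05)

  expect_error(correct_baseline(c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10)),
               "non-finite")
  expect_error(correct_baseline(rep(1, 5)), "short")
  expect_error(correct_baseline(rep(-5, 20)), "non-positive")
})

test_that("large penalty drives the baseline to the stiff (linear) limit", {
  # the second-difference penalty leaves affine baselines unpenalized, so
  # the lambda -> Inf limit is the asymmetric-weighted straight-line fit
  set.seed(1)
  y <- 100 + rnorm(200, 0, 1)
  b <- als_baseline(y, lambda = 1e12)
  resid_line <- residuals(lm(b ~ seq_along(b)))
  expect_lt(max(abs(resid_line)), 1e-3)
  # and it sits at the asymmetric (low) side of the noise band
  expect_lt(mean(b), mean(y))
})

test_that("trace normalization is idempotent and bounded", {
  x <- c(0, 0.2, 0.8, 0.4)
  n1 <- normalize_trace(x)
  expect_equal(max(n1), 1)
  expect_identical(normalize_trace(n1), n1)
  expect_identical(normalize_trace(rep(0, 5)), rep(0, 5))
})

test_that("peak extraction averages repeats and ties break earliest", {
  p <- make_protocol(repeats = 2, seed = 1, shuffle = FALSE)
  dff <- rep(0, p$n_frames)
  on <- p$events$onset[p$events$code == "W"]
  dff[which(p$times >= on[1])[3]] <- 0.6
  dff[which(p$times >= on[2])[5]] <- 0.8
  pr <- extract_response_profile(dff, p)
  expect_equal(unname(pr$amplitudes["W"]), 0.7)
  # all-zero trace: all amplitudes and the baseline SD are zero
  pr0 <- extract_response_profile(rep(0, p$n_frames), p)
  expect_true(all(pr0$amplitudes == 0))
  expect_equal(pr0$baseline_sd, 0)
  # windows beyond the trace are named errors
  expect_error(extract_response_profile(rep(0, 10), p), "frames")
})

test_that("the three automatic exclusion rules act independently", {
  # fixture of 4 ROIs: small footprint / no supra-3SD peak / single
  # response / fully valid -> exactly the last one survives
  recs <- list(
    fixture_record("small", area = 20),
    fixture_record("weak", area = 50),
    fixture_record("single", area = 50),
    fixture_record("valid", area = 50))
  profs <- list(
    fixture_profile(c(o = 0.9, W = 0.8), 0.1, "small"),
    fixture_profile(c(W = 0.25), 0.1, "weak"),
    fixture_profile(c(W = 0.8), 0.1, "single"),
    fixture_profile(c(o = 0.9, W = 0.8), 0.1, "valid"))
  res <- filter_rois(recs, profs)
  expect_equal(res$kept, 4L)
  expect_setequal(unique(res$log$roi_id), c("small", "weak", "single"))
  expect_true(any(grepl("area", res$log$rule[res$log$roi_id == "small"])))
  expect_true(any(grepl("SD", res$log$rule[res$log$roi_id == "weak"])))
  expect_true(any(grepl("supra", res$log$rule[res$log$roi_id == "single"])))

  # vacuous thresholds keep everything
  res0 <- filter_rois(recs, profs, min_area = 0, sd_factor = 0,
                      min_responses = 0)
  expect_equal(res0$kept, 1:4)

  # kept-set size is monotone non-increasing in each threshold
  kept_n <- function(...) length(filter_rois(recs, profs, ...)$kept)
  expect_true(all(diff(sapply(c(0, 20, 25, 60),
                              function(a) kept_n(min_area = a))) <= 0))
  expect_true(all(diff(sapply(c(0, 2, 3, 10),
                              function(s) kept_n(sd_factor = s))) <= 0))
  expect_true(all(diff(sapply(0:3,
                              function(m) kept_n(min_responses = m))) <= 0))

  # manual flags are applied last and logged separately
  recs[[4]]$manual_flag <- TRUE
  resm <- filter_rois(recs, profs)
  expect_length(resm$kept, 0)
  expect_true("manual" %in% resm$log$stage)
})

test_that("noise-free planted responders survive filtering exactly", {
  p <- make_protocol(repeats = 2, seed = 3)
  ds <- simulate_roi_dataset(20, p, snr = 1e6, seed = 8,
                             untuned_fraction = 0.3,
                             small_area_fraction = 0)
  profs <- lapply(ds$records, function(r) {
    extract_response_profile(normalize_trace(correct_baseline(r$raw_trace)$dff),
                             p, roi_id = r$roi_id)
  })
  res <- filter_rois(ds$records, profs)
  responders <- which(nzchar(ds$ground_truth$label))
  expect_equal(res$kept, responders)
})

test_that("SBR matches its analytic cases and is scale invariant", {
  # equal means give 0; unit mean difference with unit variances gives 1
  a <- c(0, 1, 2); b <- c(2, 1, 0)
  expect_equal(sbr_from_samples(a, b), 0)
  sig <- c(0, 2); bg <- c(-1, 1)
  # mean(sig)=1, mean(bg)=0, population variances both 1
  expect_equal(sbr_from_samples(sig, bg), 1)
  # affine gain: scaling the trace scales numerator and denominator alike
  expect_equal(sbr_from_samples(3 * sig, 3 * bg), 1)
  p <- make_protocol(repeats = 1, seed = 2, shuffle = FALSE)
  dff <- rep(0, p$n_frames)
  on <- p$events$onset[p$events$code == "K"]
  w <- glomap:::response_window(p, on)
  dff[w] <- 0.5 * exp(-(seq_along(w) - 1) / 4)  # decaying transient
  s1 <- compute_sbr(dff, p, "K")
  s2 <- compute_sbr(2.5 * dff, p, "K")
  expect_equal(s1, s2)
  expect_gt(s1, 0)
  # degenerate: zero variances with unequal means
  expect_warning(v <- sbr_from_samples(c(1, 1), c(0, 0)), "undefined")
  expect_true(is.nan(v))
  expect_error(compute_sbr(dff, p, "zz"), "no event")
})

test_that("SBR grows with the window-mean difference at fixed variances", {
  bg <- rnorm(50)
  bg <- (bg - mean(bg)) / sd(bg)
  deltas <- c(0.2, 0.5, 1, 2)
  vals <- vapply(deltas, function(d) sbr_from_samples(bg + d, bg),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("intensity difference maps isolate responding pixels", {
  p <- make_protocol(repeats = 1, seed = 1, shuffle = FALSE)
  stack <- array(10, dim = c(4, 4, p$n_frames))
  # constant stack: zero map
  m0 <- intensity_difference_map(stack, p, "M")
  expect_true(all(m0$map == 0))
  # one pixel steps 10 -> 20 at onset: value 10 there, 0 elsewhere
  on <- p$events$onset[p$events$code == "M"]
  stack[2, 3, p$times >= on] <- 20
  m1 <- intensity_difference_map(stack, p, "M")
  expect_equal(m1$map[2, 3], 10)
  expect_true(all(m1$map[-c(4 * 2 + 2)] %in% c(0, 10)))
  expect_equal(sum(m1$map != 0), 1)
})
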