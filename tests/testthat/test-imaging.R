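# Synthetic stack generator and the image-analysis pipeline.

states_small <- model_states(times = default_times(6), n_cells = 400)

test_that("stack synthesis is deterministic and renders the profile faithfully", {
  opt <- clean_optics()
  s1 <- synthesize_stack(states_small, opt, seed = 11)
  s2 <- synthesize_stack(states_small, opt, seed = 11)
  expect_identical(s1$frames, s2$frames)
  s3 <- synthesize_stack(states_small, noisy_optics(), seed = 12)
  expect_false(identical(s1$frames, s3$frames))

  # noise-free flat-background rendering: in-channel rows are an affine map
  # of the simulated profile
  truth <- attr(s1, "truth")
  fr <- s1$frames[[3]]
  mid_row <- fr[60, truth$inlet_col:ncol(fr)]
  expect_equal(mid_row, opt$base + opt$signal * truth$profiles[3, ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("photobleaching makes frame means strictly decrease", {
  # equal concentration in every frame isolates the bleaching decay
  base_state <- states_small[[1]]
  flat_states <- lapply(1:5, function(k) {
    st <- base_state
    st$time <- k
    st
  })
  stk <- synthesize_stack(flat_states, clean_optics(bleach_rate = 0.05),
                          seed = 1, n_main = 1)
  means <- vapply(stk$frames, mean, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("stack synthesis rejects out-of-bounds channel geometry", {
  expect_error(synthesize_stack(states_small,
                                clean_optics(n_rows = 50,
                                             channel_rows = c(30, 70))),
               "bounds")
})

test_that("channel sides and inlet are found within a pixel, clean and noisy", {
  for (opt in list(clean_optics(), noisy_optics())) {
    stk <- synthesize_stack(states_small, opt, seed = 5)
    truth <- attr(stk, "truth")
    det <- detect_channel(stk$frames[[1]])
    expect_lte(abs(det$side_low - truth$channel_rows[1]), 1)
    expect_lte(abs(det$side_high - truth$channel_rows[2]), 1)
    expect_lte(abs(det$inlet - truth$inlet_col), 1)
  }
})

test_that("detection is stable across the frames of one stack", {
  stk <- synthesize_stack(states_small, noisy_optics(), seed = 8)
  dets <- t(vapply(stk$frames, function(f) {
    d <- detect_channel(f)
    c(d$side_low, d$side_high, d$inlet)
  }, numeric(3)))
  expect_lte(diff(range(dets[, 1])), 1)
  expect_lte(diff(range(dets[, 2])), 1)
  expect_lte(diff(range(dets[, 3])), 1)
})

test_that("detection fails loudly on a featureless frame", {
  set.seed(1)
  flat <- matrix(0.1 + rnorm(120 * 200, 0, 1e-3), 120, 200)
  expect_error(detect_channel(flat), "detection failed")
})

test_that("flattening recovers a planted polynomial illumination", {
  opt <- optics_config(noise_sigma = 1e-4)
  stk <- synthesize_stack(states_small, opt, seed = 2)
  det <- detect_channel(stk$frames[[1]])
  fl <- flatten(stk$frames[[1]], det)
  expect_true(attr(fl, "flattened"))
  # outside the channel the flattened frame is constant 1 with no remaining
  # quadratic trend
  outside_rows <- c(1:(det$side_low - 3), (det$side_high + 3):nrow(fl))
  out <- fl[outside_rows, (ceiling(det$inlet) + 2):ncol(fl)]
  expect_lt(abs(mean(out) - 1), 1e-3)
  expect_lt(stats::sd(out), 5e-3)
})

test_that("an already-flat frame passes through flattening up to scale", {
  stk <- synthesize_stack(states_small, clean_optics(), seed = 2)
  det <- detect_channel(stk$frames[[1]])
  fl <- flatten(stk$frames[[1]], det)
  ratio <- fl / stk$frames[[1]]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("overwhelming protein brightness triggers the use-as-is fallback", {
  opt <- clean_optics(base = 0.005, signal = 5)  # channel 100x background
  stk <- synthesize_stack(states_small, opt, seed = 2)
  det <- detect_channel(stk$frames[[4]])
  fl <- flatten(stk$frames[[4]], det)
  expect_false(attr(fl, "flattened"))
  expect_true(attr(fl, "fallback"))
  expect_equal(unclass(fl)[, ], stk$frames[[4]], ignore_attr = TRUE)
})

test_that("profile extraction averages the channel center and ignores walls", {
  stk <- synthesize_stack(states_small, clean_optics(), seed = 3)
  truth <- attr(stk, "truth")
  det <- detect_channel(stk$frames[[4]])
  p <- extract_profile(stk$frames[[4]], det, stk$pixel_size,
                       time = stk$times[4])
  scale <- main_channel_reference(stk$frames[[4]], det)
  expect_lt(max(abs(p$intensity / scale - truth$profiles[4, ])), 1e-9)

  # corrupting the wall-adjacent rows does not change the profile
  fr2 <- stk$frames[[4]]
  fr2[det$side_low, ] <- 10
  fr2[det$side_high, ] <- 0
  p2 <- extract_profile(fr2, det, stk$pixel_size, time = stk$times[4])
  expect_equal(p2$intensity, p$intensity)

  # constant in-channel intensity gives a constant profile
  fr3 <- matrix(0.1, 120, 200)
  fr3[det$side_low:det$side_high, ] <- 0.7
  det3 <- det; det3$inlet <- 21
  p3 <- extract_profile(fr3, det3, 1e-6, background = NULL)
  expect_equal(diff(range(p3$intensity)), 0)

  # too narrow a central region errors
  det4 <- det; det4$side_high <- det$side_low + 3
  expect_error(extract_profile(stk$frames[[4]], det4, stk$pixel_size),
               "3 px")
})

test_that("repeated Savitzky-Golay smoothing preserves polynomials and kills noise", {
  x <- seq(0, 1, length.out = 201)
  const <- intensity_profile(x, rep(2, 201), 1)
  expect_equal(smooth_profile(const)$intensity, rep(2, 201))

  cubic <- intensity_profile(x, 1 + x - 2 * x^2 + 0.5 * x^3, 1)
  sm <- smooth_profile(cubic, window = 11, order = 3, passes = 3)
  inner <- 12:190  # ends are extrapolated by the filter
  expect_equal(sm$intensity[inner], cubic$intensity[inner], tolerance = 1e-10)

  set.seed(99)
  peak <- exp(-(x - 0.5)^2 / (2 * 0.05^2))
  noisy <- intensity_profile(x, peak + rnorm(201, 0, 0.05), 1)
  sm <- smooth_profile(noisy, window = 11, order = 3, passes = 3)
  expect_lt(abs(x[which.max(sm$intensity)] - x[which.max(peak)]),
            1.5 * diff(x)[1])
  expect_gt(stats::var(noisy$intensity - peak) /
              stats::var(sm$intensity[inner] - peak[inner]), 5)

  expect_error(smooth_profile(const, window = 10), "odd")
  expect_error(smooth_profile(const, window = 11, order = 11), "order")
})

test_that("normalization uses the late-frame median and is robust and idempotent", {
  x <- seq(0, 1e-4, length.out = 50)
  profs <- lapply(1:6, function(k) intensity_profile(x, rep(3, 50), k))
  refs <- rep(1.5, 6)
  nn <- normalize_stack(profs, refs)
  expect_equal(nn[[1]]$intensity, rep(2, 50))
  expect_true(all(vapply(nn, function(p) p$normalized, logical(1))))

  # one outlier frame among the last five does not move the median
  refs2 <- c(1.5, 1.5, 1.5, 1.5, 1.5, 50)
  n2 <- normalize_stack(profs, refs2)
  expect_equal(n2[[1]]$intensity, rep(2, 50))

  # idempotent given fixed references of 1
  n3 <- normalize_stack(nn, rep(1, 6))
  expect_equal(n3[[1]]$intensity, nn[[1]]$intensity)

  expect_error(normalize_stack(profs[1:4], refs[1:4]), "5 frames")
  expect_error(normalize_stack(profs, rep(0, 6)), "zero or negative")
})

test_that("noise-free end-to-end analysis reproduces the simulated field", {
  stk <- synthesize_stack(states_small, clean_optics(), seed = 4)
  truth <- attr(stk, "truth")
  profs <- analyze_stack(stk)
  errs <- vapply(seq_along(profs), function(k) {
    profile_truth_error(profs[[k]], truth, k)
  }, numeric(1))
  expect_lt(max(errs[-1]), 0.01)
  expect_lt(errs[1], 0.016)  # earliest frame: narrowest peak vs filter window
  meta <- attr(profs, "metadata")
  expect_false(any(meta$flatten_fallback))
})

test_that("the pipeline is deterministic given a stack", {
  stk <- synthesize_stack(states_small, noisy_optics(), seed = 6)
  p1 <- analyze_stack(stk)
  p2 <- analyze_stack(stk)
  expect_identical(lapply(p1, `[[`, "intensity"),
                   lapply(p2, `[[`, "intensity"))
})

test_that("stacks round-trip through TIFF with sidecar timestamps", {
  stk <- synthesize_stack(states_small[1:3], noisy_optics(), seed = 9)
  tf <- tempfile(fileext = ".tiff")
  write_stack(stk, tf)
  back <- read_stack(tf)
  expect_equal(back$times, stk$times)
  expect_equal(back$pixel_size, stk$pixel_size)
  for (k in 1:3) {
    expect_lt(max(abs(back$frames[[k]] - stk$frames[[k]])), 1e-6)
  }
})

test_that("profiles round-trip through CSV with metadata", {
  stk <- synthesize_stack(states_small, clean_optics(), seed = 4)
  profs <- analyze_stack(stk)
  csv <- tempfile(fileext = ".csv")
  write_profiles_csv(profs, csv)
  back <- read_profiles_csv(csv)
  expect_equal(length(back), length(profs))
  expect_equal(back[[2]]$intensity, profs[[2]]$intensity)
  meta <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_equal(meta$filter$window, 11)
})
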