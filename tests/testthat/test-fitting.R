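# Frame selection, masking, peak normalization, the nonlinear fit and the
# derived protein properties.

# model profile rendered as a normalized intensity profile at time t
model_profile <- function(t, d_p = bsa_like$d_p, gamma_p = bsa_like$gamma_p,
                          n_x = 400, length = 500e-6, noise = 0, seed = NULL) {
  prof <- solve_similarity(similarity_params(
    dp_ratio = d_p / d_s_licl, gamma_ratio = gamma_p / d_s_licl,
    alpha = 0.01))
  x <- seq(length / n_x / 2, length, length.out = n_x)
  y <- stats::approx(prof$eta, prof$n, eta_of(x, t, d_s_licl),
                     yleft = 1, yright = 0)$y
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(n_x, 0, noise)
  }
  intensity_profile(x, y, t, normalized = TRUE)
}

test_that("frame selection keeps peaked, quiet-tailed profiles only", {
  x <- seq(1e-6, 5e-4, length.out = 100)
  monotone <- intensity_profile(x, exp(-x / 1e-4), 1, normalized = TRUE)
  peaked <- model_profile(2)
  loud_tail <- intensity_profile(
    x, c(seq(1, 2, length.out = 20), seq(2, 1.1, length.out = 80)), 1,
    normalized = TRUE)
  sel <- select_frames(list(monotone, peaked, loud_tail))
  expect_length(sel, 1)
  rej <- attr(sel, "rejections")
  expect_match(rej[1], "no concentration peak")
  expect_true(is.na(rej[2]))
  expect_match(rej[3], "tail")
  expect_error(select_frames(list(monotone)), "no fittable frames")
})

test_that("the inlet-to-peak mask excludes exactly the indices up to the peak", {
  y <- c(1, 3, 2, 1.5, 1, 0.5, 0.2, 0.1)
  p <- intensity_profile(seq_along(y) * 1e-6, y, 1)
  m <- mask_inlet_to_peak(p)
  expect_equal(m, c(FALSE, FALSE, rep(TRUE, 6)))

  # deeper peak masks more points
  y2 <- c(1, 1.5, 2, 3, 2, 1, 0.5, 0.2)
  m2 <- mask_inlet_to_peak(intensity_profile(seq_along(y2) * 1e-6, y2, 1))
  expect_gt(sum(!m2), sum(!m))

  flat <- intensity_profile(seq_along(y) * 1e-6, rev(sort(y)), 1)
  expect_error(mask_inlet_to_peak(flat), "no concentration peak")
})

test_that("peak normalization rescales to unit height preserving shape", {
  p <- model_profile(2)
  pn <- normalize_by_peak(p)
  expect_equal(max(pn$intensity), 1)
  expect_equal(which.max(pn$intensity), which.max(p$intensity))
  expect_equal(pn$intensity * max(p$intensity), p$intensity)

  # profiles differing only by a scale factor collapse exactly
  p2 <- p
  p2$intensity <- 0.37 * p$intensity
  expect_equal(normalize_by_peak(p2)$intensity, pn$intensity)
})

test_that("noiseless model profiles are refit to the generating parameters", {
  profs <- lapply(c(1, 2, 4, 8), model_profile)
  fit <- fit_profiles(profs, licl)
  expect_lt(abs(fit$d_p - bsa_like$d_p) / bsa_like$d_p, 0.02)
  expect_lt(abs(fit$gamma_p - bsa_like$gamma_p) / bsa_like$gamma_p, 0.02)
  expect_true(fit$converged)
  expect_false(fit$at_boundary)
})

test_that("fit residuals on noisy model data sit at the injected noise level", {
  noise <- 0.02
  profs <- lapply(c(2, 4, 8), function(t) {
    model_profile(t, noise = noise, seed = 100 + t)
  })
  fit <- fit_profiles(profs, licl)
  # data are peak-normalized before fitting: so is the effective noise
  peak_h <- max(model_profile(2)$intensity)
  chi2_red <- mean(fit$residuals^2) / (noise / peak_h)^2
  expect_gt(chi2_red, 0.5)
  expect_lt(chi2_red, 2)
  expect_gt(fit$d_p_err, 0)
  expect_gt(fit$gamma_p_err, 0)
})

test_that("the inlet-side mask does not bias the fit on model data", {
  profs <- lapply(c(2, 4, 8), model_profile)
  fit_full <- fit_profiles(profs, licl)
  # drop the masked region from the data entirely: parameters should not move
  trimmed <- lapply(profs, function(p) {
    pk <- which.max(p$intensity)
    keep <- seq_along(p$x) >= pk - 1  # keep the peak and one flank point
    intensity_profile(p$x[keep], p$intensity[keep], p$time, normalized = TRUE)
  })
  fit_trim <- fit_profiles(trimmed, licl)
  expect_lt(abs(fit_trim$d_p - fit_full$d_p) / fit_full$d_p, 0.01)
  expect_lt(abs(fit_trim$gamma_p - fit_full$gamma_p) / fit_full$gamma_p, 0.01)
})

test_that("a single self-similar frame carries the full information", {
  one <- fit_profiles(list(model_profile(4)), licl)
  many <- fit_profiles(lapply(c(1, 2, 4, 8), model_profile), licl)
  expect_lt(abs(one$d_p - many$d_p) / many$d_p, 0.01)
  expect_lt(abs(one$gamma_p - many$gamma_p) / many$gamma_p, 0.01)
})

test_that("derived properties round-trip the forward computations", {
  cond <- solvent_conditions()
  mu_true <- -0.988e-8
  d_true <- diffusivity_from_radius(3.48e-9, cond)
  gamma_true <- gamma_electrophoretic(mu_true, licl, cond)
  expect_gt(gamma_true, 0)  # negative protein in LiCl is attracted

  props <- derive_properties(list(d_p = d_true, gamma_p = gamma_true),
                             licl, cond)
  expect_equal(props$mu_p, mu_true, tolerance = 1e-6)
  expect_equal(props$radius_h, 3.48e-9, tolerance = 1e-6)
  expect_equal(props$charge, charge_from_mobility(mu_true, d_true, cond),
               tolerance = 1e-6)
  expect_identical(derive_properties(list(d_p = 1e-10, gamma_p = 0),
                                     licl, cond)$charge, 0)
})

test_that("a weak-beta salt amplifies the inferred charge magnitude", {
  cond <- solvent_conditions()
  kcl <- builtin_salts("KCl")
  gamma_p <- 1.5e-10
  q_licl <- derive_properties(list(d_p = 5.9e-11, gamma_p = gamma_p),
                              licl, cond)$charge
  q_kcl <- derive_properties(list(d_p = 5.9e-11, gamma_p = gamma_p),
                             kcl, cond)$charge
  ratio <- abs(q_kcl / q_licl)
  expect_equal(ratio, abs(beta_coefficient(licl) / beta_coefficient(kcl)),
               tolerance = 1e-10)
  expect_gt(ratio, 15)
  expect_lt(ratio, 20)

  zero_beta <- salt("sym", 1e-9, 1e-9)
  expect_error(derive_properties(list(d_p = 5.9e-11, gamma_p = gamma_p),
                                 zero_beta, cond), "indeterminate")
})

test_that("fit configuration validates its inputs", {
  expect_error(fit_config(tail_fraction = 0), "tail_fraction")
  expect_error(fit_config(tail_threshold = -1), "threshold")
  expect_error(fit_profiles(list(), licl), "no profiles")
  raw <- model_profile(2)
  raw$normalized <- FALSE
  expect_error(fit_profiles(list(raw), licl), "normalized")
})
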