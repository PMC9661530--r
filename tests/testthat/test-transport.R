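# Similarity coordinate, salt profile and the protein boundary-value model.

test_that("similarity coordinate scales as x / sqrt(4 Ds t)", {
  # 100 um at 100 s with Ds = 1.37e-8: 1e-4 / 2.341e-3 = 0.0427
  expect_equal(eta_of(100e-6, 100, 1.37e-8), 0.0427, tolerance = 2e-3)
  expect_identical(eta_of(0, 10, 1e-8), 0)
  expect_equal(eta_of(1e-4, 4 * 25, 1e-8), eta_of(1e-4, 25, 1e-8) / 2)
  expect_error(eta_of(1e-4, 0, 1e-8), "positive")
  expect_error(eta_of(1e-4, 10, -1e-8), "positive")
})

test_that("salt profile is the erf solution with inlet value alpha", {
  expect_equal(salt_profile(0, 0.01), 0.01)
  # 0.01 + 0.99 * erf(2), erf(2) = 0.995322
  expect_equal(salt_profile(2, 0.01), 0.9954, tolerance = 1e-4)
  expect_true(all(salt_profile(seq(0, 6, 0.1), 1) == 1))
  eta <- seq(0, 6, 0.01)
  expect_true(all(diff(salt_profile(eta, 0.3)) >= 0))
  expect_error(salt_profile(1, 0), "alpha")
  expect_error(salt_profile(1, 1.5), "alpha")
})

test_that("log-gradient of the salt profile has the right value, sign and limits", {
  # (0.99 * 2/sqrt(pi)) / 0.01 = 111.71
  expect_equal(grad_ln_salt(0, 0.01), 111.7, tolerance = 1e-3)
  expect_true(all(grad_ln_salt(seq(0, 6, 0.1), 1) == 0))
  eta <- seq(0, 6, 0.05)
  g <- grad_ln_salt(eta, 0.01)
  expect_true(all(g > 0))
  expect_equal(which.max(g), 1L)  # maximal at the inlet
  expect_lt(grad_ln_salt(6, 0.01), 1e-12)
})

test_that("pure-diffusion similarity solutions match the closed form", {
  p1 <- solve_similarity(similarity_params(dp_ratio = 1, gamma_ratio = 0))
  keep <- p1$eta <= 4
  expect_lt(max(abs(p1$n[keep] - (1 - erf_base(p1$eta[keep])))), 1e-4)
  expect_equal(p1$n[1], 1)
  expect_equal(p1$n[length(p1$n)], 0)

  # slower protein: N = 1 - erf(eta * sqrt(Ds/Dp)); N(0.5) = 1 - erf(1)
  p2 <- solve_similarity(similarity_params(dp_ratio = 0.25, gamma_ratio = 0))
  expect_equal(stats::approx(p2$eta, p2$n, 0.5)$y, 0.1573, tolerance = 1e-3)
})

test_that("attractive drift focuses the protein into a strong interior peak", {
  params <- similarity_params(dp_ratio = bsa_like$d_p / d_s_licl,
                              gamma_ratio = bsa_like$gamma_p / d_s_licl,
                              alpha = 0.01)
  prof <- solve_similarity(params)
  pk <- peak_stats(prof)
  expect_false(is.null(pk))
  expect_gte(pk$height, 4)
  expect_true(all(prof$n >= 0))
})

test_that("repulsive drift suppresses entry below pure diffusion, no peak", {
  prof <- solve_similarity(similarity_params(
    dp_ratio = bsa_like$d_p / d_s_licl,
    gamma_ratio = -bsa_like$gamma_p / d_s_licl, alpha = 0.01))
  expect_null(peak_stats(prof))
  expect_equal(max(prof$n), 1)
  pure <- 1 - erf_base(prof$eta * sqrt(d_s_licl / bsa_like$d_p))
  expect_true(all(prof$n <= pure + 1e-9))
})

test_that("domain truncation beyond eta_max = 6 is immaterial", {
  for (cfg in list(c(1, 0), c(4.3e-3, 1.1e-2))) {
    p6 <- solve_similarity(similarity_params(cfg[1], cfg[2], 0.01,
                                             eta_max = 6, n_grid = 2001,
                                             mesh_ratio = 1))
    p12 <- solve_similarity(similarity_params(cfg[1], cfg[2], 0.01,
                                              eta_max = 12, n_grid = 4001,
                                              mesh_ratio = 1))
    gg <- seq(0, 4, by = 0.01)
    expect_lt(max(abs(stats::approx(p6$eta, p6$n, gg)$y -
                        stats::approx(p12$eta, p12$n, gg)$y)), 1e-6)
  }
})

test_that("peak width grows with the diffusivity ratio", {
  fwhm <- vapply(c(2e-3, 4e-3, 8e-3), function(dp) {
    peak_stats(solve_similarity(similarity_params(dp, 1.1e-2, 0.01)))$fwhm
  }, numeric(1))
  expect_true(all(diff(fwhm) > 0))
})

test_that("peak statistics return NULL for monotone profiles", {
  prof <- solve_similarity(similarity_params(1, 0, 0.01))
  expect_null(peak_stats(prof))
})

test_that("parameter sweep reproduces the qualitative optima and isolates errors", {
  base <- c(dp_ratio = unname(bsa_like$d_p / d_s_licl),
            gamma_ratio = unname(bsa_like$gamma_p / d_s_licl))
  grid <- data.frame(dp_ratio = base[["dp_ratio"]],
                     gamma_ratio = base[["gamma_ratio"]],
                     alpha = c(1e-3, 1e-2, 1e-1))
  sw <- sweep_effect_strength(grid)
  # deeper salt contrast focuses more; no peak at all counts as height 1
  heights <- ifelse(is.na(sw$height), 1, sw$height)
  expect_true(all(diff(heights) < 0))

  # one-point sweep agrees with the direct solve
  one <- sweep_effect_strength(grid[2, ])
  direct <- peak_stats(solve_similarity(do.call(similarity_params,
                                                as.list(grid[2, ]))))
  expect_equal(one$height, direct$height)

  # sign flip removes the peak; an invalid row errors without aborting
  grid2 <- data.frame(dp_ratio = c(base[["dp_ratio"]], -1),
                      gamma_ratio = c(-base[["gamma_ratio"]], 0.01),
                      alpha = 0.01)
  sw2 <- sweep_effect_strength(grid2)
  expect_true(is.na(sw2$height[1]) && is.na(sw2$error[1]))
  expect_match(sw2$error[2], "positive")

  # stronger attraction focuses more
  grid3 <- data.frame(dp_ratio = base[["dp_ratio"]],
                      gamma_ratio = base[["gamma_ratio"]] * c(0.5, 1, 2),
                      alpha = 0.01)
  sw3 <- sweep_effect_strength(grid3)
  expect_true(all(diff(sw3$height) > 0))
})

test_that("profiles export to CSV and JSON faithfully", {
  prof <- solve_similarity(similarity_params(1, 0, 0.01, n_grid = 101))
  csv <- tempfile(fileext = ".csv")
  write_profile_csv(prof, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$n, prof$n)
  js <- tempfile(fileext = ".json")
  write_profile_json(prof, js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$params$dp_ratio, 1)
  expect_equal(meta$n, prof$n)
})

test_that("similarity parameter validation and the alpha floor", {
  expect_error(similarity_params(-1), "positive")
  expect_error(similarity_params(1, n_grid = 10), "n_grid")
  expect_error(similarity_params(1, mesh_ratio = 1.1), "mesh_ratio")
  p <- similarity_params(1, alpha = 0)   # nominally salt-free main channel
  expect_equal(p$alpha, 1e-4)
})
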