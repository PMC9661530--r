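# Fitting normalized concentration profiles to the similarity model: frame
# selection, inlet-to-peak masking, peak normalization, bounded nonlinear
# least squares over (D_p, Gamma_p), and derivation of protein properties
# with first-order uncertainties.

#' Fit configuration
#'
#' @param tail_fraction Fraction of the channel length counted as the far
#'   tail; frames with significant fluorescence there violate the
#'   semi-infinite assumption and are dropped (default: the last fifth).
#' @param tail_threshold Tail mean above `tail_threshold * peak height`
#'   counts as significant.
#' @param alpha_mode `"fixed"` (from the salt concentrations, default) or
#'   `"fit"` (free within `alpha_bounds`).
#' @param alpha_bounds Bounds for a fitted alpha.
#' @param seed Integer seed for the multistart jitter.
#' @param n_starts Number of optimizer starts (best residual wins; ties go to
#'   the smaller |Gamma_p|).
#' @param model_n_grid Mesh size of the model BVP solves inside the fit.
#' @param normalize `"peak"` (fit peak-normalized shapes, default) or
#'   `"absolute"`.
#' @param log10_dp_bounds,log10_gamma_bounds Box bounds of the fit, log10 of
#'   m^2/s.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(tail_fraction = 0.2, tail_threshold = 0.1,
                       alpha_mode = c("fixed", "fit"),
                       alpha_bounds = c(1e-4, 1),
                       seed = 1, n_starts = 3, model_n_grid = 1001,
                       normalize = c("peak", "absolute"),
                       log10_dp_bounds = c(-12, -9),
                       log10_gamma_bounds = c(-11.5, -8.5)) {
  if (tail_fraction <= 0 || tail_fraction >= 1) {
    stop("tail_fraction must be in (0, 1)", call. = FALSE)
  }
  if (tail_threshold <= 0) stop("tail_threshold must be positive", call. = FALSE)
  structure(list(tail_fraction = tail_fraction,
                 tail_threshold = tail_threshold,
                 alpha_mode = match.arg(alpha_mode),
                 alpha_bounds = alpha_bounds,
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 model_n_grid = as.integer(model_n_grid),
                 normalize = match.arg(normalize),
                 log10_dp_bounds = log10_dp_bounds,
                 log10_gamma_bounds = log10_gamma_bounds),
            class = "fit_config")
}

# Interior maximum exceeding both neighbors and the inlet value; ties broken
# toward the inlet. Returns the index or NA.
.find_peak <- function(y) {
  n <- length(y)
  if (n < 3) return(NA_integer_)
  interior <- 2:(n - 1)
  is_max <- y[interior] >= y[interior - 1] & y[interior] >= y[interior + 1] &
    (y[interior] > y[interior - 1] | y[interior] > y[interior + 1])
  cand <- interior[is_max & y[interior] > y[1]]
  if (!length(cand)) return(NA_integer_)
  cand[which.max(y[cand] + 1e-12 * (n - cand))]  # ties: inlet-proximal
}

#' Select the fittable frames
#'
#' Keeps profiles that show a concentration peak (an interior maximum above
#' the inlet value) and whose mean intensity in the far tail of the channel
#' (last `tail_fraction`) stays below `tail_threshold` times the peak height:
#' fluorescence reaching the far end breaks the semi-infinite assumption of
#' the model.
#'
#' @param profiles List of normalized [intensity_profile].
#' @param config A [fit_config].
#' @return The selected sublist, with attribute `"rejections"` (per-frame
#'   reason, `NA` for kept frames). Raises an error listing the reasons if
#'   nothing survives.
#' @export
select_frames <- function(profiles, config = fit_config()) {
  reasons <- rep(NA_character_, length(profiles))
  keep <- logical(length(profiles))
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    pk <- .find_peak(p$intensity)
    if (is.na(pk)) {
      reasons[k] <- "no concentration peak"
      next
    }
    x_tail <- max(p$x) - config$tail_fraction * diff(range(p$x))
    tail_mean <- mean(p$intensity[p$x > x_tail])
    if (tail_mean > config$tail_threshold * p$intensity[pk]) {
      reasons[k] <- sprintf("significant tail fluorescence (%.3g of peak)",
                            tail_mean / p$intensity[pk])
      next
    }
    keep[k] <- TRUE
  }
  if (!any(keep)) {
    stop("no fittable frames:\n",
         paste(sprintf("  frame %d: %s", seq_along(profiles), reasons),
               collapse = "\n"), call. = FALSE)
  }
  out <- profiles[keep]
  attr(out, "rejections") <- reasons
  out
}

#' Mask the profile between the inlet and the peak
#'
#' Near the inlet the measured profiles sit above the semi-infinite model
#' (the main channel is not a perfect reservoir), so the fit ignores
#' everything from x = 0 up to and including the peak.
#'
#' @param profile An [intensity_profile] with a peak.
#' @return Logical vector, `TRUE` where the point enters the fit.
#' @export
mask_inlet_to_peak <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  pk <- .find_peak(profile$intensity)
  if (is.na(pk)) stop("profile has no concentration peak", call. = FALSE)
  mask <- rep(TRUE, length(profile$x))
  mask[1:pk] <- FALSE
  mask
}

#' Normalize a profile by its peak height
#'
#' Peak-normalized profiles of the same protein collapse onto one shape even
#' when the absolute peak height differs (e.g. through inlet depletion), so
#' the fit compares shapes.
#'
#' @param profile An [intensity_profile] with a positive peak.
#' @return The profile divided by its peak height (new peak height 1).
#' @export
normalize_by_peak <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  pk <- .find_peak(profile$intensity)
  if (is.na(pk)) stop("profile has no concentration peak", call. = FALSE)
  h <- profile$intensity[pk]
  if (h <= 0) stop("peak height is not positive", call. = FALSE)
  out <- profile
  out$intensity <- profile$intensity / h
  out
}

#' Fit profiles to the similarity model
#'
#' Maps every selected profile to the similarity coordinate (using the salt's
#' effective diffusivity), peak-normalizes data and model, masks the
#' inlet-to-peak region, and minimizes the summed squared residuals over
#' `(D_p, Gamma_p)` — parametrized in log10 — with bounded
#' Levenberg-Marquardt least squares and a seeded multistart. The peak
#' position constrains the diffusiophoretic mobility and the peak width the
#' diffusion coefficient.
#'
#' @param profiles List of normalized [intensity_profile] (typically from
#'   [select_frames()]).
#' @param s A [salt] object.
#' @param cond A [solvent_conditions].
#' @param config A [fit_config].
#' @return An object of class `fit_result`: fitted `d_p`, `gamma_p`
#'   (attractive-positive convention), 1-sigma uncertainties `d_p_err`,
#'   `gamma_p_err`, the log10-scale covariance, `frames_used` (times),
#'   `residual_norm`, per-frame residuals, convergence/boundary flags, and
#'   `derived` ([protein_properties] via [derive_properties()]).
#' @export
fit_profiles <- function(profiles, s, cond = solvent_conditions(),
                         config = fit_config()) {
  stopifnot(inherits(s, "salt"), inherits(cond, "solvent_conditions"))
  if (!length(profiles)) stop("no profiles to fit", call. = FALSE)
  if (!all(vapply(profiles, function(p) isTRUE(p$normalized), logical(1)))) {
    stop("profiles must be normalized before fitting", call. = FALSE)
  }
  d_s <- salt_diffusivity(s)
  alpha0 <- max(s$c_main / s$c_reservoir, 1e-4)

  prep <- lapply(profiles, function(p) {
    mask <- mask_inlet_to_peak(p)
    pn <- if (config$normalize == "peak") normalize_by_peak(p) else p
    list(eta = eta_of(p$x[mask], p$time, d_s),
         y = pn$intensity[mask], time = p$time)
  })
  eta_all <- unlist(lapply(prep, `[[`, "eta"))
  y_all <- unlist(lapply(prep, `[[`, "y"))
  n_obs <- length(y_all)
  fit_alpha <- config$alpha_mode == "fit"

  model_curve <- function(dp, gp, alpha) {
    prof <- solve_similarity(similarity_params(
      dp_ratio = dp / d_s, gamma_ratio = gp / d_s, alpha = alpha,
      n_grid = config$model_n_grid))
    m <- stats::approx(prof$eta, prof$n, eta_all, yleft = 1, yright = 0)$y
    if (config$normalize == "peak") m / max(prof$n) else m
  }
  residual_fn <- function(par) {
    m <- tryCatch(
      model_curve(10^par[1], 10^par[2], if (fit_alpha) par[3] else alpha0),
      error = function(e) NULL)
    if (is.null(m)) return(rep(1e3, n_obs))
    y_all - m
  }

  lower <- c(config$log10_dp_bounds[1], config$log10_gamma_bounds[1])
  upper <- c(config$log10_dp_bounds[2], config$log10_gamma_bounds[2])
  if (fit_alpha) {
    lower <- c(lower, config$alpha_bounds[1])
    upper <- c(upper, config$alpha_bounds[2])
  }
  center <- c(mean(config$log10_dp_bounds), mean(config$log10_gamma_bounds))
  if (fit_alpha) center <- c(center, alpha0)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  starts <- lapply(seq_len(config$n_starts), function(i) {
    if (i == 1) return(center)
    pmin(pmax(center + stats::runif(length(center), -0.8, 0.8) *
                c(1, 1, 0.1)[seq_along(center)], lower), upper)
  })

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance - 1e-12 ||
        (abs(res$deviance - best$deviance) <= 1e-12 &&
         abs(res$par[2]) < abs(best$par[2]))) {
      best <- res
    }
  }
  if (is.null(best)) stop("optimizer failed on every start", call. = FALSE)

  par <- best$par
  d_p <- 10^par[1]
  gamma_p <- 10^par[2]
  at_boundary <- any(abs(par - lower) < 1e-6) || any(abs(par - upper) < 1e-6)
  converged <- best$info %in% 1:4

  dof <- max(n_obs - length(par), 1)
  sigma2 <- best$deviance / dof
  cov_log10 <- tryCatch(sigma2 * solve(best$hessian),
                        error = function(e) matrix(NA_real_, length(par), length(par)))
  d_p_err <- log(10) * d_p * sqrt(cov_log10[1, 1])
  gamma_p_err <- log(10) * gamma_p * sqrt(cov_log10[2, 2])

  result <- structure(list(
    d_p = d_p, gamma_p = gamma_p,
    d_p_err = d_p_err, gamma_p_err = gamma_p_err,
    cov_log10 = cov_log10[1:2, 1:2, drop = FALSE],
    alpha = if (fit_alpha) par[3] else alpha0,
    frames_used = vapply(prep, `[[`, numeric(1), "time"),
    residual_norm = sqrt(best$deviance),
    rms = sqrt(best$deviance / n_obs),
    n_obs = n_obs,
    residuals = best$fvec,
    converged = converged, at_boundary = at_boundary,
    settings = config), class = "fit_result")
  if (!converged) {
    warning("optimizer did not report convergence; best-so-far parameters returned",
            call. = FALSE)
  }
  result$derived <- derive_properties(result, s, cond)
  result
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  cat(sprintf("  D_p     = %.4g +/- %.2g m^2/s\n", x$d_p, x$d_p_err))
  cat(sprintf("  Gamma_p = %.4g +/- %.2g m^2/s (attractive-positive)\n",
              x$gamma_p, x$gamma_p_err))
  cat(sprintf("  %d frames, %d points, rms residual %.3g%s%s\n",
              length(x$frames_used), x$n_obs, x$rms,
              if (x$at_boundary) ", AT BOUNDS" else "",
              if (!x$converged) ", NOT CONVERGED" else ""))
  if (!is.null(x$derived)) print(x$derived)
  invisible(x)
}

#' Derive protein properties from a fit
#'
#' Assuming the electrophoretic contribution dominates diffusiophoresis, the
#' fitted pair (D_p, Gamma_p) yields the hydrodynamic radius (Stokes-Einstein
#' from D_p), the electrophoretic mobility (Gamma_p inverted through the
#' ambipolar-field coupling) and the effective charge (Einstein relation).
#' Uncertainties are first-order, using the log-scale fit covariance when
#' available.
#'
#' @param result A `fit_result`, or a list with `d_p`, `gamma_p` (and
#'   optionally `d_p_err`, `gamma_p_err`, `cov_log10`).
#' @param s A [salt] object; its beta must be nonzero.
#' @param cond A [solvent_conditions].
#' @return A [protein_properties] with an `errors` attribute (named 1-sigma
#'   uncertainties for `radius_h`, `mu_p`, `charge`).
#' @export
derive_properties <- function(result, s, cond = solvent_conditions()) {
  stopifnot(inherits(s, "salt"))
  if (beta_coefficient(s) == 0) {
    stop("beta = 0: charge indeterminate (no ambipolar field)", call. = FALSE)
  }
  d_p <- result$d_p
  gamma_p <- result$gamma_p
  radius_h <- stokes_einstein_radius(d_p, cond)
  mu_p <- mobility_from_gamma(gamma_p, s, cond)
  charge <- charge_from_mobility(mu_p, d_p, cond)
  zeta <- mu_p * cond$viscosity / cond$permittivity

  d_err <- if (!is.null(result$d_p_err)) result$d_p_err else NA_real_
  g_err <- if (!is.null(result$gamma_p_err)) result$gamma_p_err else NA_real_
  rel_d <- d_err / d_p
  rel_g <- g_err / abs(gamma_p)
  # q = gamma Z e / (beta d_p): relative variance combines both, with the
  # fitted covariance when present
  cov_dg <- if (!is.null(result$cov_log10)) {
    log(10)^2 * result$cov_log10[1, 2]
  } else 0
  rel_q <- sqrt(rel_g^2 + rel_d^2 - 2 * cov_dg)
  props <- protein_properties(d_p = d_p, gamma_p = gamma_p, mu_p = mu_p,
                              zeta = zeta, charge = charge,
                              radius_h = radius_h)
  attr(props, "errors") <- c(radius_h = abs(radius_h * rel_d),
                             mu_p = abs(mu_p * rel_g),
                             charge = abs(charge * rel_q))
  props
}

#' Export the fit as JSON and per-frame model curves as CSV
#'
#' @param result A `fit_result`.
#' @param profiles The fitted profiles (for the eta/data columns).
#' @param s The salt used in the fit.
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path of `(time_s, eta, data, model)` rows.
#' @return `json_path`, invisibly.
#' @export
write_fit_json <- function(result, profiles, s, json_path, csv_path = NULL) {
  stopifnot(inherits(result, "fit_result"))
  d_s <- salt_diffusivity(s)
  out <- list(
    d_p = result$d_p, gamma_p = result$gamma_p,
    d_p_err = result$d_p_err, gamma_p_err = result$gamma_p_err,
    alpha = result$alpha, frames_used = result$frames_used,
    residual_norm = result$residual_norm, rms = result$rms,
    n_obs = result$n_obs, converged = result$converged,
    at_boundary = result$at_boundary,
    derived = unclass(result$derived),
    derived_errors = as.list(attr(result$derived, "errors")),
    settings = unclass(result$settings))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    cfg <- result$settings
    prof <- solve_similarity(similarity_params(
      dp_ratio = result$d_p / d_s, gamma_ratio = result$gamma_p / d_s,
      alpha = result$alpha, n_grid = cfg$model_n_grid))
    peak_h <- max(prof$n)
    rows <- do.call(rbind, lapply(profiles, function(p) {
      mask <- mask_inlet_to_peak(p)
      pn <- if (cfg$normalize == "peak") normalize_by_peak(p) else p
      eta <- eta_of(p$x[mask], p$time, d_s)
      m <- stats::approx(prof$eta, prof$n, eta, yleft = 1, yright = 0)$y
      if (cfg$normalize == "peak") m <- m / peak_h
      data.frame(time_s = p$time, eta = eta, data = pn$intensity[mask],
                 model = m)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
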