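# One-dimensional finite-volume simulator of coupled salt and protein
# transport in the dead-end channel. Serves as the independent forward oracle
# for the similarity model and as the ground-truth source for synthetic image
# stacks. Method of lines: fluxes assembled per cell face, time integration by
# deSolve::ode.1D (banded stiff solver).

# Bernoulli function B(x) = x/(e^x - 1) of the Scharfetter-Gummel flux
.bernoulli <- function(x) {
  out <- ifelse(abs(x) < 1e-10, 1 - x / 2, x / expm1(x))
  out
}

#' Dead-end channel geometry
#'
#' Default dimensions follow the 50 x 50 x 500 um^3 dead-end channel of the
#' measurement device; only the length enters the 1D model, width and depth
#' are carried for imaging geometry.
#'
#' @param length Channel length, m.
#' @param width Channel width, m.
#' @param depth Channel depth, m.
#' @param n_cells Number of finite-volume cells (>= 100).
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(length = 500e-6, width = 50e-6, depth = 50e-6,
                             n_cells = 400) {
  if (length <= 0 || width <= 0 || depth <= 0) {
    stop("channel dimensions must be strictly positive", call. = FALSE)
  }
  if (n_cells < 100) stop("n_cells must be >= 100", call. = FALSE)
  structure(list(length = length, width = width, depth = depth,
                 n_cells = as.integer(n_cells)),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %g x %g x %g um^3, %d cells\n",
              x$length * 1e6, x$width * 1e6, x$depth * 1e6, x$n_cells))
  invisible(x)
}

#' Simulate coupled salt and protein transport in the dead-end channel
#'
#' Finite-volume forward model. The salt diffuses with the effective
#' diffusivity of the electrolyte; the protein carries the flux
#' `J = -D_p dN/dx + Gamma_p N d ln C / dx`, with the advective part upwinded
#' by the local drift direction. The inlet cell face is held at the
#' main-channel values (Dirichlet: `c_main`, `n_main`) and the closed end is
#' no-flux (Neumann). Time zero is the instant the main-channel solution
#' contacts the inlet; the dead-end initially holds salt at `c_reservoir` and
#' no protein.
#'
#' `ln C` is evaluated on concentrations floored at `alpha_floor * c_reservoir`
#' so the drift stays finite when the main channel is nominally salt-free.
#'
#' @param geometry A [channel_geometry].
#' @param s A [salt] object (sets D_s, c_reservoir, c_main).
#' @param protein List with `d_p` (m^2/s) and `gamma_p` (m^2/s,
#'   attractive-positive: drift up the salt gradient, into the dead-end).
#' @param n_main Relative protein concentration in the main channel.
#' @param save_times Strictly increasing positive times, s.
#' @param boundary `"dead_end"` (Dirichlet inlet + closed end, the device
#'   configuration) or `"closed"` (no-flux at both ends; conserves mass, used
#'   for conservation checks).
#' @param salt_init,protein_init Optional initial fields (length `n_cells`)
#'   overriding the uniform defaults (`c_reservoir` salt, zero protein).
#' @param alpha_floor Relative floor applied to the salt field inside `ln C`.
#' @param rtol,atol Integrator tolerances.
#' @return A list of `sim_state` objects (fields `x_centers`, `salt`,
#'   `protein`, `time`), one per save time.
#' @examples
#' \donttest{
#' geom <- channel_geometry(n_cells = 200)
#' st <- simulate_channel(geom, builtin_salts("LiCl"),
#'                        protein = list(d_p = 5.9e-11, gamma_p = 1.5e-10),
#'                        save_times = c(10, 30, 100))
#' st[[3]]
#' }
#' @export
simulate_channel <- function(geometry, s, protein, n_main = 1,
                             save_times, boundary = c("dead_end", "closed"),
                             alpha_floor = 1e-4,
                             salt_init = NULL, protein_init = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(geometry, "channel_geometry"), inherits(s, "salt"))
  boundary <- match.arg(boundary)
  if (!all(diff(c(0, save_times)) > 0)) {
    stop("save_times must be strictly increasing and positive", call. = FALSE)
  }
  if (is.null(protein$d_p) || protein$d_p <= 0) {
    stop("protein$d_p must be strictly positive", call. = FALSE)
  }
  gamma_p <- if (is.null(protein$gamma_p)) 0 else protein$gamma_p

  n <- geometry$n_cells
  dx <- geometry$length / n
  x <- (seq_len(n) - 0.5) * dx
  d_s <- salt_diffusivity(s)
  d_p <- protein$d_p
  c0 <- s$c_reservoir
  c_floor <- alpha_floor * c0
  c_main <- s$c_main
  dirichlet <- boundary == "dead_end"

  rhs <- function(t, y, parms) {
    C <- y[seq_len(n)]
    N <- y[n + seq_len(n)]
    # salt: pure diffusion; interior faces 2..n, inlet face half-cell
    fC <- numeric(n + 1)
    fC[2:n] <- -d_s * diff(C) / dx
    if (dirichlet) fC[1] <- -d_s * (C[1] - c_main) / (dx / 2)
    # protein flux by Scharfetter-Gummel exponential fitting: exact for
    # piecewise-constant drift, reduces to central diffusion at Pe -> 0 and
    # to upwinding at large Pe without the first-order smearing of the peak
    Cf <- pmax(C, c_floor)
    u <- numeric(n + 1)
    u[2:n] <- gamma_p * diff(log(Cf)) / dx
    fN <- numeric(n + 1)
    peclet <- u[2:n] * dx / d_p
    fN[2:n] <- d_p / dx *
      (.bernoulli(-peclet) * N[1:(n - 1)] - .bernoulli(peclet) * N[2:n])
    if (dirichlet) {
      h0 <- dx / 2
      u[1] <- gamma_p * (log(Cf[1]) - log(max(c_main, c_floor))) / h0
      pe0 <- u[1] * h0 / d_p
      fN[1] <- d_p / h0 *
        (.bernoulli(-pe0) * n_main - .bernoulli(pe0) * N[1])
    }
    list(c(-diff(fC) / dx, -diff(fN) / dx))
  }

  if (is.null(salt_init)) salt_init <- rep(c0, n)
  if (is.null(protein_init)) protein_init <- rep(0, n)
  stopifnot(length(salt_init) == n, length(protein_init) == n)
  y0 <- c(salt_init, protein_init)
  times <- c(0, save_times)
  sol <- deSolve::ode.1D(y = y0, times = times, func = rhs, parms = NULL,
                         nspec = 2, dimens = n, method = "lsoda",
                         rtol = rtol, atol = atol * max(c0, 1),
                         maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0) {
    stop("finite-volume integration failed (solver istate < 0)", call. = FALSE)
  }
  states <- lapply(seq_along(save_times), function(k) {
    row <- unname(sol[k + 1, -1])
    salt_field <- row[seq_len(n)]
    prot_field <- row[n + seq_len(n)]
    if (min(prot_field) < -1e-6 * max(abs(prot_field), 1) ||
        min(salt_field) < -1e-6 * c0) {
      stop(sprintf("negative concentration beyond tolerance at t = %g s",
                   save_times[k]), call. = FALSE)
    }
    structure(list(x_centers = x,
                   salt = pmax(salt_field, 0),
                   protein = pmax(prot_field, 0),
                   time = save_times[k]),
              class = "sim_state")
  })
  attr(states, "geometry") <- geometry
  attr(states, "salt") <- s
  attr(states, "protein") <- list(d_p = d_p, gamma_p = gamma_p)
  attr(states, "n_main") <- n_main
  states
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> t = %g s, %d cells; salt in [%.3g, %.3g], protein max %.3g\n",
              x$time, length(x$x_centers), min(x$salt), max(x$salt),
              max(x$protein)))
  invisible(x)
}

#' Re-express a simulated state in the similarity coordinate
#'
#' Pure coordinate change x -> eta = x/sqrt(4 D_s t); values are preserved.
#' While the diffusion front is far from the closed end, states at different
#' times collapse onto a single curve in this coordinate; once the front
#' reaches the end of the channel the semi-infinite assumption breaks and the
#' collapse fails.
#'
#' @param state A `sim_state`.
#' @param d_s Effective salt diffusivity used for the rescaling, m^2/s.
#' @return A `similarity_profile` (with `params = NULL`).
#' @export
to_similarity <- function(state, d_s) {
  stopifnot(inherits(state, "sim_state"))
  if (state$time <= 0) stop("state time must be positive", call. = FALSE)
  structure(list(eta = eta_of(state$x_centers, state$time, d_s),
                 n = state$protein, params = NULL, residual = NA_real_),
            class = "similarity_profile")
}

#' Analytic model states on the channel grid
#'
#' Evaluates the similarity-model solution (protein from
#' [solve_similarity()], salt from [salt_profile()]) on the channel cell
#' centers at the requested times, producing `sim_state` objects exactly on
#' the semi-infinite model. Useful as noise-free ground truth for synthetic
#' stacks and parameter-recovery studies, where the finite-volume
#' discretization error of [simulate_channel()] would contaminate the truth.
#'
#' @param geometry A [channel_geometry].
#' @param s A [salt] object.
#' @param protein List with `d_p` and `gamma_p`, m^2/s (attractive-positive).
#' @param save_times Strictly increasing positive times, s.
#' @param n_main Relative main-channel protein concentration.
#' @param ... Further arguments to [similarity_params()] (`eta_max`,
#'   `n_grid`, ...).
#' @return A list of `sim_state`, same layout as [simulate_channel()].
#' @export
similarity_states <- function(geometry, s, protein, save_times, n_main = 1,
                              ...) {
  stopifnot(inherits(geometry, "channel_geometry"), inherits(s, "salt"))
  if (!all(diff(c(0, save_times)) > 0)) {
    stop("save_times must be strictly increasing and positive", call. = FALSE)
  }
  d_s <- salt_diffusivity(s)
  alpha <- s$c_main / s$c_reservoir
  params <- similarity_params(dp_ratio = protein$d_p / d_s,
                              gamma_ratio = protein$gamma_p / d_s,
                              alpha = alpha, ...)
  prof <- solve_similarity(params)
  n <- geometry$n_cells
  dx <- geometry$length / n
  x <- (seq_len(n) - 0.5) * dx
  states <- lapply(save_times, function(t) {
    eta <- eta_of(x, t, d_s)
    structure(list(
      x_centers = x,
      salt = s$c_reservoir * salt_profile(eta, params$alpha),
      protein = n_main * stats::approx(prof$eta, prof$n, eta,
                                       yleft = 1, yright = 0)$y,
      time = t), class = "sim_state")
  })
  attr(states, "geometry") <- geometry
  attr(states, "salt") <- s
  attr(states, "protein") <- protein
  attr(states, "n_main") <- n_main
  states
}

#' Export simulated states as CSV
#'
#' One row per cell per state, columns `time, x, salt, protein`.
#'
#' @param states List of `sim_state` (from [simulate_channel()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_states_csv <- function(states, path) {
  df <- do.call(rbind, lapply(states, function(st) {
    data.frame(time = st$time, x = st$x_centers,
               salt = st$salt, protein = st$protein)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
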