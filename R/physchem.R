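# Fixed physical constants (SI)
.kB <- 1.380649e-23  # Boltzmann constant, J/K
.e  <- 1.602177e-19  # elementary charge, C

#' Physical constants used by the package
#'
#' Returns the Boltzmann constant and the elementary charge used in all
#' mobility/charge conversions.
#'
#' @return Named list with `k_boltzmann` (J/K) and `e_charge` (C).
#' @export
physical_constants <- function() {
  list(k_boltzmann = .kB, e_charge = .e)
}

#' Binary electrolyte descriptor
#'
#' Describes a symmetric binary electrolyte by its ionic diffusion
#' coefficients, ion charge number and the concentrations on the two sides of
#' the dead-end inlet. The dead-end channel initially holds the salt at
#' `c_reservoir`; the main channel carries `c_main`.
#'
#' @param name Salt name (e.g. `"LiCl"`).
#' @param d_plus Cation diffusion coefficient, m^2/s.
#' @param d_minus Anion diffusion coefficient, m^2/s.
#' @param valence Ion charge number Z (symmetric electrolyte), >= 1.
#' @param c_reservoir Initial dead-end concentration C0, mol/m^3.
#' @param c_main Main-channel concentration, mol/m^3; `0 <= c_main <= c_reservoir`.
#'
#' @return An object of class `salt`.
#' @examples
#' licl <- salt("LiCl", d_plus = 1.03e-8, d_minus = 2.03e-8,
#'              valence = 1, c_reservoir = 200, c_main = 2)
#' beta_coefficient(licl)
#' @export
salt <- function(name, d_plus, d_minus, valence = 1,
                 c_reservoir = 200, c_main = 2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(d_plus) || !is.numeric(d_minus) ||
      d_plus <= 0 || d_minus <= 0) {
    stop("ionic diffusion coefficients must be strictly positive", call. = FALSE)
  }
  if (valence < 1) stop("valence must be >= 1", call. = FALSE)
  if (c_main < 0 || c_main > c_reservoir) {
    stop("require 0 <= c_main <= c_reservoir", call. = FALSE)
  }
  structure(list(name = name, d_plus = d_plus, d_minus = d_minus,
                 valence = valence, c_reservoir = c_reservoir,
                 c_main = c_main),
            class = "salt")
}

#' @export
print.salt <- function(x, ...) {
  cat(sprintf("<salt> %s: D+ = %.3g m^2/s, D- = %.3g m^2/s, Z = %d\n",
              x$name, x$d_plus, x$d_minus, as.integer(x$valence)))
  cat(sprintf("  C0 = %.3g mol/m^3 (dead-end), C_main = %.3g mol/m^3, beta = %.3f\n",
              x$c_reservoir, x$c_main, beta_coefficient(x)))
  invisible(x)
}

#' Built-in salt table
#'
#' The three electrolytes used in the dead-end experiments, at 200 mM in the
#' dead-end against a 2 mM main channel (concentration ratio alpha = 0.01).
#' LiCl uses the ionic diffusivities as printed alongside the experiments
#' (1.03e-8 and 2.03e-8 m^2/s); beta is invariant under a common rescaling of
#' both diffusivities, so every dimensionless model quantity is unaffected by
#' their absolute scale. For KCl and KIO3 only the beta coefficients (-0.019
#' and 0.298) accompany the experiments; their entries use a handbook-scale
#' potassium diffusivity with the counter-ion diffusivity chosen to reproduce
#' those beta values.
#'
#' @param name Optional salt name; if missing the whole named list is returned.
#' @return A `salt` object, or a named list of them.
#' @examples
#' builtin_salts("LiCl")
#' sapply(builtin_salts(), beta_coefficient)
#' @export
builtin_salts <- function(name) {
  tbl <- list(
    LiCl = salt("LiCl", d_plus = 1.03e-8,  d_minus = 2.03e-8),
    KCl  = salt("KCl",  d_plus = 1.957e-9, d_minus = 2.0328e-9),
    KIO3 = salt("KIO3", d_plus = 1.957e-9, d_minus = 1.0583e-9)
  )
  if (missing(name)) return(tbl)
  if (!name %in% names(tbl)) {
    stop("unknown built-in salt: ", name, call. = FALSE)
  }
  tbl[[name]]
}

#' Load a salt definition from a YAML or JSON config file
#'
#' The file must contain the keys `name`, `d_plus`, `d_minus` and may contain
#' `valence`, `c_reservoir`, `c_main`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `salt` object.
#' @export
load_salt <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported salt config format: ", ext, call. = FALSE)
  )
  need <- c("name", "d_plus", "d_minus")
  if (!all(need %in% names(rec))) {
    stop("salt config must define: ", paste(need, collapse = ", "), call. = FALSE)
  }
  do.call(salt, rec[intersect(names(rec),
                              c(need, "valence", "c_reservoir", "c_main"))])
}

#' Solvent conditions
#'
#' @param temperature Absolute temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param permittivity Solvent permittivity, F/m (defaults to water at 25 C).
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = 298, viscosity = 1e-3,
                               permittivity = 6.94e-10) {
  if (temperature <= 0 || viscosity <= 0 || permittivity <= 0) {
    stop("solvent conditions must be strictly positive", call. = FALSE)
  }
  structure(list(temperature = temperature, viscosity = viscosity,
                 permittivity = permittivity),
            class = "solvent_conditions")
}

#' @export
print.solvent_conditions <- function(x, ...) {
  cat(sprintf("<solvent_conditions> T = %g K, eta = %g Pa s, eps = %g F/m\n",
              x$temperature, x$viscosity, x$permittivity))
  invisible(x)
}

#' Beta coefficient of a binary electrolyte
#'
#' The normalized difference of the cation and anion diffusion coefficients,
#' beta = (D+ - D-)/(D+ + D-). It sets the magnitude and sign of the
#' spontaneous electric field that arises in a salt gradient to keep the two
#' ion species moving together: E is proportional to beta (kB T)/(Z e) grad ln C.
#'
#' @param s A [salt] object.
#' @return Dimensionless beta in \[-1, 1\].
#' @examples
#' beta_coefficient(builtin_salts("LiCl"))  # -0.327
#' @export
beta_coefficient <- function(s) {
  stopifnot(inherits(s, "salt"))
  (s$d_plus - s$d_minus) / (s$d_plus + s$d_minus)
}

#' Effective diffusion coefficient of a binary electrolyte
#'
#' A salt gradient relaxes with a single effective coefficient because the
#' ambipolar field couples the two ions. The default is the ambipolar
#' (Nernst-Hartley) harmonic form `2 D+ D- / (D+ + D-)`; the arithmetic mean
#' is available for sensitivity checks.
#'
#' @param s A [salt] object.
#' @param mode `"ambipolar"` (default) or `"arithmetic"`.
#' @return Effective salt diffusivity D_s, m^2/s; always between the ionic
#'   diffusivities.
#' @examples
#' salt_diffusivity(builtin_salts("LiCl"))  # 1.367e-8 m^2/s
#' @export
salt_diffusivity <- function(s, mode = c("ambipolar", "arithmetic")) {
  stopifnot(inherits(s, "salt"))
  mode <- match.arg(mode)
  switch(mode,
         ambipolar  = 2 * s$d_plus * s$d_minus / (s$d_plus + s$d_minus),
         arithmetic = (s$d_plus + s$d_minus) / 2)
}

#' Electrophoretic contribution to the diffusiophoretic mobility
#'
#' Under the ambipolar field E = beta (kB T)/(Z e) grad ln C, a protein with
#' electrophoretic mobility `mu_p` acquires a drift velocity
#' `mu_p * beta * kB T/(Z e) * grad ln C`; the prefactor of `grad ln C` is the
#' electrophoretic part of the diffusiophoretic mobility Gamma_p. With
#' chemiophoresis subdominant for proteins this is the whole of Gamma_p.
#'
#' @param mu_p Electrophoretic mobility, m^2/(V s); sign = sign of the charge.
#' @param s A [salt] object.
#' @param cond A [solvent_conditions] object.
#' @return Gamma_p (electrophoretic part), m^2/s. Positive values drift up the
#'   salt gradient (into the dead-end).
#' @examples
#' gamma_electrophoretic(1.76e-8, builtin_salts("KIO3"), solvent_conditions())
#' @export
gamma_electrophoretic <- function(mu_p, s, cond = solvent_conditions()) {
  stopifnot(inherits(s, "salt"), inherits(cond, "solvent_conditions"))
  if (s$valence == 0) stop("ion valence must be nonzero", call. = FALSE)
  mu_p * beta_coefficient(s) * .kB * cond$temperature / (s$valence * .e)
}

#' Invert the diffusiophoretic mobility to an electrophoretic mobility
#'
#' Inverse of [gamma_electrophoretic()]; undefined for beta = 0 (no ambipolar
#' field, so Gamma carries no mobility information).
#'
#' @param gamma_p Diffusiophoretic mobility, m^2/s (attractive-positive).
#' @inheritParams gamma_electrophoretic
#' @return Electrophoretic mobility mu_p, m^2/(V s).
#' @export
mobility_from_gamma <- function(gamma_p, s, cond = solvent_conditions()) {
  stopifnot(inherits(s, "salt"), inherits(cond, "solvent_conditions"))
  beta <- beta_coefficient(s)
  if (beta == 0) {
    stop("beta = 0: mobility is unrecoverable from the diffusiophoretic mobility",
         call. = FALSE)
  }
  gamma_p * s$valence * .e / (beta * .kB * cond$temperature)
}

#' Effective charge from mobility and diffusivity (Einstein relation)
#'
#' q_p = mu_p kB T / D_p.
#'
#' @param mu_p Electrophoretic mobility, m^2/(V s).
#' @param d_p Protein diffusion coefficient, m^2/s.
#' @param cond A [solvent_conditions] object.
#' @return Charge in Coulomb (divide by `physical_constants()$e_charge` for
#'   units of e).
#' @export
charge_from_mobility <- function(mu_p, d_p, cond = solvent_conditions()) {
  stopifnot(inherits(cond, "solvent_conditions"))
  if (d_p <= 0) stop("d_p must be strictly positive", call. = FALSE)
  mu_p * .kB * cond$temperature / d_p
}

#' Mobility from charge and diffusivity (inverse Einstein relation)
#'
#' @param q_p Effective charge, C.
#' @inheritParams charge_from_mobility
#' @return Electrophoretic mobility, m^2/(V s).
#' @export
mobility_from_charge <- function(q_p, d_p, cond = solvent_conditions()) {
  stopifnot(inherits(cond, "solvent_conditions"))
  if (d_p <= 0) stop("d_p must be strictly positive", call. = FALSE)
  q_p * d_p / (.kB * cond$temperature)
}

#' Stokes-Einstein hydrodynamic radius
#'
#' R_h = kB T / (6 pi eta D_p).
#'
#' @param d_p Protein diffusion coefficient, m^2/s.
#' @param cond A [solvent_conditions] object.
#' @return Hydrodynamic radius, m.
#' @examples
#' stokes_einstein_radius(5.9e-11)  # 3.70 nm
#' @export
stokes_einstein_radius <- function(d_p, cond = solvent_conditions()) {
  stopifnot(inherits(cond, "solvent_conditions"))
  if (d_p <= 0) stop("d_p must be strictly positive", call. = FALSE)
  .kB * cond$temperature / (6 * pi * cond$viscosity * d_p)
}

#' Diffusivity from hydrodynamic radius
#'
#' Inverse of [stokes_einstein_radius()].
#'
#' @param radius_h Hydrodynamic radius, m.
#' @param cond A [solvent_conditions] object.
#' @return Diffusion coefficient, m^2/s.
#' @export
diffusivity_from_radius <- function(radius_h, cond = solvent_conditions()) {
  stopifnot(inherits(cond, "solvent_conditions"))
  if (radius_h <= 0) stop("radius_h must be strictly positive", call. = FALSE)
  .kB * cond$temperature / (6 * pi * cond$viscosity * radius_h)
}

#' Diffusiophoretic drift velocity
#'
#' u_p = Gamma_p * grad ln C.
#'
#' @param gamma_p Diffusiophoretic mobility, m^2/s.
#' @param grad_ln_c Log-gradient of the salt concentration, 1/m.
#' @return Drift velocity, m/s.
#' @export
drift_velocity <- function(gamma_p, grad_ln_c) {
  gamma_p * grad_ln_c
}

#' Protein property bundle
#'
#' Container for the transport and electrokinetic properties of one protein.
#' Fields left `NA` are simply not yet derived.
#'
#' @param d_p Diffusion coefficient, m^2/s (required, > 0).
#' @param gamma_p Diffusiophoretic mobility, m^2/s (attractive-positive).
#' @param mu_p Electrophoretic mobility, m^2/(V s).
#' @param zeta Zeta potential, V.
#' @param charge Effective charge, C.
#' @param radius_h Hydrodynamic radius, m.
#' @return An object of class `protein_properties`.
#' @export
protein_properties <- function(d_p, gamma_p = NA_real_, mu_p = NA_real_,
                               zeta = NA_real_, charge = NA_real_,
                               radius_h = NA_real_) {
  if (d_p <= 0) stop("d_p must be strictly positive", call. = FALSE)
  if (!is.na(radius_h) && radius_h <= 0) {
    stop("radius_h must be strictly positive when set", call. = FALSE)
  }
  structure(list(d_p = d_p, gamma_p = gamma_p, mu_p = mu_p, zeta = zeta,
                 charge = charge, radius_h = radius_h),
            class = "protein_properties")
}

#' @export
print.protein_properties <- function(x, ...) {
  cat("<protein_properties>\n")
  cat(sprintf("  D_p     = %.4g m^2/s\n", x$d_p))
  if (!is.na(x$gamma_p)) cat(sprintf("  Gamma_p = %.4g m^2/s\n", x$gamma_p))
  if (!is.na(x$mu_p))    cat(sprintf("  mu_p    = %.4g m^2/(V s)\n", x$mu_p))
  if (!is.na(x$radius_h)) cat(sprintf("  R_h     = %.3g nm\n", x$radius_h * 1e9))
  if (!is.na(x$charge))  cat(sprintf("  q_p     = %.3g e\n", x$charge / .e))
  invisible(x)
}
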