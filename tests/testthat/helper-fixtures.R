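# Shared fixtures: the LiCl gradient case with a BSA-like protein
# (D_p = 5.9e-11 m^2/s, attractive Gamma_p = 1.5e-10 m^2/s), and synthetic
# stacks built from the analytic model states.

licl <- builtin_salts("LiCl")
d_s_licl <- salt_diffusivity(licl)

bsa_like <- list(d_p = 5.9e-11, gamma_p = 1.5e-10)

# 10 log-spaced frame times over the window in which the salt gradient
# persists in the 500 um channel
default_times <- function(n = 10) exp(seq(log(0.5), log(8), length.out = n))

model_states <- function(times = default_times(), n_cells = 400,
                         protein = bsa_like, s = licl) {
  similarity_states(channel_geometry(n_cells = n_cells), s, protein, times)
}

clean_optics <- function(bleach_rate = 0, ...) {
  optics_config(background_coef = c(1, 0, 0, 0, 0, 0), noise_sigma = 0,
                bleach_rate = bleach_rate, ...)
}

noisy_optics <- function(snr = 10, bleach_rate = 0.004, ...) {
  optics_config(snr = snr, bleach_rate = bleach_rate, ...)
}

# sup-norm distance between an extracted profile and the generator truth,
# relative to the truth maximum
profile_truth_error <- function(profile, truth, frame) {
  tr <- stats::approx(truth$x, truth$profiles[frame, ], profile$x,
                      rule = 2)$y
  max(abs(profile$intensity - tr)) / max(tr)
}

erf_base <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
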