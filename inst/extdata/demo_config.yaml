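# Noise-free demonstration run: an LiCl gradient focusing a BSA-like protein
# (D_p = 5.9e-11 m^2/s, Gamma_p = +1.5e-10 m^2/s, attractive), imaged without
# illumination bias, bleaching or noise. The fit stage recovers the
# configured protein parameters.
salt: LiCl
protein:
  d_p: 5.9e-11
  gamma_p: 1.5e-10
times:
  from: 0.5
  to: 8.0
  n: 10
source: similarity
optics:
  background_coef: [1.0, 0.0, 0.0, 0.0, 0.0, 0.0]
  noise_sigma: 0.0
  bleach_rate: 0.0
output_dir: demo_out
seed: 1
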