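# Example salt definition file for dphoresis::load_salt(); units: m^2/s for
# diffusivities, mol/m^3 for concentrations.
name: LiCl
d_plus: 1.03e-8
d_minus: 2.03e-8
valence: 1
c_reservoir: 200
c_main: 2
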