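# Example diatomflux configuration. Any field omitted here falls back to
# the package default (see default_config()); unknown keys are rejected.
taxa:
  diatom:
    a_c: 0.11668           # pg C per cell at V = 1 um^3
    b_c: 0.881             # dimensionless allometric exponent
    e_mu: 0.691            # growth respiration, mol C per mol biomass C
    e_si_per_si: 0.167     # deposition cost, mol C per mol Si
    r_sic: 0.163           # cellular Si:C molar ratio
    e_ex: 0.0              # excreted fraction, mol C per mol biomass C
  other:
    a_c: 0.21628
    b_c: 0.939
    e_mu: 0.691
    e_si_per_si: 0.0
    r_sic: 0.0             # non-diatoms deposit no silica
light:
  i0: 200                  # incident irradiance, umol photons m^-2 s^-1
  k_att: 0.3797598021513   # intracellular attenuation, um^-1
photosynthesis:
  p_max_v: 2.568157601449e-14  # max volumetric fixation, mol C um^-3 d^-1
  i_sat: 60                # saturation irradiance, umol photons m^-2 s^-1
sweep:
  v_min: 1                 # um^3
  v_max: 1.0e+8            # um^3
  n_points: 60             # log-spaced grid points
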