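# Case study 2: phospholipid vesicles with membrane-embedded enzymes
# hydrolyzing ATP (neutral substrate, singly charged product). The group
# prefactors rescale the raw lambda^2 and xi^2 so that they traverse their
# reported ranges (1e-15 .. 2e-13 and 3e-2 .. 2.9 respectively) over the
# default sweep window, which spans mean reaction rates of 1-100 nM/s.
params:
  C0: 0.5                 # mol/m^3 (0.5 mM)
  T0: 294.15              # K
  k_r: 250.0              # 1/s
  D_s: 3.6e-10            # m^2/s (360 um^2/s)
  eta_s: 1.0e-3           # Pa s
  U: 10.0                 # 1/s
  dH_r: -30.0e+3          # J/mol
  dmu_r0: -60.0e+3        # J/mol
  kappa: 0.59             # W/(K m)
  U_q: 0.01               # W/(K m^2)
  eps_thick: 1.5e-8       # m (main fitting parameter)
  z_M: 0
  z_N: -1
  gamma_CM: -1.0e-8       # J m/mol  (-0.01 mJ/m^2/M)
  gamma_CN: 2.0e-8        # J m/mol  (0.02 mJ/m^2/M)
  gamma_T: -1.0e-5        # J/(m^2 K)
  D0: 6.5e-14             # m^2/s (0.065 um^2/s)
  R: 2.1e-6               # m
  w0: 0.5
  phi0: 1.5707963267948966
  eps_r: 78.5
  xi2_prefactor: 30.85814
  lambda2_prefactor: 0.1874933
  tau_mode: kr
sweep:
  rdot_min_nMps: 1.0
  rdot_max_nMps: 100.0
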