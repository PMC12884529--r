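# Case study 1: nanometric catalytic Janus particles with a charged salt
# substrate. Dimensional values as tabulated for this system; the
# lambda2_prefactor rescales the raw heat-generation group so that it
# traverses the reported range 1e-19 .. 1.13e-17 over the default sweep
# window, which itself is chosen so that the electrostatic group xi^2
# (prefactor 1) traverses its reported range 3e-4 .. 3.29e-2.
params:
  C0: 0.5                 # mol/m^3 (0.5 mM)
  T0: 298.15              # K
  k_r: 21.4               # 1/s
  D_s: 6.5e-10            # m^2/s (650 um^2/s)
  eta_s: 8.91e-4          # Pa s
  U: 10.0                 # 1/s
  dH_r: -91.0e+3          # J/mol (exothermic)
  dmu_r0: 30.0e+3         # J/mol
  kappa: 0.6              # W/(K m)
  U_q: 0.01               # W/(K m^2)
  eps_thick: 5.0e-9       # m (main fitting parameter)
  z_M: -3
  z_N: -4
  gamma_CM: 1.5e-6        # J m/mol  (1.5 mJ/m^2/M)
  gamma_CN: 2.0e-7        # J m/mol  (0.2 mJ/m^2/M)
  gamma_T: -2.0e-4        # J/(m^2 K)
  D0: 7.75e-12            # m^2/s (7.75 um^2/s)
  R: 9.0e-9               # m
  w0: 0.5
  phi0: 1.5707963267948966
  eps_r: 78.5
  xi2_prefactor: 1.0
  lambda2_prefactor: 1.679371e-4
  tau_mode: kr_beta2
sweep:
  c0_min: 6.854899e-4     # mol/m^3
  c0_max: 7.517539e-2     # mol/m^3
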