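# Default run configuration (SI units throughout).
# geometry: idealized axisymmetric spinal canal; volumes in m^3, lengths in m
geometry:
  length: 0.60                # S1 (z = 0, caudal) -> C1
  reservoir_volume: 2.4e-4    # lumped cranial CSF
mesh:
  nz: 96                      # axial cells before refinement
  nr: 6                       # radial cells across the dura-cord gap
  refine: 2                   # axial refinement inside the L4-L5 window
waveform:
  heart_rate: 60.0            # beats/min
  pulse_volume: 1.0e-6        # m^3 per cardiac cycle
  resp_rate: 12.0             # breaths/min
  tidal_csf_volume: 5.0e-7    # m^3 per breath
  production_rate: 6.6667e-9  # m^3/s (= 0.4 mL/min)
fluid:
  rho: 998.3                  # kg/m^3
  mu: 8.9e-4                  # Pa s
transport:
  D: 5.0e-10                  # m^2/s, drug diffusivity
  scheme: vanleer             # or minmod / first-order
solver:
  dt: 0.01                    # s
  tol: 1.0e-6                 # inner convergence criterion
  max_inner: 6
  cfl_max: 0.45
  scheme: minmod              # momentum convection limiter
runs: [1, 2, 3, 4, 5, 6, 7, 8, 9]
t_end: 360.0
snapshot_times: [60.0, 180.0, 360.0]
record_dt: 0.1
seed: 1
strict: false
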