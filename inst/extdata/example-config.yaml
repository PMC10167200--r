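# Example riisvalve pipeline configuration (desk-scale preset).
# Angles in leaflet blocks, if given explicitly, are degrees.
fixture:
  name: severe        # healthy | mild | moderate | severe
  seed: 42            # asymmetry jitter seed; omit for a symmetric valve
geometry:
  nu: 25              # surface sampling per patch for STL/VTK export
  nv: 25
mesh:
  h_fine: 1.5         # mm, inside the valve refinement band (fine preset: 0.5)
  h_coarse: 2.25      # mm, elsewhere (fine preset: 0.75)
gamma:
  C: 1.0e8            # penalization constant
  h_phys: 0           # physiological thickness floor, mm
flow:
  Re_max: 1200        # peak inlet Reynolds number (diameter-based)
  T: 0.4              # systolic interval, s
  T_end: 0.2          # run to peak systole, s
  dt: 0.01            # s (fine preset: 0.0025)
  rho: 1060           # kg/m^3
  mu: 3.5e-3          # Pa s
  backflow_coeff: 0.5
output: riisvalve-out
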