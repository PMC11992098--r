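array:
  rows: 8
  cols: 8
  pitch_mm: 4.5
  kerf_mm: 0.2
  frequency_khz: 500.0
medium:
  density_kg_m3: 1000.0
  sound_speed_m_s: 1500.0
  conductivity_s_m: 0.5
  attenuation_np_m: 0.0
magnetic_field:
  kind: uniform
  b_tesla: 0.5
assignment:
  strategy: block
grid:
  x_mm:
  - -37.5
  - 37.5
  y_mm:
  - -37.5
  - 37.5
  z_mm: -50.0
  step_mm: 0.25
solver:
  subsource_spacing_fraction: 0.25
drive:
  amplitude: 1.0
scenario: b_sweep
targets:
- label: left
  x_mm: -9.0
  y_mm: 0.0
  z_mm: -50.0
- label: right
  x_mm: 9.0
  y_mm: 0.0
  z_mm: -50.0
sweep:
  b_tesla_values:
  - 0.2
  - 0.3
  - 0.5
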