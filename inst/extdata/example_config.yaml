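# Example rfasim pipeline configuration.
# Units: mm for lengths, s for durations, W for power, deg C for
# temperatures; omega_b in kg/(m^3 s).
seed: 1

phantom:
  grid:
    shape: [48, 48, 48]
    spacing: 2
  tumor:
    center: [47, 47, 47]
    radius: 10
  vessels:
    - p0: [63, 47, -20]
      p1: [63, 47, 120]
      radius: 3
  crop_radius: 60
  properties:
    healthy: {omega_b: 2.0}
    tumor: {omega_b: 0.6}

needle:
  model: umbrella
  tip: [47, 47, 40.25]
  shaft_point: [47, 47, 100.25]
  rotation_deg: 0
  extension_fraction: 1

protocol:
  gaussian_sigma: 4
  control_band: 5
  phases:
    - {duration_s: 600, mode: temperature_controlled, power_W: 40,
       target_temp_C: 105, extension_fraction: 1}
    - {duration_s: 60, mode: cooldown, power_W: 0}

solver:
  dt: 2
  record_every: 15

ensemble:
  p1: {name: tissue_perfusion, range: [0.5, 4], iterations: 5,
       sampling: linear}
  p2: {name: tumor_perfusion, range: [0.2, 1], iterations: 5,
       sampling: linear}
  outlier_depth_threshold: 0.1
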