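# Demo sedimentation run: 2 mg/mL dry yeast in water settling onto the
# sensor for 2.5 h, pulsed at 0.5 W / 1 s with 60 s cooling.
seed: 1
noise_sd_V: 2.0e-4
sensor:
  r_ref_ohm: 8
  t_ref_K: 293.15
  alpha_per_K: 3.818e-3
  heater_area_m2: 81.0e-6
  heater_areal_heat_capacity_J_m2K: 51.7
protocol:
  power_W: 0.5
  pulse_duration_s: 1
  cooling_time_s: 60
  sample_rate_Hz: 500
  total_duration_s: 9000
scenario:
  mode: sedimentation
  concentration_mg_mL: 2
analysis:
  window_sqrt_s: [0.16, 0.56]
  domain: temperature
  baseline: first
  endpoint_from_h: 2
  endpoint_to_h: 12
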