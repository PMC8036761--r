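# Demo proliferation run: yeast at OD600 0.2 in medium with 10 g/L glucose,
# 5 h lag then logistic growth with a 90 min doubling time; pulses at
# 0.5 W / 1 s with 300 s cooling for 18 h.
seed: 1
noise_sd_V: 2.0e-4
sensor:
  r_ref_ohm: 8
protocol:
  power_W: 0.5
  pulse_duration_s: 1
  cooling_time_s: 300
  sample_rate_Hz: 500
  total_duration_s: 64800
scenario:
  mode: proliferation
  od_start: 0.2
  glucose_g_L: 10.0
  lag_h: 5
  doubling_time_min: 90
  yield_od_per_gL: 0.5
analysis:
  window_sqrt_s: [0.16, 0.56]
  domain: temperature
  baseline: first
  endpoint_from_h: 2
  endpoint_to_h: 12
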