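# Shared fixtures, built lazily and cached for the session: several tests
# reuse the same simulated experiments, and the solver runs are the slow part.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default sedimentation experiment (2 mg/mL, 1.5 h, default noise, seed 1)
fx_sediment_noisy <- function() fixture("sediment_noisy", function() {
  generate_experiment(
    culture_scenario("sedimentation", concentration = 2),
    sensor_spec(),
    pulse_protocol(total_duration = 1.5 * 3600),
    seed = 1
  )
})

# stock-concentration sedimentation, noise-free, past the settling plateau
fx_sediment_clean8 <- function() fixture("sediment_clean8", function() {
  generate_experiment(
    culture_scenario("sedimentation", concentration = 8),
    sensor_spec(),
    pulse_protocol(total_duration = 2.2 * 3600),
    seed = 1, noise_sd = 0
  )
})

# 18 h proliferation run at the nutrient-experiment conditions, default noise
fx_proliferation <- function(seed = 3, noise_sd = 2e-4,
                             od_start = 0.2, glucose = 10) {
  key <- sprintf("prolif_%d_%g_%g_%g", seed, noise_sd, od_start, glucose)
  fixture(key, function() {
    generate_experiment(
      culture_scenario("proliferation", od_start = od_start, glucose = glucose),
      sensor_spec(),
      pulse_protocol(power = 0.5, pulse_duration = 1, cooling_time = 300,
                     total_duration = 18 * 3600),
      seed = seed, noise_sd = noise_sd
    )
  })
}

# the sensor's slope-vs-thickness response curve at default materials
fx_response <- function() fixture("response", function() slope_response())

# a noiseless synthetic pulse from a prescribed linear-in-sqrt(t) transient
fake_linear_pulse <- function(slope, n = 500, fs = 500, spec = sensor_spec(),
                              current = 0.25, index = 0L, onset = 0) {
  t <- seq_len(n) / fs
  curve <- structure(data.frame(t = t, dT = slope * sqrt(t)),
                     class = c("transient_curve", "data.frame"))
  synthesize_pulse(spec, curve, current, noise_sd = 0,
                   pulse_index = index, onset = onset)
}
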