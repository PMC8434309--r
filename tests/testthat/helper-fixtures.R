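# Shared fixtures, all generated in code.

# A linear ramp y = slope * t sampled at `rate` Hz over `dur` seconds.
ramp_signal <- function(slope = 2, rate = 1000, dur = 1) {
  t <- seq(0, dur, by = 1 / rate)
  uniform_signal(slope * t, 1 / rate, 0)
}

# Noise-free strictly periodic trace plus annotations.
clean_trace <- function(n_cycles = 12, mean_hr = 60, sample_rate = 500,
                        seed = 1) {
  simulate_preset("clean", n_cycles = n_cycles, mean_hr = mean_hr,
                  sample_rate = sample_rate, seed = seed)
}

# Randomized trace family used by the property suites.
random_trace <- function(seed) {
  hrs <- c(45, 60, 75, 90, 110, 140)
  with_local_seed(seed, {
    hr <- sample(hrs, 1)
    params <- ecg_model_params(
      mean_hr = hr,
      hr_variability = stats::runif(1, 0, 0.08),
      noise_std = stats::runif(1, 0, 0.12),
      duration = 8 + 2.2 * 60 / hr,
      sample_rate = 250, seed = seed)
    fx <- generate_ecg(params)
    if (seed %% 2 == 1)
      fx$signal <- add_baseline_wander(fx$signal, stats::runif(1, 0, 0.5),
                                       stats::runif(1, 0.1, 0.5))
    fx
  })
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Step the exported one-tick API over a grid trace, recording the
# threshold trajectory and event ticks.  Independent of run_streaming's
# internal loop; used to assert state-level invariants.
trace_state_machine <- function(ecg, cfg) {
  g <- resample_to_grid(ecg, cfg$tick)
  st <- detector_state()
  tt <- signal_times(g)
  thr <- numeric(length(tt))
  det <- numeric(0); rise <- numeric(0); fall <- numeric(0)
  for (i in seq_along(tt)) {
    out <- detector_step(st, g, tt[i], cfg)
    st <- out$state
    thr[i] <- if (is.na(st$thr)) NA_real_ else st$thr
    if ("detection" %in% out$events) det <- c(det, tt[i])
    if ("ttl_rising" %in% out$events) rise <- c(rise, tt[i])
    if ("ttl_falling" %in% out$events) fall <- c(fall, tt[i])
  }
  list(thr = thr, detections = det, rising = rise, falling = fall,
       times = tt)
}
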