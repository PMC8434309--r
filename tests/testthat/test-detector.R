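cfg0 <- detector_config()

test_that("finite_difference is the un-normalized two-sample difference", {
  const <- uniform_signal(rep(3, 201), 0.005, 0)
  expect_equal(finite_difference(const, 0.25, cfg0), 0)
  ramp <- ramp_signal(slope = 2, rate = 1000, dur = 1)
  expect_equal(finite_difference(ramp, 0.1, cfg0), 2 * 0.005,
               tolerance = 1e-12)
  t <- seq(0, 1, by = 0.001)
  sine <- uniform_signal(sin(2 * pi * t), 0.001, 0)
  expect_equal(finite_difference(sine, 0, cfg0), sin(0.01 * pi),
               tolerance = 1e-9)
  expect_error(finite_difference(ramp, 1.0, cfg0), "outside")
  expect_error(finite_difference(ramp, 0.0021, cfg0), "not on the tick grid")
})

test_that("decay_threshold follows the configured law", {
  expect_equal(decay_threshold(1, cfg0), 0.9986)
  # 500 successive steps against the repeated-multiplication oracle
  thr <- 1
  for (i in 1:500) thr <- decay_threshold(thr, cfg0)
  oracle <- 1
  for (i in 1:500) oracle <- oracle * (1 - 0.0014)
  expect_identical(thr, oracle)
  expect_equal(thr, 0.4963418, tolerance = 1e-6)
  # x -> 0 limit leaves thr essentially unchanged
  tiny <- detector_config(decay_rate = 1e-12)
  expect_equal(decay_threshold(5, tiny), 5, tolerance = 1e-9)
  # the state-dependent exponential variant, exactly as stated
  ex <- detector_config(decay_law = "true_exponential")
  expect_equal(decay_threshold(2, ex), 2 * exp(-2 * 0.0014))
  expect_error(decay_threshold(0, cfg0), "thr must be > 0")
  expect_error(decay_threshold(-1, cfg0), "thr must be > 0")
})

test_that("update_heart_rate inverts the period", {
  expect_equal(update_heart_rate(2, 1), list(period = 1, hr = 60))
  r <- update_heart_rate(1.66, 1)
  expect_equal(r$hr, 60 / 0.66, tolerance = 1e-9)   # ~90.91 bpm
  expect_equal(update_heart_rate(1.5, 1)$hr, 120)
  expect_error(update_heart_rate(1, 1), "strictly increasing")
})

test_that("schedule_trigger lands on the first grid point past ti + Tj - dtMP", {
  c50 <- detector_config(dt_mp = 0.05)
  expect_equal(schedule_trigger(10, 1, c50), 10.955)
  expect_equal(schedule_trigger(10, 1, cfg0), 11.005)  # dt_mp = 0
  c2 <- detector_config(dt_mp = 2)
  expect_warning(s <- schedule_trigger(10, 1, c2), "clamped")
  expect_equal(s, 10.005)
})

test_that("a flat trace never detects and never raises the line", {
  flat <- uniform_signal(rep(0, 400), 0.005, 0)
  run <- run_streaming(flat, cfg0)
  expect_length(run$detections, 0)
  expect_length(run$rising, 0)
  expect_true(all(run$ttl$samples == 0))
})

test_that("the refractory suppresses recrossings but the threshold decays", {
  # diffs: 0.1 (init), 0.2 (detect), then large values inside 20 ms
  y <- cumsum(c(0, 0.1, 0.2, 0.5, 0.5, 0.5, 0.5))
  sig <- uniform_signal(y, 0.005, 0)
  g <- sig
  st <- detector_state()
  out <- detector_step(st, g, 0, cfg0)       # init: thr = 0.1
  expect_equal(out$state$thr, 0.1)
  out <- detector_step(out$state, g, 0.005, cfg0)
  expect_equal(out$events, "detection")      # 0.2 > 0.1
  expect_equal(out$state$thr, 0.2)
  st <- out$state
  for (t in c(0.010, 0.015, 0.020, 0.025)) { # all within t - ti <= 20 ms
    out <- detector_step(st, g, t, cfg0)
    expect_false("detection" %in% out$events)
    expect_equal(out$state$thr, st$thr * 0.9986)  # still decaying
    st <- out$state
  }
  expect_equal(st$detections_seen, 1L)
})

test_that("pulses last pulse_width, tick-quantized, and ties favor the raise", {
  fx <- clean_trace(n_cycles = 8, seed = 4)
  run <- suppressWarnings(run_streaming(fx$signal, cfg0))
  n <- min(length(run$rising), length(run$falling))
  expect_gt(n, 2)
  expect_equal(run$falling$times[seq_len(n)] - run$rising$times[seq_len(n)],
               rep(0.025, n), tolerance = 1e-9)
  # pulse_width below one tick: raise wins, lower happens the next tick
  sub <- detector_config(pulse_width = 0.003)
  run2 <- suppressWarnings(run_streaming(fx$signal, sub))
  n2 <- min(length(run2$rising), length(run2$falling))
  expect_equal(run2$falling$times[seq_len(n2)] - run2$rising$times[seq_len(n2)],
               rep(0.005, n2), tolerance = 1e-9)
  # a non-multiple width rounds up to the next tick
  odd <- detector_config(pulse_width = 0.022)
  run3 <- suppressWarnings(run_streaming(fx$signal, odd))
  n3 <- min(length(run3$rising), length(run3$falling))
  expect_equal(run3$falling$times[seq_len(n3)] - run3$rising$times[seq_len(n3)],
               rep(0.025, n3), tolerance = 1e-9)
})

test_that("runs are deterministic and config validation rejects bad values", {
  fx <- clean_trace(n_cycles = 6, seed = 9)
  a <- suppressWarnings(run_streaming(fx$signal, cfg0))
  b <- suppressWarnings(run_streaming(fx$signal, cfg0))
  expect_identical(a$ttl$samples, b$ttl$samples)
  expect_identical(a$detections$times, b$detections$times)
  expect_error(detector_config(decay_rate = 0), "0 < x < 1")
  expect_error(detector_config(decay_rate = 1), "0 < x < 1")
  expect_error(detector_config(tick = 0), "> 0")
  expect_error(detector_config(refractory = -1), ">= 0")
  expect_error(run_streaming(uniform_signal(c(0, 1), 0.005, 0), cfg0),
               "shorter")
})
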