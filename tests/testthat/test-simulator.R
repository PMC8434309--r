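test_that("generation is seeded and deterministic", {
  p <- ecg_model_params(mean_hr = 70, hr_variability = 0.05,
                        noise_std = 0.05, duration = 10, seed = 42)
  a <- generate_ecg(p)
  b <- generate_ecg(p)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$r_truth$times, b$r_truth$times)
  c <- generate_ecg(ecg_model_params(mean_hr = 70, hr_variability = 0.05,
                                     noise_std = 0.05, duration = 10,
                                     seed = 43))
  expect_false(identical(a$signal$samples, c$signal$samples))
})

test_that("constant-rate generation yields one beat per period", {
  fx <- generate_ecg(ecg_model_params(mean_hr = 60, hr_variability = 0,
                                      duration = 60, seed = 1))
  n <- length(fx$r_truth)
  expect_true(abs(n - 60) <= 1)
  expect_equal(diff(fx$r_truth$times), rep(1, n - 1), tolerance = 1e-9)
})

test_that("a noise-free constant-rate trace is exactly periodic", {
  fx <- generate_ecg(ecg_model_params(mean_hr = 60, hr_variability = 0,
                                      noise_std = 0, duration = 12,
                                      sample_rate = 500, seed = 1))
  y <- fx$signal$samples
  shift <- 500                       # one 1-s period at 500 Hz
  mid <- 1001:4000                   # interior slice, away from the ends
  expect_equal(y[mid], y[mid + shift], tolerance = 1e-9)
})

test_that("baseline wander adds exactly the stated sinusoid", {
  fx <- generate_ecg(ecg_model_params(duration = 20.5, seed = 2))
  w <- add_baseline_wander(fx$signal, amplitude = 0.4, frequency = 0.5,
                           phase = 0.3)
  t <- signal_times(fx$signal)
  expect_equal(w$samples - fx$signal$samples,
               0.4 * sin(2 * pi * 0.5 * t + 0.3), tolerance = 1e-12)
  # amplitude 0 is the identity
  expect_equal(add_baseline_wander(fx$signal, 0, 0.5)$samples,
               fx$signal$samples)
  # zero mean over an integer number of wander periods
  added <- w$samples - fx$signal$samples
  k <- 1:(10 / 0.5 * 500)            # first 10 periods minus phase term
  w0 <- add_baseline_wander(fx$signal, 1, 0.5)
  expect_lt(abs(mean((w0$samples - fx$signal$samples)[k])), 1e-10)
  expect_error(add_baseline_wander(fx$signal, -1, 0.5), ">= 0")
  expect_error(add_baseline_wander(fx$signal, 1, 0), "> 0")
})

test_that("motion artifacts are confined to their event windows", {
  fx <- generate_ecg(ecg_model_params(duration = 10, seed = 3))
  # no events: identity
  expect_equal(add_motion_artifact(fx$signal, numeric(0), 1, 0.5)$samples,
               fx$signal$samples)
  # a step event is a boxcar
  s <- add_motion_artifact(fx$signal, 4, 0.8, 0.5, "step")
  dd <- s$samples - fx$signal$samples
  t <- signal_times(fx$signal)
  inside <- t >= 4 & t < 4.5
  expect_equal(dd[inside], rep(0.8, sum(inside)))
  expect_true(all(dd[!inside] == 0))
  # burst energy is confined to the window
  b <- add_motion_artifact(fx$signal, 4, 0.8, 0.5, "burst")
  db <- b$samples - fx$signal$samples
  expect_true(all(db[!inside] == 0))
  expect_gt(max(abs(db[inside])), 0.3)
  expect_error(add_motion_artifact(fx$signal, 9.9, 1, 0.5), "within the trace")
})

test_that("ground truth annotates the beat process, not the stressors", {
  fx <- generate_ecg(ecg_model_params(duration = 15, seed = 5))
  before <- fx$r_truth$times
  sig <- add_baseline_wander(fx$signal, 0.5, 0.3)
  sig <- add_motion_artifact(sig, 6, 1, 0.4, "burst")
  expect_identical(fx$r_truth$times, before)
})

test_that("parameter validation catches invalid models", {
  expect_error(ecg_model_params(mean_hr = 0), "mean_hr")
  expect_error(ecg_model_params(hr_variability = -0.1), ">= 0")
  expect_error(ecg_model_params(duration = 1.5), "2 beats")
  ws <- default_wave_set()
  ws$amplitude[ws$wave == "R"] <- 0.1   # R no longer dominant
  expect_error(ecg_model_params(wave_set = ws), "largest positive")
  ws2 <- default_wave_set()
  ws2$width[1] <- 0
  expect_error(ecg_model_params(wave_set = ws2), "> 0")
})

test_that("presets emit the named fixture sets", {
  for (p in c("clean", "wander", "noisy", "motion")) {
    fx <- simulate_preset(p, n_cycles = 6, seed = 8)
    expect_s3_class(fx$signal, "uniform_signal")
    expect_equal(length(fx$r_truth), 6)
    expect_identical(fx$preset, p)
  }
  cl <- simulate_preset("clean", n_cycles = 6, seed = 8)
  wd <- simulate_preset("wander", n_cycles = 6, seed = 8)
  t <- signal_times(cl$signal)
  expect_equal(wd$signal$samples - cl$signal$samples,
               0.5 * sin(2 * pi * 0.3 * t), tolerance = 1e-12)
})
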