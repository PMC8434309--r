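cfg0 <- detector_config()

test_that("ideal_ttl mirrors the warm-up and applies the phase offset", {
  refs <- (1:10) * 0.8
  d <- detector_config(dt_mp = 0.04)
  expect_equal(ideal_ttl(refs, d)$times, (3:10) * 0.8 - 0.04)
  expect_equal(ideal_ttl(refs, cfg0)$times, (3:10) * 0.8)
  expect_error(ideal_ttl(0.8, cfg0), "at least 2")
  expect_length(ideal_ttl(c(0.8, 1.6), cfg0), 0)
})

test_that("derivative maxima sit on the R upstroke", {
  fx <- clean_trace(n_cycles = 8, seed = 2)
  refs <- derivative_max_times(fx$signal, fx$r_truth, cfg0)
  expect_length(refs, 8)
  off <- refs - fx$r_truth$times
  # the steepest upstroke precedes the R peak by a few ticks
  expect_true(all(off > -0.05 & off < 0))
})

test_that("match_edges classifies FP, missed FN and stuck-high FN", {
  truth <- c(1, 2, 3)
  m <- match_edges(truth - 0.02, truth, window = 0.15)
  expect_equal(nrow(m$matched), 3)
  expect_length(m$false_positives, 0)
  expect_equal(nrow(m$false_negatives), 0)

  # one extra mid-diastole edge is exactly one FP
  m2 <- match_edges(c(truth - 0.02, 2.5), truth, window = 0.15)
  expect_equal(nrow(m2$matched), 3)
  expect_equal(m2$false_positives, 2.5)

  # a pulse held high across a truth time with no edge nearby
  tt <- seq(0, 3.5, by = 0.005)
  lv <- as.numeric(tt >= 1.99 & tt < 3.2)
  ttl <- uniform_signal(lv, 0.005, 0, ttl = TRUE)
  m3 <- match_edges(c(0.98, 1.99), truth, ttl = ttl, window = 0.15)
  expect_equal(nrow(m3$matched), 2)
  expect_equal(m3$false_negatives$time, 3)
  expect_equal(m3$false_negatives$type, "stuck_high")

  expect_error(match_edges(1, 1, window = 0), "> 0")
})

test_that("category counts always reconcile", {
  for (seed in 1:20) {
    ev <- with_local_seed(seed, {
      list(e = sort(stats::runif(stats::rpois(1, 8), 0, 10)),
           r = sort(stats::runif(stats::rpois(1, 8), 0, 10)))
    })
    e <- ev$e[!duplicated(ev$e)]; r <- ev$r[!duplicated(ev$r)]
    m <- match_edges(e, r, window = 0.3)
    expect_equal(nrow(m$matched) + length(m$false_positives), length(e))
    expect_equal(nrow(m$matched) + nrow(m$false_negatives), length(r))
  }
})

test_that("error_rates reproduces the published row arithmetic", {
  mk <- function(nfp, nfn) list(
    false_positives = seq_len(nfp),
    false_negatives = data.frame(time = seq_len(nfn),
                                 type = rep("missed", nfn)))
  z <- error_rates(mk(0, 0), 100)
  expect_equal(c(z$fp_pct, z$fn_pct, z$error_pct), c(0, 0, 0))
  expect_equal(error_rates(mk(0, 4), 221)$fn_pct, 1.8099548,
               tolerance = 1e-6)                      # prints as 1.81
  expect_equal(error_rates(mk(1, 0), 136)$fp_pct, 0.7352941,
               tolerance = 1e-6)                      # prints as 0.74
  r <- error_rates(mk(3, 2), 50)
  expect_equal(r$error_pct, r$fp_pct + r$fn_pct)
  expect_error(error_rates(mk(0, 0), 0), "> 0")
})

test_that("timing_stats measures ideal minus actual in ms", {
  ideal <- c(1, 2, 3)
  s <- timing_stats(ideal - c(0.010, 0.020, 0.030), ideal)
  expect_equal(s$dt_mean_ms, 20)
  expect_equal(s$dt_std_ms, 10)
  s2 <- timing_stats(c(1.005, 1.995), c(1, 2))
  expect_equal(s2$dt_mean_ms, 0)
  expect_equal(s2$dt_std_ms, 7.0710678, tolerance = 1e-6)
  # perfect-detector fixed point
  s3 <- timing_stats(ideal, ideal)
  expect_equal(s3$dt_mean_ms, 0)
  expect_equal(s3$dt_std_ms, 0)
  expect_error(timing_stats(1, c(1, 2)), "at least 2")
})

test_that("forcing the pulse across a beat yields only stuck-high FNs", {
  fx <- clean_trace(n_cycles = 10, seed = 6)
  cfg <- detector_config(pulse_width = 1.2)   # longer than the 1-s beat
  run <- suppressWarnings(run_streaming(fx$signal, cfg))
  rep <- evaluate_run(run, fx$r_truth, ecg = fx$signal)
  fn <- rep$match$false_negatives
  expect_gt(nrow(fn), 0)
  expect_true(all(fn$type == "stuck_high"))
  expect_equal(rep$fp_pct, 0)
})

test_that("evaluate_run produces a consistent report row", {
  fx <- simulate_preset("wander", n_cycles = 12, seed = 3)
  run <- suppressWarnings(run_streaming(fx$signal))
  rep <- evaluate_run(run, fx$r_truth, ecg = fx$signal, trace_id = "w12")
  expect_equal(rep$n_cycles, 10)
  expect_equal(rep$error_pct, rep$fp_pct + rep$fn_pct)
  expect_identical(rep$reference, "derivative_max")
  df <- as.data.frame(rep)
  expect_equal(df$trace_id, "w12")
  # truth-referenced evaluation is flagged
  rep2 <- evaluate_run(run, fx$r_truth)
  expect_identical(rep2$reference, "truth")
  expect_error(evaluate_run(run, c(1, 2)), "at least 3")
})

test_that("the overlay plot renders to a file", {
  fx <- clean_trace(n_cycles = 5, seed = 13)
  run <- suppressWarnings(run_streaming(fx$signal))
  refs <- derivative_max_times(fx$signal, fx$r_truth)
  f <- withr::local_tempfile(fileext = ".png")
  plot_overlay(fx$signal, run, ideal = ideal_ttl(refs), file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
})
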