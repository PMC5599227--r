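test_that("canonical HRF peaks at peak_time_s with unit amplitude", {
  fs <- 25.7
  k <- canonical_hrf(fs, peak_time_s = 6, undershoot_time_s = 16)
  expect_equal(max(k), 1)
  expect_lt(abs((which.max(k) - 1) / fs - 6), 1 / fs + 1e-9)
  expect_gte(length(k), round(2 * 16 * fs))
  # main lobe non-negative until after the peak
  expect_true(all(k[seq_len(round(8 * fs))] > -1e-12))
  expect_error(canonical_hrf(0.1), "too low")
})

test_that("simulate_session is seed-deterministic and seed-sensitive", {
  cfg <- fast_sim_config(seed = 11)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$record$hbo, b$record$hbo)
  expect_identical(a$record$hbr, b$record$hbr)
  c <- simulate_session(fast_sim_config(seed = 12))
  expect_gt(max(abs(a$record$hbo - c$record$hbo)), 0.01)
})

test_that("default design yields 100 rest, 50 right, 50 left blocks", {
  cfg <- simulation_config()
  plan <- rep(cfg$session_plan, cfg$n_sessions * cfg$n_experiments)
  expect_equal(as.vector(table(factor(plan, task_levels()))),
               c(100, 50, 50))
  # session arithmetic: 4 blocks x 10 s x 25.7 Hz = 1028 samples >= 2^10
  expect_equal(length(cfg$session_plan) * round(10 * cfg$fs_hz), 1028)
})

test_that("zero noise and zero effect give an identically zero record", {
  cfg <- simulation_config(
    n_experiments = 1L, n_sessions = 1L,
    hrf = list(peak_time_s = 6, undershoot_time_s = 16,
               amplitude_hbo = 0, amplitude_hbr = 0),
    noise = list(cardiac = list(freq_hz = 0.8, amplitude = 0),
                 respiration = list(freq_hz = 0.2, amplitude = 0),
                 mayer = list(freq_hz = 0.1, amplitude = 0),
                 vlf = list(freq_hz = 0.03, amplitude = 0),
                 white_sd = 0))
  sess <- simulate_session(cfg)
  expect_true(all(sess$record$hbo == 0))
  expect_true(all(sess$record$hbr == 0))
})

test_that("task polarity and lateralization are as configured", {
  # right-hand-only plan: every response shares the same spatial gain
  # pattern, so the ipsi/contra ratio is exact even with overlapping
  # response tails (mixed plans let the left response's undershoot bleed
  # into right blocks and vice versa)
  cfg <- simulation_config(
    n_experiments = 1L, seed = 5,
    session_plan = c("rest", "right"),
    noise = list(cardiac = list(freq_hz = 0.8, amplitude = 0),
                 respiration = list(freq_hz = 0.2, amplitude = 0),
                 mayer = list(freq_hz = 0.1, amplitude = 0),
                 vlf = list(freq_hz = 0.03, amplitude = 0),
                 white_sd = 0))
  sess <- simulate_session(cfg)
  trials <- segment_trials(sess$record, sess$onsets_s, sess$labels)
  c3 <- channels_over(sess$record$layout, "C3")   # contralateral to right
  c4 <- channels_over(sess$record$layout, "C4")
  right <- trials$labels == "right"
  mean_abs <- function(sel_trials, chans, chrom_offset = 0) {
    mean(trials$x[sel_trials, , chans + chrom_offset])
  }
  # right-hand blocks: C3 HbO response much larger than ipsilateral C4
  expect_gt(mean_abs(right, c3), 4 * mean_abs(right, c4))
  # HbO positive, HbR negative in activated channels
  expect_gt(mean_abs(right, c3), 0)
  expect_lt(mean_abs(right, c3, chrom_offset = 34), 0)
  # ipsilateral spill is the configured fraction
  expect_equal(mean_abs(right, c4) / mean_abs(right, c3), 0.2,
               tolerance = 1e-9)
})

test_that("noise-only spectrum has peaks at the configured frequencies", {
  cfg <- simulation_config(
    n_channels = 2L, n_experiments = 4L, seed = 9,
    hrf = list(peak_time_s = 6, undershoot_time_s = 16,
               amplitude_hbo = 0, amplitude_hbr = 0),
    noise = list(cardiac = list(freq_hz = 0.8, amplitude = 1),
                 respiration = list(freq_hz = 0.2, amplitude = 1),
                 mayer = list(freq_hz = 0.1, amplitude = 1),
                 vlf = list(freq_hz = 0.03, amplitude = 1),
                 white_sd = 0.05))
  sess <- simulate_session(cfg)
  x <- sess$record$hbo[, 1]
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2)]^2
  freqs <- (seq_len(n %/% 2) - 1) * cfg$fs_hz / n
  bin <- cfg$fs_hz / n
  for (f0 in c(0.8, 0.2, 0.1, 0.03)) {
    # the dominant power within +-5 bins of f0 must lie within one bin
    win <- which(abs(freqs - f0) <= 5 * bin)
    peak_f <- freqs[win[which.max(spec[win])]]
    expect_lt(abs(peak_f - f0), bin + 1e-12)
    # and must dominate the local background away from all components
    bg <- which(freqs > 1.2 & freqs < 2)
    expect_gt(max(spec[win]), 50 * max(spec[bg]))
  }
})

test_that("task-block HbO mean exceeds rest-block mean in activated channels", {
  trials <- fast_trials(seed = 2)
  c3 <- channels_over(default_layout(34), "C3")
  right_mean <- mean(trials$x[trials$labels == "right", , c3])
  rest_mean <- mean(trials$x[trials$labels == "rest", , c3])
  expect_gt(right_mean, rest_mean)
})

test_that("config validation rejects bad parameters", {
  expect_error(simulation_config(hrf = list(peak_time_s = 6,
                                            undershoot_time_s = 16,
                                            amplitude_hbo = 1,
                                            amplitude_hbr = 0.5)),
               "amplitude_hbr")
  expect_error(simulation_config(noise = list(
    cardiac = list(freq_hz = 20, amplitude = 1),
    respiration = list(freq_hz = 0.2, amplitude = 1),
    mayer = list(freq_hz = 0.1, amplitude = 1),
    vlf = list(freq_hz = 0.03, amplitude = 1),
    white_sd = 0)), "Nyquist")
  expect_error(simulation_config(session_plan = c("rest", "jump")),
               "session_plan")
})
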