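test_that("threshold search basics: empty traces, bad thresholds, refractory", {
  fs <- 20000
  expect_length(detect_spikes(numeric(fs), fs, threshold = 1)$spike_times, 0)
  expect_error(detect_spikes(numeric(fs), fs, threshold = -1), "positive")
  expect_error(detect_spikes(rep(2, fs), fs), "constant trace")
  # two supra-threshold peaks 0.4 ms apart with 1 ms refractory: one spike
  x <- numeric(fs)
  x[1000] <- 2
  x[1008] <- 2
  st <- detect_spikes(x, fs, threshold = 1, refractory = 0.001)
  expect_length(st$spike_times, 1)
  expect_equal(st$spike_times, 999 / fs)
})

test_that("template spikes at SNR 10 are found within 0.25 ms of truth", {
  fs <- 20000
  truth <- c(0.10, 0.20, 0.30)
  for (s in 1:5) {
    set.seed(s)
    x <- make_spike_trace(truth, fs, dur = 0.5, amp = 1, noise_sd = 0.1)
    st <- detect_spikes(x, fs)
    expect_length(st$spike_times, 3)
    expect_lt(max(abs(st$spike_times - truth)), 2.5e-4)
    # oracle: exhaustive local-extrema scan with the same threshold
    orc <- oracle_detect(x, fs, st$threshold_used)
    expect_equal(st$spike_times, orc, tolerance = 1e-12)
  }
})

test_that("spike trains are strictly increasing and respect the refractory", {
  fs <- 20000
  for (s in 1:10) {
    set.seed(s)
    x <- make_spike_trace(sort(runif(30, 0.05, 0.45)), fs, noise_sd = 0.08)
    st <- detect_spikes(x, fs, refractory = 0.001)
    if (length(st$spike_times) > 1) {
      expect_true(all(diff(st$spike_times) >= 0.001 - 1e-12))
    }
  }
})

test_that("DC response onset: step input, offset invariance, null input", {
  fs <- 20000
  n <- fs # 1 s
  stim <- 0.6
  dc <- numeric(n)
  drop_at <- round((stim + 0.05) * fs)
  dc[(drop_at + 1):n] <- -5
  on <- detect_response_onset(dc, stim, fs)
  expect_lt(abs(on - (stim + 0.05)), 1.5 / fs)
  # constant offset leaves the onset unchanged
  expect_equal(detect_response_onset(dc + 10, stim, fs), on)
  # no deflection anywhere: no-response
  expect_true(is.na(detect_response_onset(numeric(n), stim, fs)))
  # search window past the end of the recording is rejected
  expect_error(detect_response_onset(dc, 0.999, fs), "past the end")
  expect_error(detect_response_onset(dc, 0.1, fs), "baseline")
})

test_that("response features match their arithmetic definitions", {
  fs <- 20000
  onset <- 1.0
  mk_train <- function(t) structure(list(spike_times = t, threshold_used = 1,
                                         polarity = "positive"),
                                    class = "spike_train")
  dc <- numeric(2 * fs)
  # equal 10 ms ISIs: latency 2 ms, F6AP = 100 Hz
  sp <- mk_train(onset + c(2, 12, 22, 32, 42, 52) / 1000)
  f <- compute_response_features(sp, dc, fs, onset, 0.9)
  expect_equal(f$latency_ms, 2)
  expect_equal(f$f6ap_hz, 100)
  expect_equal(f$n_aps_early, 6)
  # first six ISIs {5,5,5,10,20} ms: mean reciprocal = 150 Hz
  sp2 <- mk_train(onset + cumsum(c(2, 5, 5, 5, 10, 20)) / 1000)
  f2 <- compute_response_features(sp2, dc, fs, onset, 0.9)
  expect_equal(f2$f6ap_hz, 150)
  # fewer than six spikes in the first second: F6AP missing
  sp3 <- mk_train(onset + c(0.002, 0.1, 0.4, 0.8))
  f3 <- compute_response_features(sp3, dc, fs, onset, 0.9)
  expect_true(is.na(f3$f6ap_hz))
  expect_equal(f3$n_aps_early, 4)
  # SPA is the magnitude from baseline to the DC minimum
  dc2 <- numeric(2 * fs)
  dc2[seq(round(1.1 * fs), round(1.4 * fs))] <- -3.2
  f4 <- compute_response_features(mk_train(numeric(0)), dc2, fs, onset, 0.9)
  expect_equal(f4$spa_mv, 3.2, tolerance = 1e-9)
  # missing onset: all features missing
  f5 <- compute_response_features(sp, dc, fs, NA, 0.9)
  expect_true(all(is.na(f5)))
  expect_error(compute_response_features(sp, dc, fs, onset, 0.9,
                                         early_window = -1), "positive")
})

test_that("F6AP scales exactly with uniform ISI compression", {
  onset <- 0
  isis <- c(4, 6, 5, 8, 11) / 1000
  mk <- function(isis) structure(list(spike_times = cumsum(c(0.003, isis)),
                                      threshold_used = 1,
                                      polarity = "positive"),
                                 class = "spike_train")
  dc <- numeric(20000)
  base <- compute_response_features(mk(isis), dc, 20000, onset, 0.01)$f6ap_hz
  for (c_fac in c(1.5, 2, 3.7)) {
    comp <- compute_response_features(mk(isis / c_fac), dc, 20000,
                                      onset, 0.01)$f6ap_hz
    expect_equal(comp, base * c_fac)
  }
})

test_that("LLPR counting: window boundaries and the 295 s convention", {
  # onsets 300 s and 600 s: spike at 302 s falls in the 5 s exclusion
  expect_equal(compute_llpr_count(c(302, 310, 400), 300, 600), 2)
  expect_equal(compute_llpr_count(numeric(0), 300, 600), 0)
  # boundary semantics: [onset + 5, next_onset) spans exactly 295 s
  expect_equal(compute_llpr_count(c(304.9999, 305, 599.9999, 600), 300, 600), 2)
  expect_error(compute_llpr_count(c(1, 2), 300, 304), "exceed")
})

test_that("early-window counts nest: 1 s count >= 100 ms count", {
  gt <- ground_truth_params(noise_sd = 0.05)
  out <- generate_recording(gt, short_design(n_stim = 2), seed = 21)
  f_1s <- extract_features(out$recording, early_window = 1.0)
  f_100 <- extract_features(out$recording, early_window = 0.1)
  expect_true(all(f_1s$n_aps_early >= f_100$n_aps_early))
})

test_that("noiseless end-to-end extraction recovers the ground truth", {
  gt <- ground_truth_params(noise_sd = 0)
  out <- generate_recording(gt, short_design(n_stim = 3), seed = 11)
  ft <- extract_features(out$recording)
  tr <- out$truth
  fs <- 20000
  expect_lte(max(abs(ft$latency_ms - tr$latency_ms)) / 1000, 1.01 / fs)
  expect_equal(ft$f6ap_hz, tr$f6ap_hz, tolerance = 1e-9)
  expect_lt(max(abs(ft$spa_mv / tr$spa_mv - 1)), 0.01)
  expect_equal(ft$n_aps_early, tr$n_aps_early)
  expect_equal(ft$n_aps_llpr[1:2], tr$n_aps_llpr[1:2])
  expect_true(is.na(ft$n_aps_llpr[3]) == is.na(tr$n_aps_llpr[3]))
})
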