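test_that("default schedule yields 24 onsets over 120 min at 5 min spacing", {
  out <- generate_recording(ground_truth_params(), cohort_design(),
                            seed = 1, render = "none")
  expect_equal(length(out$stimulus_onsets), 24)
  expect_equal(out$stimulus_onsets[1], 0)
  expect_equal(out$stimulus_onsets[24], 115 * 60)
  expect_equal(nrow(out$truth), 24)
})

test_that("identical seeds give bit-identical recordings and truth", {
  gt <- ground_truth_params()
  des <- short_design(n_stim = 2)
  a <- generate_recording(gt, des, seed = 99)
  b <- generate_recording(gt, des, seed = 99)
  expect_identical(a$recording$dc, b$recording$dc)
  expect_identical(a$recording$ac, b$recording$ac)
  expect_identical(a$truth, b$truth)
  c <- generate_recording(gt, des, seed = 100)
  expect_false(identical(a$recording$dc, c$recording$dc))
})

test_that("noiseless 6-spike 200 Hz burst is recovered as F6AP = 200 exactly", {
  gt <- ground_truth_params(n_phasic = 6, f_phasic = 200, phasic_shape = Inf,
                            noise_sd = 0, tonic_rate = 0, llpr_rate = 0,
                            spontaneous_rate = 0)
  out <- generate_recording(gt, short_design(n_stim = 1), seed = 5)
  ft <- extract_features(out$recording)
  # 5 ms ISI is an exact number of samples at 20 kHz, so no quantisation
  expect_equal(ft$f6ap_hz, 200)
  expect_equal(out$truth$f6ap_hz, 200)
})

test_that("phasic burst fits within 100 ms of response onset", {
  gt <- ground_truth_params()
  for (s in 1:10) {
    out <- generate_recording(gt, short_design(n_stim = 2), seed = s,
                              render = "none")
    for (i in 1:2) {
      ro <- out$truth$response_onset_s[i]
      phasic <- out$spike_times[out$spike_times >= ro][seq_len(gt$n_phasic)]
      expect_lt(max(phasic) - ro, 0.1)
    }
  }
})

test_that("every ground-truth spike is rendered and detected (conservation)", {
  gt <- ground_truth_params(noise_sd = 0)
  out <- generate_recording(gt, short_design(n_stim = 2), seed = 3)
  det <- detect_spikes(out$recording$ac, 20000, threshold = 0.5)$spike_times
  expect_equal(length(det), length(out$spike_times))
  expect_lte(max(abs(det - out$spike_times)) * 20000, 1)
})

test_that("drift is linear in time and clamps rates at zero with a flag", {
  gt <- ground_truth_params(drift = c(f6ap_hz = -60), noise_sd = 0,
                            phasic_shape = Inf, spontaneous_rate = 0,
                            tonic_rate = 0, llpr_rate = 0)
  # f_phasic 150 -> 0 within 2.5 min; later stimuli are clamped
  des <- cohort_design(stimulus_interval = 60, recording_duration = 5,
                       first_stimulus = 1, sampling_rate = 2000)
  out <- generate_recording(gt, des, seed = 1, render = "none")
  expect_false(out$truth$clamped[1])
  expect_true(any(out$truth$clamped))
  drifted <- ssrquant:::drifted_params(gt, 1)
  expect_equal(unname(drifted$values[["f_phasic"]]), 90)
  expect_error(ground_truth_params(drift = c(bogus = 1)), "bogus")
})

test_that("cohort bookkeeping: labels, counts, and paired day structure", {
  groups <- expand.grid(condition = c("ctrl", "drug"),
                        zt = c("ZT1-3", "ZT9-11"))
  groups$n_animals <- 3
  des <- cohort_design(groups = groups, stimulus_interval = 20,
                       recording_duration = 1.5, first_stimulus = 1,
                       sampling_rate = 2000)
  gts <- list(ctrl = ground_truth_params(), drug = ground_truth_params())
  coh <- generate_cohort(des, gts, seed = 8)
  expect_equal(length(coh$animals), 12)
  expect_equal(nrow(unique(coh$truth[c("condition", "zt")])), 4)
  expect_setequal(unique(coh$truth$condition), c("ctrl", "drug"))
  # missing group parameters are rejected with the offending label
  expect_error(generate_cohort(des, gts["ctrl"], seed = 1), "drug")

  pdes <- cohort_design(groups = data.frame(condition = "toxin",
                                            zt = "ZT1-3", n_animals = 2),
                        paired = TRUE, stimulus_interval = 20,
                        first_stimulus = 1, sampling_rate = 2000)
  pco <- generate_cohort(pdes, list(control = ground_truth_params(),
                                    toxin = ground_truth_params()), seed = 2)
  expect_equal(length(pco$animals), 4) # two days per animal
  d1 <- pco$truth[pco$truth$day == 1, ]
  d2 <- pco$truth[pco$truth$day == 2, ]
  # three control stimulations on day 1, six treatment stimulations on day 2
  expect_equal(as.integer(table(d1$animal_id)), c(3L, 3L))
  expect_equal(as.integer(table(d2$animal_id)), c(6L, 6L))
  expect_true(all(d1$condition == "control"))
  expect_true(all(d2$condition == "toxin"))
})

test_that("qPCR generator honours the replicate design and null identities", {
  # 2 target genes x 3 ZT x 3 biological x 3 technical = 54 target rows
  d <- generate_qpcr_dataset(c("PLCb4", "tim"), sigma_ct = 0.1, seed = 1)
  expect_equal(sum(d$gene %in% c("PLCb4", "tim")), 54)
  expect_setequal(unique(d$gene), c("PLCb4", "tim", "RPS13", "G3PDH"))
  expect_equal(max(d$technical_replicate), 3)
  expect_equal(max(d$biological_replicate), 3)

  # all-null, noise-free: every relative expression is exactly 1
  d0 <- generate_qpcr_dataset("g1", sigma_ct = 0, seed = 1)
  expr <- compute_relative_expression(d0, "g1")
  expect_equal(expr$fold_change, rep(1, 9))

  # programmed fold change 2 at ZT17, sigma = 0: recovered exactly
  d2 <- generate_qpcr_dataset("g1", fold_changes = list(g1 = c(ZT17 = 2)),
                              sigma_ct = 0, seed = 1)
  e2 <- compute_relative_expression(d2, "g1")
  expect_equal(e2$fold_change[e2$zt == "ZT17"], rep(2, 3))
  expect_equal(e2$fold_change[e2$zt == "ZT1"], rep(1, 3))

  expect_error(generate_qpcr_dataset("g1", fold_changes = list(g1 = c(ZT9 = -1))),
               "positive")
  expect_error(generate_qpcr_dataset("g1", sigma_ct = -0.1))
})
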