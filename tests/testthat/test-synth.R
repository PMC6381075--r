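test_that("condition labelling matches the probe/response contingency for all 15 combinations", {
  expected <- rbind(
    c("target_target", "old_old", "correct"),
    c("target_target", "old_new", "error"),
    c("target_target", "new_old", "error"),
    c("target_target", "new_new", "error"),
    c("target_target", "none", "unanswered"),
    c("target_lure", "old_new", "correct"),
    c("target_lure", "old_old", "false_memory"),
    c("target_lure", "new_old", "error"),
    c("target_lure", "new_new", "error"),
    c("target_lure", "none", "unanswered"),
    c("lure_target", "new_old", "correct"),
    c("lure_target", "old_old", "false_memory"),
    c("lure_target", "old_new", "error"),
    c("lure_target", "new_new", "error"),
    c("lure_target", "none", "unanswered"))
  expect_identical(derive_condition(expected[, 1], expected[, 2]),
                   expected[, 3])
  # false memory is impossible without a lure probe
  expect_false("false_memory" %in%
                 derive_condition(rep("target_target", 5),
                                  c("old_old", "old_new", "new_old",
                                    "new_new", "none")))
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(condition_probs = c(correct = 0.5,
                                                false_memory = 0.2,
                                                error = 0.2,
                                                unanswered = 0.2)),
               "sum to 1")
  expect_error(synth_config(sampling_rate = 100), ">= 250")
  expect_error(synth_config(channels = c("O1", "Oz")), "layout")
  cfg <- synth_config()
  expect_s3_class(cfg, "wm_synth_config")
  expect_equal(sum(cfg$condition_probs), 1, tolerance = 1e-9)
})

test_that("degenerate condition probabilities give an all-correct table", {
  cfg <- synth_config(n_trials = 40,
                      condition_probs = c(correct = 1, false_memory = 0,
                                          error = 0, unanswered = 0),
                      seed = 3)
  beh <- generate_behavior(cfg, 1)
  expect_true(all(beh$condition == "correct"))
  expect_true(all(!is.na(beh$rt_s)))
})

test_that("empirical condition rates match the configured probabilities within 3 binomial SE", {
  cfg <- synth_config(n_trials = 10000, seed = 11)
  beh <- generate_behavior(cfg, 1)
  p <- cfg$condition_probs
  for (cd in names(p)) {
    se <- sqrt(p[[cd]] * (1 - p[[cd]]) / 10000)
    expect_lt(abs(mean(beh$condition == cd) - p[[cd]]), 3 * se + 1e-12)
  }
})

test_that("behaviour generation is deterministic in (seed, subject) and balanced over probes", {
  cfg <- synth_config(n_trials = 300, seed = 7)
  b1 <- generate_behavior(cfg, 2)
  b2 <- generate_behavior(cfg, 2)
  expect_identical(b1, b2)
  b3 <- generate_behavior(cfg, 3)
  expect_false(identical(b1$condition, b3$condition))
  counts <- table(b1$probe_type)
  expect_lte(diff(range(counts)), 2 + sum(b1$condition == "false_memory"))
  # lure probes only for false-memory trials
  expect_true(all(b1$probe_type[b1$condition == "false_memory"] !=
                    "target_target"))
  expect_true(all((b1$response == "none") ==
                    (b1$condition == "unanswered")))
})

test_that("error response times are stochastically slower than correct ones", {
  cfg <- synth_config(n_trials = 8000, seed = 5)
  beh <- generate_behavior(cfg, 1)
  med <- tapply(beh$rt_s, beh$condition, median, na.rm = TRUE)
  expect_gt(med[["error"]], med[["correct"]])
  expect_gt(med[["error"]], med[["false_memory"]])
  # medians should approximate the configured targets (about 1.145 / 1.330 s)
  expect_equal(unname(med[["correct"]]), 1.145, tolerance = 0.05)
  expect_equal(unname(med[["error"]]), 1.330, tolerance = 0.06)
  expect_true(all(beh$rt_s[!is.na(beh$rt_s)] > 0 &
                    beh$rt_s[!is.na(beh$rt_s)] <= 4))
})

test_that("subject ICFs sit on the even 10-26 Hz grid and recordings are reproducible", {
  cfg <- synth_config(n_trials = 6, seed = 13)
  icfs <- vapply(1:20, function(s) subject_icf(cfg, s), 0)
  expect_true(all(icfs %in% seq(10, 26, 2)))
  expect_gt(length(unique(icfs)), 3)
  beh <- generate_behavior(cfg, 1)
  r1 <- generate_recording(cfg, beh, 1)
  r2 <- generate_recording(cfg, beh, 1)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$events, r2$events)
})

test_that("event spacing respects the trial timeline", {
  cfg <- synth_config(n_trials = 30, seed = 2)
  beh <- generate_behavior(cfg, 1)
  rec <- generate_recording(cfg, beh, 1)
  fs <- rec$sfreq
  expect_equal(nrow(rec$events), 30)
  # a full epoch window must fit around every event: >= 1 s before
  # (fixation) and >= 2 s after (encoding 1 s + retention >= 1 s)
  gaps <- diff(rec$events$sample) / fs
  expect_true(all(gaps >= 3))
  expect_gte(min(rec$events$sample) / fs, 1)
  expect_lte(max(rec$events$sample) + 2 * fs, ncol(rec$signal))
})

test_that("a lone theta burst carries the expected narrowband power", {
  cfg <- synth_config(n_trials = 3, seed = 21)
  cfg$noise$rms <- 0; cfg$noise$artifact_prob <- 0
  cfg$eog$rate <- 0; cfg$eog$amp <- 0
  cfg$alpha_bg$amp <- 0
  cfg$icf_burst$amp[] <- 0
  cfg$theta_burst$freq <- 6            # exact analysis bin
  cfg$theta_burst$window <- c(0, 1)
  A <- cfg$theta_burst$amp[["correct"]]
  cfg$theta_burst$amp[] <- A           # condition-independent
  beh <- generate_behavior(cfg, 1)
  rec <- generate_recording(cfg, beh, 1)
  tf <- compute_tfr(epoch_and_demean(rec), channels = "Oz")
  # at the Hanning envelope's peak the 500 ms analysis window sees a nearly
  # pure sinusoid of amplitude ~A: power is bounded by A^2/2 and dominated
  # by the 6 Hz bin
  p6 <- tf$power[1, 1, tf$freqs == 6, which.min(abs(tf$times - 0.5))]
  expect_gt(p6, 0.5 * A^2 / 2)
  expect_lte(p6, 1.01 * A^2 / 2)
  off <- mean(tf$power[1, 1, tf$freqs >= 16, ])
  expect_gt(p6 / off, 100)
})

test_that("retention-window spectrum peaks at the subject's planted ICF", {
  cfg <- synth_config(n_trials = 72, seed = 17)
  for (s in 1:3) {
    out <- quiet_subject_tfr(cfg, s, channels = c("P4", "P8", "O2"))
    prof <- apply(out$tfr$power[, , , out$tfr$times >= 1.5], 3, mean)
    cand <- out$tfr$freqs >= 10 & out$tfr$freqs <= 26
    expect_equal(out$tfr$freqs[cand][which.max(prof[cand])],
                 out$recording$icf)
  }
})

test_that("datasets round-trip through the BrainVision and CSV readers", {
  cfg <- synth_config(n_trials = 5, seed = 19)
  behs <- lapply(1:2, function(s) generate_behavior(cfg, s))
  recs <- lapply(1:2, function(s) generate_recording(cfg, behs[[s]], s))
  td <- withr::local_tempdir()
  write_dataset(recs, behs, td)
  ds <- read_dataset(td)
  expect_identical(ds$recordings[[1]]$events$sample, recs[[1]]$events$sample)
  expect_identical(ds$recordings[[2]]$channel_names, recs[[2]]$channel_names)
  # int16 dialect quantises at 0.1 uV resolution
  expect_lt(max(abs(ds$recordings[[1]]$signal - recs[[1]]$signal)), 0.05 + 1e-9)
  expect_identical(ds$behaviors[[2]]$condition, behs[[2]]$condition)
  expect_equal(ds$behaviors[[1]]$rt_s, behs[[1]]$rt_s, tolerance = 1e-9)

  # float32 dialect is tighter
  td2 <- withr::local_tempdir()
  write_dataset(recs, behs, td2, format = "float32")
  ds2 <- read_dataset(td2)
  expect_lt(max(abs(ds2$recordings[[1]]$signal - recs[[1]]$signal)), 1e-3)

  # empty cohort: manifest only
  td3 <- withr::local_tempdir()
  mf <- write_dataset(list(), list(), td3)
  expect_equal(mf$n_subjects, 0)
  expect_identical(sort(list.files(td3)), "manifest.json")
})

test_that("behaviour reader rejects tables inconsistent with the contingency mapping", {
  cfg <- synth_config(n_trials = 8, seed = 23)
  beh <- generate_behavior(cfg, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  bad <- beh
  bad$condition[1] <- if (bad$condition[1] == "error") "correct" else "error"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_behavior(f), "inconsistent")
})
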