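test_that("the degenerate constant configuration yields exact beats", {
  cfg <- clean_config(duration = 8, mean_ibi = 800, lf_osc = c(0.1, 0),
                      hf_osc = c(0.25, 0), ibi_jitter_sd = 0)
  s <- generate_ibi_series(cfg)
  expect_equal(s$beat_times, seq(0, 8, by = 0.8))
  expect_equal(s$ibi_ms, rep(800, 10))
})

test_that("the IBI generator is seeded and rejects impossible configurations", {
  cfg <- synth_config(duration = 60, seed = 4)
  a <- generate_ibi_series(cfg)
  b <- generate_ibi_series(cfg)
  expect_identical(a, b)

  cfg2 <- synth_config(duration = 60, seed = 5)
  expect_false(identical(generate_ibi_series(cfg2)$ibi_ms, a$ibi_ms))

  bad <- synth_config(duration = 60, mean_ibi = 100, lf_osc = c(0.1, 300))
  expect_error(generate_ibi_series(bad), "rejected configuration")
})

test_that("the generated IBI spectrum carries the configured oscillation", {
  cfg <- clean_config(duration = 600, lf_osc = c(0.1, 40), hf_osc = c(0.25, 0),
                      ibi_jitter_sd = 0, seed = 6)
  s <- generate_ibi_series(cfg)
  ls <- lomb_scargle(s$ibi_ms, times = s$beat_times[-1])
  expect_lt(abs(ls$freq[which.max(ls$power)] - 0.1), 0.0015)
})

test_that("band powers respond monotonically to the configured amplitudes", {
  lf_power <- hf_power <- numeric(3)
  for (i in 1:3) {
    amp <- c(10, 30, 60)[i]
    cfg <- clean_config(duration = 300, lf_osc = c(0.1, amp),
                        hf_osc = c(0.25, amp / 2), ibi_jitter_sd = 2, seed = 30)
    s <- generate_ibi_series(cfg)
    ls <- lomb_scargle(s$ibi_ms, times = s$beat_times[-1])
    lf_power[i] <- ls$lf; hf_power[i] <- ls$hf
  }
  expect_true(all(diff(lf_power) > 0))
  expect_true(all(diff(hf_power) > 0))
})

test_that("recordings satisfy their beat-wise invariants and are reproducible", {
  cfg <- synth_config(duration = 90, seed = 14)
  sr <- generate_recording(cfg)
  nb <- length(sr$true_rptt)
  expect_length(sr$true_sbp, nb)
  expect_length(sr$true_dbp, nb)
  expect_length(sr$true_beat_times, nb)
  expect_true(all(sr$true_sbp > sr$true_dbp))
  expect_true(all(sr$true_dbp > 0))
  expect_true(all(sr$true_rptt > 0))
  expect_true(all(sr$true_rptt < c(diff(sr$true_beat_times), Inf)))

  sr2 <- generate_recording(cfg)
  expect_identical(sr$recording$ppg, sr2$recording$ppg)
  expect_identical(sr$true_sbp, sr2$true_sbp)
})

test_that("a 60-s recording at 75 beats/min yields the expected beat count downstream", {
  cfg <- clean_config(duration = 60, mean_ibi = 800, lf_osc = c(0.1, 0),
                      hf_osc = c(0.25, 0), ibi_jitter_sd = 0, seed = 1)
  sr <- generate_recording(cfg)
  ann <- detect_peaks(sr$recording)
  expect_gte(length(ann$peak_times), 74)
  expect_lte(length(ann$peak_times), 76)
})

test_that("the noise-free model round trip recovers the generated pressures", {
  cfg <- clean_config(duration = 120, rptt = 0.25, seed = 7)
  sr <- generate_recording(cfg)
  row <- run_subject(sr$recording,
                     run_config(cal_window_s = 30, test_window_s = 60,
                                sdann_segment_s = 20))
  expect_lt(abs(row$model_sbp - row$true_sbp), 1)
  expect_lt(abs(row$model_dbp - row$true_dbp), 1)
})

test_that("cohort generation enforces its contract and couples ka to pulse pressure", {
  expect_error(generate_cohort(1), "at least 2")

  coh <- generate_cohort(4, synth_config(duration = 60), seed = 3)
  expect_length(coh$recordings, 4)
  expect_equal(nrow(coh$manifest), 4)

  # equal R-PTT, different ka -> different pulse pressure
  i <- order(coh$manifest$ka)[c(1, 4)]
  pa <- predict_bp(0.26, coh$recordings[[i[1]]]$true_params)
  pb <- predict_bp(0.26, coh$recordings[[i[2]]]$true_params)
  expect_lt(pa$sbp - pa$dbp, pb$sbp - pb$dbp)

  coh2 <- generate_cohort(4, synth_config(duration = 60), seed = 3)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$recordings[[2]]$true_sbp, coh2$recordings[[2]]$true_sbp)
})

test_that("noise-free calibration recovers the true ka within one percent", {
  tmpl <- clean_config(duration = 120, ibi_jitter_sd = 0)
  coh <- generate_cohort(4, tmpl, seed = 3, cal_bp_error_sd = 0)
  rc <- run_config(cal_window_s = 30, test_window_s = 60, sdann_segment_s = 20)
  for (i in 1:4) {
    row <- suppressWarnings(run_subject(coh$recordings[[i]]$recording, rc))
    ka_est <- attr(row, "log")$params$ka
    expect_lt(abs(ka_est / coh$manifest$ka[i] - 1), 0.01)
  }
})

test_that("cohorts written to disk round-trip through the manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(3, synth_config(duration = 45), seed = 8, dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3)
  back <- read_recording(man$file[2])
  expect_identical(back$ppg, coh$recordings[[2]]$recording$ppg)
  expect_equal(back$subject, "s02")
})
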