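test_that("staging rule order: high EMG tone wins regardless of EEG", {
  set.seed(10)
  eeg <- channel_trace("EEG", "EEG", "PARIETAL", 250,
                       rnorm(250 * 120, sd = 1))
  emg <- channel_trace("EMG", "EMG", "NECK", 250,
                       rnorm(250 * 120, sd = 200))
  h <- score_sleep(eeg, emg)
  expect_true(all(h$stages == "WAKE"))
  short <- channel_trace("EEG", "EEG", "PARIETAL", 250, rnorm(250))
  expect_error(score_sleep(short, short), "shorter than one epoch")
})

test_that("an all-NREM synthetic recording is scored as NREM", {
  p <- sim_params(duration_s = 240,
                  bout_means_s = c(WAKE = 0.001, NREM = 1e6, REM = 0.001))
  h_true <- hypnogram(rep("NREM", 60), 4)
  eeg <- synthesize_background(h_true, list(name = "EEG", modality = "EEG",
                                            region = "PARIETAL", rate = 250),
                               p, seed = 2)
  emg <- synthesize_background(h_true, list(name = "EMG", modality = "EMG",
                                            region = "NECK", rate = 250),
                               p, seed = 2)
  h <- score_sleep(eeg, emg)
  expect_gte(mean(h$stages == "NREM"), 0.85)
})

test_that("staging is unaffected by channel renaming", {
  ses <- shared_session()
  eeg <- get_channel(ses$record, "EEG")
  emg <- get_channel(ses$record, "EMG")
  h1 <- score_sleep(eeg, emg)
  eeg$name <- "totally_different"
  emg$name <- "names"
  h2 <- score_sleep(eeg, emg)
  expect_identical(h1$stages, h2$stages)
})

test_that("stage spectra are normalized and localize injected rhythms", {
  ses <- shared_session()
  eeg <- get_channel(ses$record, "EEG")
  h <- ses$truth$hypnogram
  for (st in intersect(c("WAKE", "NREM", "REM"), unique(h$stages))) {
    sp <- stage_spectrum(eeg, h, st)
    expect_equal(sum(sp$relative_power), 1, tolerance = 1e-6)
    expect_true(all(sp$relative_power >= 0))
  }
  if ("REM" %in% h$stages) {
    sp <- stage_spectrum(eeg, h, "REM")
    f_peak <- sp$frequencies[which.max(sp$relative_power)]
    expect_gte(f_peak, 6)
    expect_lte(f_peak, 9)
  }
  none <- hypnogram(rep("WAKE", length(h$stages)), h$epoch_length_s)
  expect_error(stage_spectrum(eeg, none, "REM"), "REM")
})

test_that("band powers partition the spectrum and match analytic cases", {
  ses <- shared_session()
  sp <- stage_spectrum(get_channel(ses$record, "EEG"),
                       ses$truth$hypnogram, "NREM")
  full <- band_power(sp, bands = list(all_lo = c(0.5, 15),
                                      all_hi = c(15, 30.001)))
  expect_equal(sum(full$relative_power), 1, tolerance = 1e-6)

  flat <- structure(list(stage = "WAKE", frequencies = seq(1, 20, by = 1),
                         relative_power = rep(1 / 20, 20), n_epochs = 1),
                    class = "stage_spectrum")
  bp <- band_power(flat, bands = list(half = c(0.5, 10.5)))
  expect_equal(bp$relative_power, 0.5, tolerance = 1e-9)
  expect_error(band_power(flat, bands = list(bad = c(50, 60))),
               "outside")

  # synthetic NREM is delta-dominated
  bp2 <- band_power(sp)
  expect_gt(bp2$relative_power[bp2$band == "delta"],
            bp2$relative_power[bp2$band == "beta"])
})

test_that("architecture summaries conserve time", {
  h <- hypnogram(rep("WAKE", 1800), 4)  # 2 h
  arch <- architecture_summary(h)
  expect_equal(arch$totals$minutes[arch$totals$stage == "WAKE"], 120)
  expect_equal(sum(arch$totals$minutes), 120)

  ses <- shared_session()
  h2 <- ses$truth$hypnogram
  arch2 <- architecture_summary(h2)
  expect_equal(sum(arch2$totals$minutes),
               hypnogram_duration(h2) / 60)
  hourly <- arch2$hourly
  for (hr in unique(hourly$hour)) {
    tot <- sum(hourly$minutes[hourly$hour == hr])
    expect_lte(tot, 60 + 1e-9)
  }
  full_hours <- floor(hypnogram_duration(h2) / 3600)
  if (full_hours >= 1) {
    for (hr in seq_len(full_hours) - 1) {
      expect_equal(sum(hourly$minutes[hourly$hour == hr]), 60)
    }
  }
  expect_equal(sum(arch2$phase$minutes), sum(arch2$totals$minutes))
})
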