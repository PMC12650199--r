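test_that("state sequences have the right epoch count and forbidden moves", {
  p <- sim_params(duration_s = 40)
  h <- sample_state_sequence(p, seed = 1)
  expect_length(h$stages, 10)
  expect_error(sim_params(duration_s = 40,
                          bout_means_s = c(WAKE = 200, NREM = 0, REM = 0)),
               "bout means")
  # WAKE -> REM never occurs; REM entered only from NREM
  for (seed in 1:20) {
    h <- sample_state_sequence(sim_params(duration_s = 4000), seed)
    s <- h$stages
    trans <- paste(s[-length(s)], s[-1])
    expect_false(any(trans == "WAKE REM"))
  }
})

test_that("NREM bout lengths converge to the configured mean", {
  p <- sim_params(duration_s = 10000)
  lens <- c()
  for (seed in 1:50) {
    h <- sample_state_sequence(p, seed)
    r <- rle(h$stages)
    lens <- c(lens, r$lengths[r$values == "NREM"] * p$epoch_length_s)
  }
  expect_gt(length(lens), 50)
  expect_lt(abs(mean(lens) - p$bout_means_s[["NREM"]]),
            0.15 * p$bout_means_s[["NREM"]])
})

test_that("background traces carry the stage-dependent signatures", {
  p <- sim_params(duration_s = 240)
  h_wake <- hypnogram(rep("WAKE", 60), 4)
  h_rem <- hypnogram(rep("REM", 60), 4)
  h_nrem <- hypnogram(rep("NREM", 60), 4)
  emg_spec <- list(name = "EMG", modality = "EMG", region = "NECK",
                   rate = 250)
  eeg_spec <- list(name = "EEG", modality = "EEG", region = "PARIETAL",
                   rate = 250)
  emg_w <- synthesize_background(h_wake, emg_spec, p, seed = 3)
  emg_r <- synthesize_background(h_rem, emg_spec, p, seed = 3)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(emg_w$samples), 2 * rms(emg_r$samples))

  eeg_w <- synthesize_background(h_wake, eeg_spec, p, seed = 4)
  eeg_n <- synthesize_background(h_nrem, eeg_spec, p, seed = 4)
  rel_delta <- function(tr, h) {
    sp <- stage_spectrum(tr, h, h$stages[1])
    band_power(sp)$relative_power[1]
  }
  expect_gt(rel_delta(eeg_n, h_nrem), rel_delta(eeg_w, h_wake))

  again <- synthesize_background(h_wake, emg_spec, p, seed = 3)
  expect_identical(again$samples, emg_w$samples)
})

test_that("zero densities give a pure background with empty ground truth", {
  p <- sim_params(duration_s = 120,
                  densities_per_min = c(ripple = 0, delta = 0, spindle = 0),
                  coupling_prob_rd = 0, coupling_prob_ds = 0)
  ses <- generate_session(p, seed = 5)
  expect_equal(nrow(ses$truth$events), 0)
  h <- ses$truth$hypnogram
  bg <- synthesize_background(h, list(name = "LFP_CA1", modality = "LFP",
                                      region = "CA1", rate = 1000), p,
                              seed = 5)
  expect_equal(get_channel(ses$record, "LFP", "CA1")$samples, bg$samples)
})

test_that("forced D-S coupling gives every delta a spindle child in window", {
  p <- sim_params(duration_s = 1800,
                  densities_per_min = c(ripple = 0, delta = 6, spindle = 0),
                  coupling_prob_rd = 0, coupling_prob_ds = 1,
                  bout_means_s = c(WAKE = 30, NREM = 600, REM = 30))
  truth <- schedule_events(sample_state_sequence(p, 11), p, seed = 11)
  deltas <- truth[truth$kind == "DELTA", ]
  spindles <- truth[truth$kind == "SPINDLE", ]
  expect_gt(nrow(deltas), 20)
  expect_equal(nrow(spindles), nrow(deltas))
  lag <- spindles$peak_s[match(deltas$event_id,
                               spindles$parent_event_id)] - deltas$peak_s
  expect_true(all(lag >= 0.2 - 1e-9 & lag <= 0.8 + 1e-9))
})

test_that("all injected event peaks lie in NREM epochs", {
  ses <- shared_session()
  st <- stage_at(ses$truth$hypnogram, ses$truth$events$peak_s)
  expect_true(all(st == "NREM"))
})

test_that("injected amplitudes calibrate to their envelope targets", {
  ses <- shared_session()
  p <- sim_params(duration_s = 480)
  tr <- ses$truth$events
  lfp <- get_channel(ses$record, "LFP", "CA1")
  fs <- lfp$sampling_rate_hz
  env <- normalized_envelope(lfp, c(100, 250), "square_lowpass",
                             lowpass_hz = 30)
  ripples <- tr[tr$kind == "RIPPLE", ]
  expect_gt(nrow(ripples), 50)
  peaks <- vapply(seq_len(nrow(ripples)), function(k) {
    i1 <- max(1, round(ripples$start_s[k] * fs))
    i2 <- min(length(env), round(ripples$end_s[k] * fs))
    max(env[i1:i2])
  }, numeric(1))
  target <- p$amplitude_sd[["ripple"]]
  expect_lt(abs(mean(peaks) - target), 0.15 * target)
})

test_that("session generation is deterministic in (params, seed)", {
  p <- sim_params(duration_s = 120)
  s1 <- generate_session(p, seed = 9)
  s2 <- generate_session(p, seed = 9)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(s1$truth$hypnogram$stages, s2$truth$hypnogram$stages)
  expect_identical(get_channel(s1$record, "LFP", "MPFC")$samples,
                   get_channel(s2$record, "LFP", "MPFC")$samples)
  expect_error(sim_params(duration_s = 0), "duration_s")
})

test_that("behavior tables express the configured object preference", {
  specs <- list(list(group = "null", n = 200, multiplier = 1),
                list(group = "pref", n = 200, multiplier = 3))
  tb <- generate_behavior_table(specs, seed = 2)
  expect_equal(nrow(tb), 400)
  di <- discrimination_index(tb$t_displaced_s, tb$t_stationary_s)
  expect_lt(abs(mean(di[tb$group == "null"])), 5)
  expect_gt(mean(di[tb$group == "pref"]), 0)
  tb2 <- generate_behavior_table(specs, seed = 2)
  expect_identical(tb, tb2)
})
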