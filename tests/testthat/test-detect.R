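make_lfp <- function(x, fs = 1000, region = "CA1") {
  channel_trace(paste0("LFP_", region), "LFP", region, fs, x)
}

test_that("zero-phase bandpass passes, stops and preserves symmetry", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  s150 <- sin(2 * pi * 150 * t)
  y <- bandpass_zero_phase(s150, c(100, 250), rate = fs)
  mid <- 2000:8000
  expect_lt(abs(sd(y[mid]) / sd(s150[mid]) - 1), 0.05)

  s10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_zero_phase(s10, c(100, 250), rate = fs)
  expect_lt(sd(y10[mid]) / sd(s10[mid]), 0.05)

  # filtering a reversed input equals reversing the filtered input;
  # the comparison excludes the edge transients of the finite recording
  x <- fixture_noise(4000, fs, seed = 3)
  a <- bandpass_zero_phase(rev(x), c(5, 40), rate = fs)
  b <- rev(bandpass_zero_phase(x, c(5, 40), rate = fs))
  mid2 <- 601:3400
  expect_lt(max(abs(a[mid2] - b[mid2])) / sd(b[mid2]), 1e-3)

  expect_error(bandpass_zero_phase(x, c(100, 600), rate = fs), "Nyquist")
})

test_that("normalized envelopes are z-scored and scale invariant", {
  x <- fixture_noise(20000, 1000, seed = 4)
  for (m in c("square_lowpass", "rms_gauss")) {
    env <- normalized_envelope(x, c(9, 17), m, rate = 1000)
    expect_equal(mean(env), 0, tolerance = 1e-9)
    expect_equal(sd(env), 1, tolerance = 1e-9)
    env10 <- normalized_envelope(10 * x, c(9, 17), m, rate = 1000)
    expect_equal(env, env10, tolerance = 1e-9)
  }
  expect_error(normalized_envelope(rep(1, 5000), c(9, 17), rate = 1000),
               "degenerate")
})

test_that("detected events respect their duration bounds exactly", {
  ses <- shared_session()
  ca1 <- get_channel(ses$record, "LFP", "CA1")
  pfc <- get_channel(ses$record, "LFP", "MPFC")
  rp <- detect_ripples(ca1)
  expect_true(all(rp$duration_ms >= 30 - 1e-6 & rp$duration_ms <= 100 + 1e-6))
  dl <- detect_delta(pfc)
  expect_true(all(dl$duration_ms >= 150 - 1e-6 &
                    dl$duration_ms <= 500 + 1e-6))
  sp <- detect_spindles(pfc)
  expect_true(all(sp$duration_ms > 500 & sp$duration_ms <= 3000 + 1e-6))
  for (tab in list(rp, dl, sp)) {
    if (nrow(tab)) {
      expect_true(all(tab$start_s <= tab$peak_s & tab$peak_s <= tab$end_s))
    }
  }
})

test_that("raising any threshold never increases the event count", {
  ses <- shared_session()
  ca1 <- get_channel(ses$record, "LFP", "CA1")
  pfc <- get_channel(ses$record, "LFP", "MPFC")
  n_rip <- vapply(c(2.5, 3, 4, 5), function(thr)
    nrow(detect_ripples(ca1, ripple_params(peak_threshold_sd = thr,
                                           boundary_threshold_sd = thr))),
    numeric(1))
  expect_true(all(diff(n_rip) <= 0))
  n_del <- vapply(c(1.5, 2, 3), function(thr)
    nrow(detect_delta(pfc, delta_params(peak_threshold_sd = thr))),
    numeric(1))
  expect_true(all(diff(n_del) <= 0))
  n_spi <- vapply(c(4, 5, 6), function(thr)
    nrow(detect_spindles(pfc, spindle_params(peak_threshold_sd = thr))),
    numeric(1))
  expect_true(all(diff(n_spi) <= 0))
})

test_that("detections are invariant to positive rescaling of the trace", {
  ses <- shared_session()
  ca1 <- get_channel(ses$record, "LFP", "CA1")
  scaled <- ca1
  scaled$samples <- 7.3 * scaled$samples
  a <- detect_ripples(ca1)
  b <- detect_ripples(scaled)
  expect_equal(a$peak_s, b$peak_s, tolerance = 1e-9)
  expect_equal(a$peak_z, b$peak_z, tolerance = 1e-6)
})

test_that("detectors agree exactly with a sample-scan reference", {
  fs <- 1000
  rp_par <- ripple_params()
  sp_par <- spindle_params(min_dur_ms = 200)  # more candidates at 6 s
  dl_par <- delta_params()
  for (seed in 1:30) {
    x <- fixture_noise(6 * fs, fs, alpha = 1.5, seed = seed)
    lfp <- make_lfp(x, fs)
    got <- detect_ripples(lfp, rp_par)
    want <- bf_times(bf_detect_ripples(lfp, rp_par), fs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_s, want$start_s, tolerance = 1e-9)
      expect_equal(got$peak_s, want$peak_s, tolerance = 1e-9)
      expect_equal(got$end_s, want$end_s, tolerance = 1e-9)
    }
    got <- detect_delta(make_lfp(x, fs, "MPFC"), dl_par)
    want <- bf_times(bf_detect_delta(make_lfp(x, fs, "MPFC"), dl_par), fs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) expect_equal(got$peak_s, want$peak_s, tolerance = 1e-9)
    got <- detect_spindles(make_lfp(x, fs, "MPFC"), sp_par)
    want <- bf_times(bf_detect_spindles(make_lfp(x, fs, "MPFC"), sp_par),
                     fs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) expect_equal(got$peak_s, want$peak_s, tolerance = 1e-9)
  }
})

test_that("sleep restriction and event rates behave as specified", {
  ses <- shared_session()
  tr <- ses$truth$events
  h <- ses$truth$hypnogram
  all_wake <- hypnogram(rep("WAKE", length(h$stages)), h$epoch_length_s)
  expect_equal(nrow(restrict_to_sleep(tr, all_wake, "NREM")), 0)
  expect_equal(nrow(restrict_to_sleep(tr, h, c("WAKE", "NREM", "REM"))),
               nrow(tr))
  expect_equal(nrow(restrict_to_sleep(tr, h, "NREM")), nrow(tr))

  outside <- tr
  outside$start_s <- outside$start_s + hypnogram_duration(h)
  outside$peak_s <- outside$peak_s + hypnogram_duration(h)
  outside$end_s <- outside$end_s + hypnogram_duration(h)
  expect_error(restrict_to_sleep(event_table(outside), h),
               "outside hypnogram")

  # 30 events in 10 NREM minutes -> incidence 3/min
  h10 <- hypnogram(rep("NREM", 150), 4)
  ev <- point_events(seq(10, 590, length.out = 30), "DELTA")
  er <- event_rates(ev, h10, "NREM")
  expect_equal(er$incidence_per_min, 3)
  expect_equal(er$density, 1)

  er0 <- event_rates(event_table(), h10, "NREM")
  expect_equal(nrow(er0), 0)
  expect_error(event_rates(ev, hypnogram(rep("WAKE", 10), 4), "NREM"),
               "zero time")
})

test_that("measured incidence of injected ripples is Poisson-consistent", {
  ses <- shared_session()
  tr <- ses$truth$events
  h <- ses$truth$hypnogram
  er <- event_rates(tr, h, "NREM")
  lam <- sim_params()$densities_per_min[["ripple"]]
  n <- er$n[er$kind == "RIPPLE"]
  expected <- lam * stage_minutes(h, "NREM")
  # within a 99.9% Poisson band
  expect_gt(n, qpois(0.0005, expected))
  expect_lt(n, qpois(0.9995, expected))
})
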