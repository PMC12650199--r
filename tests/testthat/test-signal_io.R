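test_that("channel and record constructors enforce their invariants", {
  expect_error(channel_trace("a", "EEG", "PARIETAL", 0, rnorm(10)),
               "sampling_rate")
  expect_error(channel_trace("a", "EEG", "PARIETAL", 100, c(1, NaN)),
               "non-finite")
  expect_error(channel_trace("a", "EEG", "PARIETAL", 100, numeric()),
               "zero samples")
  a <- channel_trace("a", "eeg", "parietal", 100, rnorm(200))
  b <- channel_trace("b", "EMG", "NECK", 50, rnorm(100))
  rec <- signal_record(list(a, b), "s1")
  expect_equal(trace_duration(a), 2)
  expect_error(signal_record(list()), "at least one")
  short <- channel_trace("c", "LFP", "CA1", 100, rnorm(120))
  expect_error(signal_record(list(a, short)), "duration")
  expect_identical(get_channel(rec, "EMG")$name, "b")
  expect_error(get_channel(rec, "LFP"), "no channel")
})

test_that("EDF round-trip recovers samples within 16-bit quantization", {
  rec <- signal_record(list(
    channel_trace("EEG_par", "EEG", "PARIETAL", 250, rnorm(2500, sd = 50)),
    channel_trace("EMG_nk", "EMG", "NECK", 250, rnorm(2500, sd = 120))
  ), "rt")
  path <- tempfile(fileext = ".edf")
  write_signals(rec, path)
  map <- tempfile(fileext = ".json")
  write_channel_map(rec, map)
  back <- read_signals(path, read_channel_map(map))
  expect_length(back$channels, 2)
  expect_equal(trace_duration(back$channels[[1]]), 10)
  for (i in 1:2) {
    orig <- rec$channels[[i]]
    got <- back$channels[[i]]
    expect_identical(got$modality, orig$modality)
    expect_identical(got$region, orig$region)
    expect_equal(got$sampling_rate_hz, orig$sampling_rate_hz)
    qstep <- diff(range(orig$samples) * 1.0) / 65535
    expect_lt(max(abs(got$samples - orig$samples)),
              2.1 * max(abs(range(orig$samples))) / 65535 + 1e-9)
  }
})

test_that("EDF handles a 3000 Hz LFP channel", {
  rec <- signal_record(list(
    channel_trace("LFP_CA1", "LFP", "CA1", 3000, rnorm(9000, sd = 60))
  ), "hi")
  path <- tempfile(fileext = ".edf")
  write_signals(rec, path)
  back <- read_signals(path)
  expect_equal(back$channels[[1]]$sampling_rate_hz, 3000)
  expect_length(back$channels[[1]]$samples, 9000)
  expect_identical(back$channels[[1]]$modality, "OTHER")  # no map given
})

test_that("EDF writer and reader reject invalid input", {
  bad <- signal_record(list(channel_trace("x", "EEG", "OTHER", 100,
                                          rnorm(100))))
  bad$channels[[1]]$samples[5] <- NA
  expect_error(write_signals(bad, tempfile()), "non-finite")

  ok <- signal_record(list(channel_trace("x", "EEG", "OTHER", 100,
                                         rnorm(300))))
  path <- tempfile(fileext = ".edf")
  write_signals(ok, path)
  # truncate: declared record count no longer matches the payload
  sz <- file.info(path)$size
  con <- file(path, "r+b")
  truncate_at <- sz - 100
  raw_all <- readBin(con, "raw", truncate_at)
  close(con)
  writeBin(raw_all, path)
  expect_error(read_signals(path), "mismatch")
  writeBin(as.raw(rep(0, 100)), path)
  expect_error(read_signals(path), "corrupt|short")
  expect_error(read_signals(tempfile("nope")), "not found")
})

test_that("hypnogram TSV round-trips exactly, including a 48 h record", {
  h <- hypnogram(c("WAKE", "NREM", "REM"), 4)
  p <- tempfile(fileext = ".tsv")
  write_hypnogram(h, p)
  h2 <- read_hypnogram(p)
  expect_identical(h2$stages, h$stages)
  expect_equal(h2$epoch_length_s, 4)

  set.seed(48)
  big <- hypnogram(sample(c("WAKE", "NREM", "REM"), 43200, replace = TRUE),
                   epoch_length_s = 4)
  write_hypnogram(big, p)
  big2 <- read_hypnogram(p)
  expect_identical(big2$stages, big$stages)
  expect_equal(hypnogram_duration(big2), 48 * 3600)

  # gap in epoch_index is a format error
  df <- utils::read.delim(p)
  df <- df[-2, ]
  utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_hypnogram(p), "contiguous")
  expect_error(hypnogram(c("WAKE", "DOZE")), "unknown stage")
})

test_that("event tables validate, sort and round-trip", {
  t2 <- data.frame(session_id = "s", region = "CA1", kind = "RIPPLE",
                   start_s = c(5.0, 1.0), peak_s = c(5.03, 1.02),
                   end_s = c(5.06, 1.05), peak_z = c(4, 5))
  tab <- event_table(t2)
  expect_equal(nrow(tab), 2)
  expect_true(!is.unsorted(tab$peak_s))
  expect_equal(tab$duration_ms, c(50, 60), tolerance = 1e-9)
  p <- tempfile(fileext = ".tsv")
  write_events(tab, p)
  expect_equal(nrow(read_events(p)), 2)

  bad <- t2
  bad$end_s[1] <- 4.9
  expect_error(event_table(bad), "start_s > end_s")
  over <- data.frame(session_id = "s", region = "CA1", kind = "RIPPLE",
                     start_s = c(1, 1.04), peak_s = c(1.02, 1.06),
                     end_s = c(1.05, 1.09), peak_z = 4)
  expect_error(event_table(over), "overlapping")
})

test_that("a large random event table round-trips through TSV", {
  set.seed(99)
  n <- 1000
  starts <- sort(runif(n, 0, 1e5))
  starts <- starts + seq_len(n)  # enforce spacing > max duration
  durs <- runif(n, 0.03, 0.9)
  df <- data.frame(
    session_id = "s", region = sample(c("CA1", "MPFC"), n, TRUE),
    kind = "RIPPLE",
    start_s = starts, peak_s = starts + durs / 2, end_s = starts + durs,
    peak_z = runif(n, 3, 10))
  df$kind <- sample(c("RIPPLE", "DELTA", "SPINDLE"), n, TRUE)
  tab <- event_table(df)
  p <- tempfile(fileext = ".tsv")
  write_events(tab, p)
  back <- read_events(p)
  expect_equal(nrow(back), n)
  for (col in c("start_s", "peak_s", "end_s", "peak_z")) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-8)
  }
  expect_identical(back$kind, tab$kind)
})

test_that("pipeline configuration round-trips through YAML", {
  cfg <- default_config(seed = 7)
  p <- tempfile(fileext = ".yaml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(cfg2$seed, 7)
  expect_equal(cfg2$detectors$ripple$band, cfg$detectors$ripple$band)
  expect_equal(cfg2$coupling$ds_window_s, cfg$coupling$ds_window_s)
  expect_equal(unlist(cfg2$simulation$bout_means_s),
               unlist(cfg$simulation$bout_means_s))
  expect_equal(cfg2$simulation$amplitude_sd, cfg$simulation$amplitude_sd)
  bad <- cfg
  bad$detectors <- NULL
  expect_error(validate_config(bad), "detectors")
  bad2 <- cfg
  bad2$coupling$rd_window_s <- c(0.3, 0.1)
  expect_error(validate_config(bad2), "rd_window")
})
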