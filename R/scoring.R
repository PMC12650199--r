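# Epoch-based sleep staging from EEG/EMG, stage-relative power spectra
# and sleep-architecture summaries.

#' Staging parameters
#'
#' Wakefulness is scored from EMG tone (low-amplitude high-frequency EEG
#' with high EMG); NREM from high-amplitude low-frequency (0.5-4 Hz) EEG
#' with low EMG; REM from dominant theta (6-9 Hz) with muscle atonia. An
#' epoch is WAKE when its EMG RMS robust-z exceeds `emg_wake_z` or its
#' absolute EMG RMS exceeds `emg_wake_abs_uv` (the absolute floor keeps
#' the rule meaningful for recordings that are almost entirely wake,
#' where an epoch-relative criterion has no sleep reference).
#'
#' @param epoch_length_s Epoch length in seconds (default 4, the common
#'   rodent convention).
#' @param emg_wake_z Robust-z threshold on epoch EMG RMS.
#' @param emg_wake_abs_uv Absolute EMG RMS floor (microvolts).
#' @param theta_delta_rem_ratio Theta/delta power ratio above which a
#'   non-wake epoch is REM.
#' @param delta_band,theta_band Frequency bands in Hz.
#' @param smoothing_epochs Majority-vote smoothing window (odd).
#' @return A list of class `staging_params`.
#' @export
staging_params <- function(epoch_length_s = 4, emg_wake_z = 1.0,
                           emg_wake_abs_uv = 50,
                           theta_delta_rem_ratio = 1.5,
                           delta_band = c(0.5, 4), theta_band = c(6, 9),
                           smoothing_epochs = 3) {
  if (smoothing_epochs %% 2 != 1) {
    stop("smoothing_epochs must be odd", call. = FALSE)
  }
  structure(list(epoch_length_s = epoch_length_s, emg_wake_z = emg_wake_z,
                 emg_wake_abs_uv = emg_wake_abs_uv,
                 theta_delta_rem_ratio = theta_delta_rem_ratio,
                 delta_band = delta_band, theta_band = theta_band,
                 smoothing_epochs = smoothing_epochs),
            class = "staging_params")
}

# Hann-windowed periodogram of one epoch: power per frequency bin.
epoch_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nf <- floor(n / 2) + 1
  p <- (Mod(X[seq_len(nf)])^2) / (sum(w^2) * fs)
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  list(freq = (seq_len(nf) - 1) * fs / n, power = p)
}

band_sum <- function(pg, band) {
  sum(pg$power[pg$freq >= band[1] & pg$freq < band[2]])
}

#' Score sleep stages from EEG and EMG
#'
#' Per epoch: compute the EMG RMS and EEG delta/theta band powers; label
#' WAKE when EMG tone is high (robust-z above threshold or RMS above the
#' absolute floor), otherwise REM when the theta/delta ratio exceeds the
#' REM criterion, otherwise NREM. Labels are then majority-smoothed, and
#' REM epochs entered directly from WAKE are relabelled NREM (REM is
#' entered only from sleep).
#'
#' @param eeg EEG [channel_trace()].
#' @param emg EMG [channel_trace()] covering the same duration.
#' @param params A [staging_params()].
#' @return A [hypnogram()].
#' @export
score_sleep <- function(eeg, emg, params = staging_params()) {
  el <- params$epoch_length_s
  dur <- min(trace_duration(eeg), trace_duration(emg))
  n_ep <- floor(dur / el)
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)

  fs_e <- eeg$sampling_rate_hz
  fs_m <- emg$sampling_rate_hz
  ne <- round(el * fs_e)
  nm <- round(el * fs_m)

  emg_rms <- vapply(seq_len(n_ep), function(k) {
    seg <- emg$samples[((k - 1) * nm + 1):(k * nm)]
    sqrt(mean(seg^2))
  }, numeric(1))
  med <- stats::median(emg_rms)
  mad_ <- stats::mad(emg_rms)
  emg_z <- if (mad_ > 0) (emg_rms - med) / mad_ else rep(0, n_ep)
  wake <- emg_z > params$emg_wake_z | emg_rms > params$emg_wake_abs_uv

  ratio <- vapply(seq_len(n_ep), function(k) {
    seg <- eeg$samples[((k - 1) * ne + 1):(k * ne)]
    pg <- epoch_periodogram(seg, fs_e)
    th <- band_sum(pg, params$theta_band)
    de <- band_sum(pg, params$delta_band)
    if (de > 0) th / de else Inf
  }, numeric(1))

  stages <- ifelse(wake, "WAKE",
                   ifelse(ratio > params$theta_delta_rem_ratio, "REM",
                          "NREM"))

  # majority-vote smoothing
  w <- params$smoothing_epochs
  half <- (w - 1) / 2
  if (half > 0 && n_ep > w) {
    sm <- stages
    for (k in seq_len(n_ep)) {
      lo <- max(1, k - half)
      hi <- min(n_ep, k + half)
      tb <- table(stages[lo:hi])
      top <- names(tb)[tb == max(tb)]
      sm[k] <- if (stages[k] %in% top) stages[k] else top[1]
    }
    stages <- sm
  }
  # REM entered only from sleep: REM directly after WAKE becomes NREM
  for (k in seq_len(n_ep)) {
    if (stages[k] == "REM" && (k == 1 || stages[k - 1] == "WAKE")) {
      stages[k] <- "NREM"
    }
  }
  hypnogram(stages, epoch_length_s = el, start_s = 0)
}

#' Stage-relative power spectrum
#'
#' Averages Hann-windowed per-epoch periodograms over all epochs of the
#' requested stage, restricts to the analysis band and normalizes so the
#' relative power sums to 1 over that band (power expressed relative to
#' the total power of the same stage).
#'
#' @param eeg EEG [channel_trace()].
#' @param hypnogram A [hypnogram()].
#' @param stage Stage to analyse (`"WAKE"`, `"NREM"` or `"REM"`).
#' @param band Analysis band in Hz (default `c(0.5, 30)`).
#' @return A list of class `stage_spectrum` with `stage`, `frequencies`,
#'   `relative_power` (sums to 1) and `n_epochs`.
#' @export
stage_spectrum <- function(eeg, hypnogram, stage, band = c(0.5, 30)) {
  stage <- toupper(stage)
  el <- hypnogram$epoch_length_s
  fs <- eeg$sampling_rate_hz
  ne <- round(el * fs)
  n_ep <- min(length(hypnogram$stages),
              floor(length(eeg$samples) / ne))
  idx <- which(hypnogram$stages[seq_len(n_ep)] == stage)
  if (length(idx) == 0L) {
    stop("no epochs of stage ", stage, " in hypnogram", call. = FALSE)
  }
  acc <- NULL
  for (k in idx) {
    pg <- epoch_periodogram(eeg$samples[((k - 1) * ne + 1):(k * ne)], fs)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
  }
  power <- acc / length(idx)
  freq <- pg$freq
  keep <- freq >= band[1] & freq <= band[2]
  rel <- power[keep] / sum(power[keep])
  structure(list(stage = stage, frequencies = freq[keep],
                 relative_power = rel, n_epochs = length(idx)),
            class = "stage_spectrum")
}

#' Relative band powers from a stage spectrum
#'
#' @param spectrum A [stage_spectrum()].
#' @param bands Named list of `c(lo, hi)` bands in Hz; a bin contributes
#'   to a band when its center frequency lies in `[lo, hi)`. Defaults:
#'   delta 0.5-4, theta 6-9, alpha 9-12, beta 12-30.
#' @return Data frame with columns `band`, `lo_hz`, `hi_hz`,
#'   `relative_power`.
#' @export
band_power <- function(spectrum,
                       bands = list(delta = c(0.5, 4), theta = c(6, 9),
                                    alpha = c(9, 12), beta = c(12, 30))) {
  f <- spectrum$frequencies
  grid_rng <- range(f)
  rows <- lapply(names(bands), function(nm) {
    b <- bands[[nm]]
    if (b[1] > grid_rng[2] || b[2] < grid_rng[1]) {
      stop("band '", nm, "' [", b[1], ", ", b[2],
           "] lies outside the spectrum grid", call. = FALSE)
    }
    data.frame(band = nm, lo_hz = b[1], hi_hz = b[2],
               relative_power = sum(spectrum$relative_power[f >= b[1] &
                                                              f < b[2]]))
  })
  do.call(rbind, rows)
}

#' Sleep-architecture summary
#'
#' Per-stage totals split by light/dark phase and an hourly time course.
#' Stage minutes partition the recording exactly.
#'
#' @param hypnogram A [hypnogram()].
#' @param light_dark_boundary_s Duration of each photoperiod phase in
#'   seconds (default 43200 = 12 h); the recording starts in the light
#'   phase and phases alternate.
#' @return List with `hourly` (hour, stage, minutes), `phase` (phase,
#'   stage, minutes) and `totals` (stage, minutes).
#' @export
architecture_summary <- function(hypnogram,
                                 light_dark_boundary_s = 43200) {
  el <- hypnogram$epoch_length_s
  starts <- hypnogram$start_s + (seq_along(hypnogram$stages) - 1) * el
  hour <- floor(starts / 3600)
  phase <- ifelse(floor(starts / light_dark_boundary_s) %% 2 == 0,
                  "LIGHT", "DARK")
  stf <- factor(hypnogram$stages, levels = STAGES)
  hourly <- as.data.frame(table(hour = hour, stage = stf),
                          stringsAsFactors = FALSE)
  hourly$minutes <- hourly$Freq * el / 60
  hourly$Freq <- NULL
  hourly$hour <- as.integer(hourly$hour)
  ph <- as.data.frame(table(phase = phase, stage = stf),
                      stringsAsFactors = FALSE)
  ph$minutes <- ph$Freq * el / 60
  ph$Freq <- NULL
  tot <- as.data.frame(table(stage = stf), stringsAsFactors = FALSE)
  tot$minutes <- tot$Freq * el / 60
  tot$Freq <- NULL
  list(hourly = hourly[order(hourly$hour), ], phase = ph, totals = tot)
}
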