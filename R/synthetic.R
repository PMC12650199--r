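# Synthetic EEG/EMG/LFP sessions with known vigilance-state sequences and
# embedded, optionally coupled ripple / delta / spindle events. Every
# downstream stage (staging, detection, coupling) can be scored against
# the generated ground truth.

#' Simulation parameters
#'
#' Defaults describe a realistic mouse recording session; all amplitudes
#' are in microvolts except event amplitudes, which are targets in SD
#' units of the corresponding detector envelope (self-calibrating against
#' the detectors). Coupled event lags are drawn uniformly from supports
#' that lie inside the coupling windows used by the analysis (ripple to
#' delta 0.05-0.25 s; delta to spindle 0.2-0.8 s).
#'
#' @param duration_s Session length in seconds.
#' @param epoch_length_s Hypnogram epoch length in seconds.
#' @param rates_hz Named list: sampling rates for `eeg`, `emg`, `lfp`.
#' @param bout_means_s Named vector: mean bout lengths (s) for WAKE, NREM,
#'   REM (exponential bouts, alternating; REM entered only from NREM).
#' @param transition Named list: `nrem_to_rem` and `rem_to_nrem`
#'   probabilities of the semi-Markov chain.
#' @param densities_per_min Named vector: expected NREM event densities
#'   per minute for `ripple`, `delta`, `spindle`.
#' @param amplitude_sd Named vector: injected amplitude targets, in
#'   detector-envelope SD units, for `ripple`, `delta`, `spindle`.
#' @param coupling_prob_rd Probability that a ripple schedules a delta.
#' @param coupling_prob_ds Probability that a delta schedules a spindle.
#' @param rd_lag_s,ds_lag_s Uniform lag supports (s), peak to peak.
#' @param event_dur_ms Named list of `c(lo, hi)` duration ranges (ms).
#'   These are the nominal waveform supports; they are chosen so the
#'   operational event durations (the time the detection envelope spends
#'   above threshold, which is how the detectors measure duration) fall
#'   inside the published bounds.
#' @param alpha EEG/EMG background spectral exponent (power ~ 1/f^alpha).
#' @param lfp_alpha LFP background spectral exponent. Defaults to 2, the
#'   textbook deep-electrode LFP spectrum; a flatter exponent would put a
#'   physiologically implausible share of variance into the 100-250 Hz
#'   ripple band.
#' @param eeg_base_uv EEG 1/f background SD.
#' @param eeg_delta_uv Named vector: EEG 0.5-4 Hz component SD per stage
#'   (NREM three times wake).
#' @param eeg_theta_uv Named vector: EEG 6-9 Hz component SD per stage
#'   (REM theta-dominant).
#' @param emg_uv Named vector: EMG noise SD per stage (atonia in REM).
#' @param lfp_base_uv LFP 1/f background SD (CA1 and mPFC).
#' @param ripple_freq_hz,spindle_freq_hz Carrier frequencies of injected
#'   bursts.
#' @param crossfade_s Cross-fade time at stage boundaries.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(duration_s = 7200,
                       epoch_length_s = 4,
                       rates_hz = list(eeg = 250, emg = 250, lfp = 1000),
                       bout_means_s = c(WAKE = 200, NREM = 120, REM = 60),
                       transition = list(nrem_to_rem = 0.4,
                                         rem_to_nrem = 0.5),
                       densities_per_min = c(ripple = 20, delta = 18,
                                             spindle = 3),
                       amplitude_sd = c(ripple = 7, delta = 4, spindle = 8),
                       coupling_prob_rd = 0.25,
                       coupling_prob_ds = 0.25,
                       rd_lag_s = c(0.05, 0.25),
                       ds_lag_s = c(0.2, 0.8),
                       event_dur_ms = list(ripple = c(60, 90),
                                           delta = c(180, 300),
                                           spindle = c(900, 1300)),
                       alpha = 1.0,
                       lfp_alpha = 2.0,
                       eeg_base_uv = 40,
                       eeg_delta_uv = c(WAKE = 25, NREM = 75, REM = 25),
                       eeg_theta_uv = c(WAKE = 12, NREM = 12, REM = 70),
                       emg_uv = c(WAKE = 120, NREM = 30, REM = 10),
                       lfp_base_uv = 60,
                       ripple_freq_hz = 150,
                       spindle_freq_hz = 12,
                       crossfade_s = 0.5) {
  p <- structure(as.list(environment()), class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  if (!is.numeric(p$duration_s) || p$duration_s <= 0) {
    stop("duration_s must be > 0", call. = FALSE)
  }
  if (any(p$bout_means_s <= 0)) {
    stop("all bout means must be > 0 (WAKE, NREM, REM)", call. = FALSE)
  }
  if (any(p$densities_per_min < 0)) {
    stop("event densities must be >= 0", call. = FALSE)
  }
  for (pr in c("coupling_prob_rd", "coupling_prob_ds")) {
    v <- p[[pr]]
    if (v < 0 || v > 1) stop(pr, " must be in [0, 1]", call. = FALSE)
  }
  if (p$rd_lag_s[1] < 0.05 - 1e-12 || p$rd_lag_s[2] > 0.25 + 1e-12 ||
      p$ds_lag_s[1] < 0.1 - 1e-12 || p$ds_lag_s[2] > 1.3 + 1e-12) {
    stop("coupled lag supports must lie inside the coupling windows ",
         "(R-D within [0.05, 0.25] s, D-S within [0.1, 1.3] s)",
         call. = FALSE)
  }
  invisible(p)
}

#' Sample a wake/NREM/REM state sequence
#'
#' Alternating bouts with exponential durations (configured means),
#' discretized to epoch labels by majority occupancy. The chain starts in
#' WAKE; wake is always followed by NREM, REM is entered only from NREM.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A [hypnogram()].
#' @export
sample_state_sequence <- function(params = sim_params(), seed = 1L) {
  validate_sim_params(params)
  set.seed(seed)
  dur <- params$duration_s
  el <- params$epoch_length_s
  if (dur < el) stop("duration shorter than one epoch", call. = FALSE)
  states <- character(0)
  lengths <- numeric(0)
  cur <- "WAKE"
  total <- 0
  while (total < dur) {
    b <- stats::rexp(1, rate = 1 / params$bout_means_s[[cur]])
    states <- c(states, cur)
    lengths <- c(lengths, b)
    total <- total + b
    cur <- switch(cur,
      WAKE = "NREM",
      NREM = if (stats::runif(1) < params$transition$nrem_to_rem) "REM"
             else "WAKE",
      REM = if (stats::runif(1) < params$transition$rem_to_nrem) "NREM"
            else "WAKE")
  }
  # majority occupancy per epoch on a fine grid
  n_ep <- floor(dur / el)
  grid_dt <- el / 8
  grid <- seq(grid_dt / 2, n_ep * el, by = grid_dt)
  bout_end <- cumsum(lengths)
  lab <- states[findInterval(grid, c(0, bout_end), rightmost.closed = TRUE)]
  ep_of <- ceiling(grid / el - 1e-12)
  stages <- vapply(seq_len(n_ep), function(k) {
    tb <- table(lab[ep_of == k])
    names(tb)[which.max(tb)]
  }, character(1))
  hypnogram(stages, epoch_length_s = el, start_s = 0)
}

# FFT-shaped 1/f^alpha Gaussian noise, unit SD.
colored_noise <- function(n, fs, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  W <- stats::fft(w)
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k) * fs / n
  sc <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(stats::fft(W * sc, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Zero-phase FFT notch: removes [band[1], band[2]] Hz with cosine
# transition edges of width trans_hz; exact on a padded finite waveform.
fft_notch <- function(x, fs, band, trans_hz = 0.6) {
  n <- length(x)
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k) * fs / n
  H <- rep(1, n)
  lo <- band[1] - trans_hz
  hi <- band[2] + trans_hz
  inside <- f >= band[1] & f <= band[2]
  H[inside] <- 0
  rlo <- f >= lo & f < band[1]
  H[rlo] <- 0.5 * (1 + cos(pi * (f[rlo] - lo) / trans_hz))
  rhi <- f > band[2] & f <= hi
  H[rhi] <- 0.5 * (1 - cos(pi * (f[rhi] - band[2]) / trans_hz))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# Unit-SD narrowband Gaussian noise.
narrowband_noise <- function(n, fs, band, order = 2) {
  x <- bandpass_zero_phase(stats::rnorm(n), band, order = order, rate = fs)
  x / stats::sd(x)
}

# Per-sample stage gain vector, cross-faded at boundaries.
stage_gain <- function(hyp, n, fs, per_stage, crossfade_s) {
  t <- (seq_len(n) - 1) / fs
  st <- stage_at(hyp, pmin(t, hypnogram_duration(hyp) - 1e-9))
  g <- unname(per_stage[st])
  w <- max(1L, round(crossfade_s * fs))
  if (w > 1L) {
    k <- rep(1 / w, w)
    pad <- floor(w / 2)
    gp <- c(rep(g[1], pad), g, rep(g[n], w - pad - 1))
    g <- as.numeric(stats::filter(gp, k, sides = 1))[(w):(w + n - 1)]
  }
  g
}

#' Synthesize a stage-dependent background trace
#'
#' 1/f^alpha noise plus stage-dependent narrowband components: NREM adds
#' 0.5-4 Hz power (three times the wake delta amplitude by default), REM
#' adds 6-9 Hz theta; EMG variance is high in wake, low in NREM and
#' minimal in REM (muscle atonia). Stage boundaries are cross-faded.
#'
#' @param hypnogram A [hypnogram()].
#' @param channel Named list: `name`, `modality` (`EEG`/`EMG`/`LFP`),
#'   `region`, `rate` (Hz).
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A [channel_trace()].
#' @export
synthesize_background <- function(hypnogram, channel, params = sim_params(),
                                  seed = 1L) {
  set.seed(seed_child(seed, paste0("bg:", channel$name)))
  fs <- channel$rate
  n <- round(hypnogram_duration(hypnogram) * fs)
  mod <- toupper(channel$modality)
  if (mod == "EEG") {
    x <- params$eeg_base_uv * colored_noise(n, fs, params$alpha) +
      stage_gain(hypnogram, n, fs, params$eeg_delta_uv,
                 params$crossfade_s) *
        narrowband_noise(n, fs, c(0.5, 4)) +
      stage_gain(hypnogram, n, fs, params$eeg_theta_uv,
                 params$crossfade_s) *
        narrowband_noise(n, fs, c(6, 9))
  } else if (mod == "EMG") {
    x <- stage_gain(hypnogram, n, fs, params$emg_uv, params$crossfade_s) *
      stats::rnorm(n)
  } else {
    x <- params$lfp_base_uv * colored_noise(n, fs, params$lfp_alpha)
  }
  channel_trace(channel$name, mod, channel$region, fs, x)
}

# ---- event scheduling ------------------------------------------------

# Intervals (s) of maximal runs of the given stage.
stage_intervals <- function(hyp, stage = "NREM") {
  r <- rle(hyp$stages == stage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_s = hyp$start_s + (starts[keep] - 1) * hyp$epoch_length_s,
    end_s = hyp$start_s + ends[keep] * hyp$epoch_length_s
  )
}

in_intervals <- function(t, iv, margin = 0) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (k in seq_len(nrow(iv))) {
    out <- out | (t >= iv$start_s[k] + margin & t <= iv$end_s[k] - margin)
  }
  out
}

overlaps_any <- function(start, end, starts, ends) {
  any(start < ends & end > starts)
}

# Place n events of half-width hw (s) uniformly in the stage intervals,
# rejecting same-kind overlap. Errors when the density is unachievable.
place_poisson <- function(n, iv, hw, taken_start, taken_end, kind,
                          max_tries = 200L) {
  placed <- numeric(0)
  if (n == 0L) return(placed)
  lens <- pmax(iv$end_s - iv$start_s - 2 * hw, 0)
  if (sum(lens) <= 0) {
    stop("placement error for kind ", kind,
         ": no eligible NREM time", call. = FALSE)
  }
  for (j in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      seg <- sample.int(nrow(iv), 1, prob = lens)
      t0 <- stats::runif(1, iv$start_s[seg] + hw, iv$end_s[seg] - hw)
      if (!overlaps_any(t0 - hw, t0 + hw, taken_start, taken_end)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("placement error for kind ", kind,
           ": requested density unachievable without overlap",
           call. = FALSE)
    }
    placed <- c(placed, t0)
    taken_start <- c(taken_start, t0 - hw)
    taken_end <- c(taken_end, t0 + hw)
  }
  placed
}

# Place a coupled child at parent + U(lag) subject to NREM containment and
# same-kind non-overlap; falls back to a deterministic scan of the lag
# window before giving up.
place_child <- function(parent_t, lag_rng, hw, iv, taken_start, taken_end,
                        max_tries = 50L) {
  for (tr in seq_len(max_tries)) {
    lag <- stats::runif(1, lag_rng[1], lag_rng[2])
    t0 <- parent_t + lag
    if (all(in_intervals(c(t0 - hw, t0 + hw), iv)) &&
        !overlaps_any(t0 - hw, t0 + hw, taken_start, taken_end)) {
      return(t0)
    }
  }
  for (lag in seq(lag_rng[1], lag_rng[2], length.out = 201)) {
    t0 <- parent_t + lag
    if (all(in_intervals(c(t0 - hw, t0 + hw), iv)) &&
        !overlaps_any(t0 - hw, t0 + hw, taken_start, taken_end)) {
      return(t0)
    }
  }
  NA_real_
}

#' Schedule ground-truth events for a session
#'
#' Draws ripple, delta and spindle peak times and durations inside NREM:
#' ripples as a Poisson process; with probability `coupling_prob_rd` each
#' ripple schedules a delta at a lag uniform on `rd_lag_s`; with
#' probability `coupling_prob_ds` each delta schedules a spindle at a lag
#' uniform on `ds_lag_s`; remaining deltas/spindles are placed as Poisson
#' processes to meet the configured NREM densities. Same-kind overlap is
#' rejected during placement.
#'
#' @param hypnogram A [hypnogram()].
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param session_id Session label.
#' @return An [event_table()] with extra columns `event_id`,
#'   `parent_event_id` (coupling lineage; NA for uncoupled events) and
#'   `injected_amplitude_sd`.
#' @export
schedule_events <- function(hypnogram, params = sim_params(), seed = 1L,
                            session_id = "session") {
  validate_sim_params(params)
  set.seed(seed_child(seed, "schedule"))
  iv <- stage_intervals(hypnogram, "NREM")
  nrem_min <- stage_minutes(hypnogram, "NREM")
  dens <- params$densities_per_min
  dur_rng <- params$event_dur_ms

  draw_dur <- function(kind, n) {
    stats::runif(n, dur_rng[[kind]][1], dur_rng[[kind]][2]) / 1000
  }
  mk_id <- function(kind, k) sprintf("%s_%s_%04d", session_id,
                                     tolower(kind), k)

  # ripples
  n_r <- stats::rpois(1, dens[["ripple"]] * nrem_min)
  hw_r <- dur_rng$ripple[2] / 2000
  t_r <- if (n_r > 0 && nrow(iv) > 0) {
    sort(place_poisson(n_r, iv, hw_r, numeric(0), numeric(0), "ripple"))
  } else numeric(0)
  dur_r <- draw_dur("ripple", length(t_r))

  # deltas: ripple-coupled children first, then a Poisson fill up to the
  # configured density. Spacing must keep one delta's main lobe clear of
  # another's flanking slow-oscillation lobes (0.7 s each side): centre
  # distance > lobe + main, i.e. half-width = main/2 + lobe/2. Only the
  # peak must lie in NREM; a flank crossing an epoch boundary is
  # harmless background. A Poisson-fill delta that is due to spawn a
  # spindle is placed JOINTLY with its child: if no in-window child
  # position is free, the delta position itself is resampled, so a
  # spawning delta always carries its child.
  hw_d <- dur_rng$delta[2] / 2000 + 0.35
  hw_s <- dur_rng$spindle[2] / 2000
  d_peak <- numeric(0)
  d_parent <- character(0)
  s_peak <- numeric(0)
  s_parent_time <- numeric(0)   # keyed by the parent delta's peak time

  free_child_lag <- function(parent_t) {
    place_child(parent_t, params$ds_lag_s, hw_s, iv,
                s_peak - hw_s, s_peak + hw_s)
  }

  if (length(t_r)) {
    spawn <- stats::runif(length(t_r)) < params$coupling_prob_rd
    spawn_s <- stats::runif(length(t_r)) < params$coupling_prob_ds
    for (k in which(spawn)) {
      t0 <- place_child(t_r[k], params$rd_lag_s, hw_d, iv,
                        d_peak - hw_d, d_peak + hw_d)
      if (is.na(t0)) next
      d_peak <- c(d_peak, t0)
      d_parent <- c(d_parent, mk_id("ripple", k))
      if (spawn_s[k]) {
        t1 <- free_child_lag(t0)
        if (!is.na(t1)) {
          s_peak <- c(s_peak, t1)
          s_parent_time <- c(s_parent_time, t0)
        }
      }
    }
  }

  n_d_extra <- max(0L, stats::rpois(1, dens[["delta"]] * nrem_min) -
                     length(d_peak))
  if (n_d_extra > 0 && nrow(iv) > 0) {
    lens <- pmax(iv$end_s - iv$start_s - 2 * hw_d, 0)
    if (sum(lens) <= 0) {
      stop("placement error for kind delta: no eligible NREM time",
           call. = FALSE)
    }
    for (j in seq_len(n_d_extra)) {
      spawn_s <- stats::runif(1) < params$coupling_prob_ds
      ok <- FALSE
      for (tr in seq_len(300L)) {
        seg <- sample.int(nrow(iv), 1, prob = lens)
        t0 <- stats::runif(1, iv$start_s[seg] + hw_d, iv$end_s[seg] - hw_d)
        if (overlaps_any(t0 - hw_d, t0 + hw_d, d_peak - hw_d,
                         d_peak + hw_d)) next
        if (spawn_s) {
          t1 <- free_child_lag(t0)
          if (is.na(t1)) next   # resample the delta, keep the child
          s_peak <- c(s_peak, t1)
          s_parent_time <- c(s_parent_time, t0)
        }
        d_peak <- c(d_peak, t0)
        d_parent <- c(d_parent, NA_character_)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("placement error for kind delta: requested density ",
             "unachievable without overlap", call. = FALSE)
      }
    }
  }
  ord <- order(d_peak)
  d_peak <- d_peak[ord]
  d_parent <- d_parent[ord]
  dur_d <- draw_dur("delta", length(d_peak))

  # remaining spindles as a Poisson fill
  n_s_extra <- max(0L, stats::rpois(1, dens[["spindle"]] * nrem_min) -
                     length(s_peak))
  if (n_s_extra > 0 && nrow(iv) > 0) {
    extra <- place_poisson(n_s_extra, iv, hw_s, s_peak - hw_s,
                           s_peak + hw_s, "spindle")
    s_peak <- c(s_peak, extra)
    s_parent_time <- c(s_parent_time, rep(NA_real_, length(extra)))
  }
  ord <- order(s_peak)
  s_peak <- s_peak[ord]
  s_parent_time <- s_parent_time[ord]
  s_parent <- vapply(s_parent_time, function(tt) {
    if (is.na(tt)) return(NA_character_)
    mk_id("delta", which.min(abs(d_peak - tt)))
  }, character(1))
  dur_s <- draw_dur("spindle", length(s_peak))

  amp <- params$amplitude_sd
  mk <- function(kind, region, peaks, durs, parents) {
    if (length(peaks) == 0L) return(NULL)
    data.frame(
      session_id = session_id, region = region, kind = kind,
      start_s = peaks - durs / 2, peak_s = peaks, end_s = peaks + durs / 2,
      peak_z = amp[[tolower(kind)]],
      event_id = vapply(seq_along(peaks), function(k) mk_id(kind, k),
                        character(1)),
      parent_event_id = parents,
      injected_amplitude_sd = amp[[tolower(kind)]]
    )
  }
  df <- rbind(
    mk("RIPPLE", "CA1", t_r, dur_r, rep(NA_character_, length(t_r))),
    mk("DELTA", "MPFC", d_peak, dur_d, d_parent),
    mk("SPINDLE", "MPFC", s_peak, dur_s, s_parent)
  )
  if (is.null(df)) {
    out <- event_table()
    out$event_id <- character(0)
    out$parent_event_id <- character(0)
    out$injected_amplitude_sd <- numeric(0)
    return(out)
  }
  event_table(df, provenance = list(seed = seed,
                                    densities = as.list(dens),
                                    coupling_prob_rd = params$coupling_prob_rd,
                                    coupling_prob_ds = params$coupling_prob_ds))
}

# ---- waveforms and calibration ---------------------------------------

tukey_window <- function(n, taper) {
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < taper / 2
  hi <- x > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / taper - 2 / taper + 1)))
  w
}

# Event waveforms. The nominal duration dur_s is the main support; the
# returned offset_s says how far the waveform starts before the event's
# start_s (nonzero for the biphasic delta, whose flanking lobes pin the
# zero crossings of the filtered trace to the main-lobe edges, as the
# surrounding troughs of a real cortical delta wave do; the lobes are
# kept shorter than the minimum delta duration and at half amplitude so
# they are not themselves detectable).
event_waveform <- function(kind, dur_s, fs, params) {
  n <- max(3L, round(dur_s * fs))
  t <- (seq_len(n) - (n + 1) / 2) / fs
  if (kind == "RIPPLE") {
    # sustained body with a central crest: the envelope stays above the
    # boundary threshold for most of the support but has a unique,
    # curved maximum so the detected peak localizes the event
    env <- 0.75 * tukey_window(n, 0.4) + 0.25 * exp(-t^2 / (2 * (dur_s / 5)^2))
    env <- env / max(env)
    list(w = env * sin(2 * pi * params$ripple_freq_hz * t),
         offset_s = 0, env = env)
  } else if (kind == "DELTA") {
    # flanking half-waves of opposite sign emulate the slow-oscillation
    # cycle a cortical delta wave is embedded in; they pin the zero
    # crossings of the filtered trace to the main-lobe edges, and their
    # duration exceeds the detector's 500 ms cap so they can never be
    # scored as delta waves themselves
    ns <- round(0.7 * fs)
    lobe <- -0.65 * sin(pi * (seq_len(ns) - 0.5) / ns)
    w <- c(lobe, sin(pi * (seq_len(n) - 0.5) / n), lobe)
    # the corners of the composite splash broadband energy; remove the
    # sigma-band (9-17 Hz) content so a delta cannot masquerade as, or
    # distort, a spindle on the shared mPFC channel
    np <- round(0.5 * fs)
    wp <- c(rep(0, np), w, rep(0, np))
    # notch out the sigma band (9-17 Hz) so the corners of the composite
    # cannot masquerade as, or interfere with, a spindle on the shared
    # mPFC channel; an FFT notch with narrow cosine transitions leaves
    # the lobes' own low-frequency content untouched
    wp <- fft_notch(wp, fs, c(9, 17), trans_hz = 0.6)
    keep <- round(0.25 * fs)
    list(w = wp[(np - keep + 1):(np + length(w) + keep)],
         offset_s = (ns + keep) / fs)
  } else {
    # envelope = sustained plateau (keeps the smoothed envelope above the
    # sustain threshold for the whole event) plus a narrow central crest
    # (a sharply curved unique maximum, so the detected envelope peak
    # localizes the event in time)
    env <- 0.45 * tukey_window(n, 0.5) + 0.55 * exp(-t^2 / (2 * 0.05^2))
    env <- env / max(env)
    list(w = env * sin(2 * pi * params$spindle_freq_hz * t),
         offset_s = 0, env = env)
  }
}

# Peak of the detector transform of a unit-amplitude waveform (padded to
# avoid filter edge effects).
unit_transform_peak <- function(kind, w, fs, det) {
  pad <- round(2 * fs)
  x <- c(rep(0, pad), w, rep(0, pad))
  switch(kind,
    RIPPLE = max(envelope_raw(x, fs, "square_lowpass", det$band,
                              lowpass_hz = det$envelope_lowpass_hz,
                              order = det$filter_order)),
    DELTA = max(abs(bandpass_zero_phase(x, det$band,
                                        order = det$filter_order,
                                        rate = fs))),
    SPINDLE = max(envelope_raw(x, fs, "rms_gauss", det$band,
                               smoothing_ms = det$smoothing_ms,
                               order = det$filter_order))
  )
}

# Amplitude (uV) for one event so its detector-envelope peak reaches
# target_z SD units given the transformed-trace statistics (m, s).
calibrate_amplitude <- function(kind, target_z, unit_peak, m, s, m2 = NULL) {
  switch(kind,
    RIPPLE = sqrt(target_z * s / unit_peak),
    DELTA = target_z * s / unit_peak,
    SPINDLE = {
      target_env <- m + target_z * s
      sqrt(max(target_env^2 - (m2 %||% m^2), 0)) / unit_peak
    }
  )
}

trace_stats_for_kind <- function(kind, x, fs, det) {
  if (kind == "RIPPLE") {
    env <- envelope_raw(x, fs, "square_lowpass", det$band,
                        lowpass_hz = det$envelope_lowpass_hz,
                        order = det$filter_order)
    list(m = mean(env), s = stats::sd(env), m2 = NULL)
  } else if (kind == "DELTA") {
    y <- bandpass_zero_phase(x, det$band, order = det$filter_order,
                             rate = fs)
    list(m = mean(y), s = stats::sd(y), m2 = NULL)
  } else {
    env <- envelope_raw(x, fs, "rms_gauss", det$band,
                        smoothing_ms = det$smoothing_ms,
                        order = det$filter_order)
    list(m = mean(env), s = stats::sd(env), m2 = mean(env^2))
  }
}

#' Inject scheduled events into background traces
#'
#' Ripples are Gaussian-windowed high-frequency bursts on the CA1 channel;
#' delta waves are single half-sine deflections and spindles waxing-waning
#' sigma-band bursts on the mPFC channel. Amplitudes are calibrated so the
#' injected peak, measured in SD units of the corresponding detector
#' envelope over the whole trace, hits each event's
#' `injected_amplitude_sd`. Calibration runs twice: the second pass uses
#' the envelope statistics of the event-laden trace, compensating the
#' variance the events themselves add.
#'
#' @param traces List of [channel_trace()] including a CA1 LFP and an
#'   mPFC LFP (other channels pass through).
#' @param hypnogram A [hypnogram()].
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param session_id Session label.
#' @param detectors Optional list with elements `ripple`, `delta`,
#'   `spindle` giving the detector parameter blocks used for calibration.
#' @return List with `record` (a [signal_record()]) and `truth` (list of
#'   `hypnogram` and `events`, the ground-truth [event_table()]).
#' @export
inject_events <- function(traces, hypnogram, params = sim_params(),
                          seed = 1L, session_id = "session",
                          detectors = NULL) {
  detectors <- detectors %||% list(ripple = ripple_params(),
                                   delta = delta_params(),
                                   spindle = spindle_params())
  mods <- vapply(traces, `[[`, character(1), "modality")
  regs <- vapply(traces, `[[`, character(1), "region")
  i_ca1 <- which(mods == "LFP" & regs == "CA1")[1]
  i_pfc <- which(mods == "LFP" & regs == "MPFC")[1]
  if (is.na(i_ca1) || is.na(i_pfc)) {
    stop("traces must include CA1 LFP and MPFC LFP channels", call. = FALSE)
  }
  truth <- schedule_events(hypnogram, params, seed, session_id)
  set.seed(seed_child(seed, "inject"))

  kind_chan <- c(RIPPLE = i_ca1, DELTA = i_pfc, SPINDLE = i_pfc)
  det_of <- c(RIPPLE = "ripple", DELTA = "delta", SPINDLE = "spindle")
  signs <- stats::setNames(vector("list", 3), EVENT_KINDS)

  # waveforms and their unit transform peaks do not change across
  # calibration passes; compute once (cached by rounded sample length)
  wf_cache <- list()
  up_cache <- list()
  event_wf <- function(kind, r, fs, det) {
    dur <- truth$end_s[r] - truth$start_s[r]
    key <- paste0(kind, ":", round(dur * fs))
    if (is.null(wf_cache[[key]])) {
      wf <- event_waveform(kind, dur, fs, params)
      wf_cache[[key]] <<- wf
      up_cache[[key]] <<- unit_transform_peak(kind, wf$w, fs, det)
    }
    list(wf = wf_cache[[key]], up = up_cache[[key]])
  }

  if (nrow(truth) == 0L) {
    rec <- signal_record(traces, session_id = session_id)
    return(list(record = rec, truth = list(hypnogram = hypnogram,
                                           events = truth)))
  }

  for (kind in EVENT_KINDS) {
    rows <- which(truth$kind == kind)
    if (kind == "DELTA" && length(rows)) {
      signs[[kind]] <- sample(c(-1, 1), length(rows), replace = TRUE)
    }
  }

  # initial amplitudes from background statistics
  amps <- numeric(nrow(truth))
  for (kind in EVENT_KINDS) {
    rows <- which(truth$kind == kind)
    if (!length(rows)) next
    fs <- traces[[kind_chan[[kind]]]]$sampling_rate_hz
    det <- detectors[[det_of[[kind]]]]
    st <- trace_stats_for_kind(kind, traces[[kind_chan[[kind]]]]$samples,
                               fs, det)
    for (r in rows) {
      cw <- event_wf(kind, r, fs, det)
      amps[r] <- calibrate_amplitude(kind, truth$injected_amplitude_sd[r],
                                     cw$up, st$m, st$s, st$m2)
    }
  }

  # An oscillatory burst dominates the local field: within the event
  # envelope the pre-existing in-band background is suppressed before
  # the burst is added, as in a recorded trace where the event IS the
  # local in-band signal. Without this the background cross term carves
  # dips into the detection envelope, fragments threshold runs and
  # wobbles the envelope argmax the peak time is read from.
  rip_det <- detectors$ripple
  spi_det <- detectors$spindle
  inband <- list(
    RIPPLE = bandpass_zero_phase(
      traces[[kind_chan[["RIPPLE"]]]]$samples, rip_det$band,
      order = rip_det$filter_order,
      rate = traces[[kind_chan[["RIPPLE"]]]]$sampling_rate_hz),
    SPINDLE = bandpass_zero_phase(
      traces[[kind_chan[["SPINDLE"]]]]$samples, spi_det$band,
      order = spi_det$filter_order,
      rate = traces[[kind_chan[["SPINDLE"]]]]$sampling_rate_hz))
  suppress_frac <- 0.9

  build <- function() {
    out <- traces
    for (kind in EVENT_KINDS) {
      rows <- which(truth$kind == kind)
      if (!length(rows)) next
      ch <- out[[kind_chan[[kind]]]]
      fs <- ch$sampling_rate_hz
      det <- detectors[[det_of[[kind]]]]
      for (j in seq_along(rows)) {
        r <- rows[j]
        cw <- event_wf(kind, r, fs, det)
        i0 <- round((truth$start_s[r] - cw$wf$offset_s) * fs) + 1L
        idx <- i0:(i0 + length(cw$wf$w) - 1L)
        keep <- idx >= 1L & idx <= length(ch$samples)
        sgn <- if (kind == "DELTA") signs[[kind]][j] else 1
        add <- sgn * amps[r] * cw$wf$w[keep]
        if (kind %in% names(inband) && !is.null(cw$wf$env)) {
          add <- add - suppress_frac * cw$wf$env[keep] *
            inband[[kind]][idx[keep]]
        }
        ch$samples[idx[keep]] <- ch$samples[idx[keep]] + add
      }
      out[[kind_chan[[kind]]]] <- ch
    }
    out
  }

  # measure-and-correct passes: the events themselves inflate the
  # envelope statistics their amplitude is expressed in (and the analytic
  # first guess ignores event/background cross terms), so measure each
  # event's achieved envelope peak on the assembled trace and trim its
  # amplitude toward the target
  final <- build()
  for (pass in 1:3) {
    changed <- FALSE
    for (kind in EVENT_KINDS) {
      rows <- which(truth$kind == kind)
      if (!length(rows)) next
      ch <- final[[kind_chan[[kind]]]]
      fs <- ch$sampling_rate_hz
      det <- detectors[[det_of[[kind]]]]
      # z-scored detector transform of the whole event-laden trace
      if (kind == "DELTA") {
        y <- bandpass_zero_phase(ch$samples, det$band,
                                 order = det$filter_order, rate = fs)
        st <- list(m = mean(y), s = stats::sd(y), m2 = NULL)
        zvec <- abs(y - st$m) / st$s
      } else {
        env <- envelope_raw(ch$samples, fs,
                            if (kind == "RIPPLE") "square_lowpass"
                            else "rms_gauss",
                            det$band,
                            lowpass_hz = det$envelope_lowpass_hz %||% 20,
                            smoothing_ms = det$smoothing_ms %||% 100,
                            order = det$filter_order)
        st <- list(m = mean(env), s = stats::sd(env), m2 = mean(env^2))
        zvec <- (env - st$m) / st$s
      }
      for (r in rows) {
        i1 <- max(1L, round(truth$start_s[r] * fs))
        i2 <- min(length(ch$samples), round(truth$end_s[r] * fs))
        za <- max(zvec[i1:i2])
        zt <- truth$injected_amplitude_sd[r]
        if (!is.finite(za) || za <= 0) next
        fac <- switch(kind,
          RIPPLE = sqrt(zt / za),
          DELTA = zt / za,
          SPINDLE = {
            num <- (st$m + zt * st$s)^2 - (st$m2 %||% st$m^2)
            den <- (st$m + za * st$s)^2 - (st$m2 %||% st$m^2)
            if (den > 0 && num > 0) sqrt(num / den) else zt / za
          })
        fac <- min(max(fac, 0.5), 2)
        if (abs(fac - 1) > 0.02) changed <- TRUE
        amps[r] <- amps[r] * fac
      }
    }
    if (!changed) break
    final <- build()
  }
  rec <- signal_record(final, session_id = session_id)
  list(record = rec, truth = list(hypnogram = hypnogram, events = truth))
}

#' Generate a complete synthetic session
#'
#' Composes [sample_state_sequence()], [synthesize_background()] for the
#' EEG, EMG and two LFP channels, and [inject_events()]. Deterministic
#' given `(params, seed)`.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param session_id Session label.
#' @param detectors Optional detector parameter blocks for calibration.
#' @return List with `record` and `truth` (see [inject_events()]).
#' @export
generate_session <- function(params = sim_params(), seed = 1L,
                             session_id = "session", detectors = NULL) {
  validate_sim_params(params)
  hyp <- sample_state_sequence(params, seed_child(seed, "states"))
  chans <- list(
    list(name = "EEG_parietal", modality = "EEG", region = "PARIETAL",
         rate = params$rates_hz$eeg),
    list(name = "EMG_neck", modality = "EMG", region = "NECK",
         rate = params$rates_hz$emg),
    list(name = "LFP_CA1", modality = "LFP", region = "CA1",
         rate = params$rates_hz$lfp),
    list(name = "LFP_mPFC", modality = "LFP", region = "MPFC",
         rate = params$rates_hz$lfp)
  )
  traces <- lapply(chans, function(cs)
    synthesize_background(hyp, cs, params, seed))
  inject_events(traces, hyp, params, seed, session_id, detectors)
}

#' Generate a synthetic behavioral exploration table
#'
#' Exploration times are gamma-distributed per object; the displaced
#' object's time is multiplied by the group's preference multiplier, so a
#' multiplier of 1 yields an expected discrimination index of 0.
#'
#' @param group_specs List of lists with `group`, `n`, and optionally
#'   `multiplier` (default 1), `mean_time_s` (default 15) and `shape`
#'   (gamma shape, default 4).
#' @param seed Integer seed.
#' @return Data frame with columns `animal_id`, `group`, `t_displaced_s`,
#'   `t_stationary_s`.
#' @export
generate_behavior_table <- function(group_specs, seed = 1L) {
  set.seed(seed_child(seed, "behavior"))
  rows <- lapply(group_specs, function(gs) {
    if (is.null(gs$n) || gs$n < 1) stop("each group needs n >= 1",
                                        call. = FALSE)
    mult <- gs$multiplier %||% 1
    mu <- gs$mean_time_s %||% 15
    shape <- gs$shape %||% 4
    data.frame(
      animal_id = sprintf("%s_%03d", gs$group, seq_len(gs$n)),
      group = gs$group,
      t_displaced_s = mult * stats::rgamma(gs$n, shape, rate = shape / mu),
      t_stationary_s = stats::rgamma(gs$n, shape, rate = shape / mu)
    )
  })
  do.call(rbind, rows)
}
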