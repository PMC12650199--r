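# Oscillatory event detection: band filter -> envelope -> z-score ->
# threshold runs -> duration criterion. Ripples on hippocampal CA1 LFP,
# delta waves and spindles on prefrontal (mPFC) LFP.

#' Ripple detector parameters
#'
#' Defaults implement the standard two-threshold envelope detector for
#' hippocampal sharp-wave ripples: 100-250 Hz band, envelope = squared
#' signal low-pass filtered (30 Hz default), z-scored over all samples; events are
#' maximal runs above `boundary_threshold_sd` whose maximum reaches
#' `peak_threshold_sd`, lasting 30-100 ms (inclusive).
#'
#' @param band Passband in Hz.
#' @param peak_threshold_sd Envelope peak criterion in SD units.
#' @param boundary_threshold_sd Run boundary criterion in SD units. The
#'   published rule uses the peak threshold for the boundary crossings;
#'   two-threshold variants can lower this.
#' @param min_dur_ms,max_dur_ms Duration bounds in ms, both inclusive.
#' @param envelope_lowpass_hz Envelope smoothing cutoff in Hz. The
#'   default of 30 Hz keeps the envelope's temporal resolution
#'   (~1/(2 x cutoff) = 17 ms) fine enough that a burst shorter than the
#'   30 ms minimum duration is not smeared past the criterion.
#' @param filter_order Butterworth order (applied forward and backward).
#' @return A list of class `ripple_params`.
#' @export
ripple_params <- function(band = c(100, 250), peak_threshold_sd = 3,
                          boundary_threshold_sd = 3, min_dur_ms = 30,
                          max_dur_ms = 100, envelope_lowpass_hz = 30,
                          filter_order = 4) {
  structure(list(band = band, peak_threshold_sd = peak_threshold_sd,
                 boundary_threshold_sd = boundary_threshold_sd,
                 min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
                 envelope_lowpass_hz = envelope_lowpass_hz,
                 filter_order = filter_order),
            class = "ripple_params")
}

#' Delta-wave detector parameters
#'
#' Delta waves are half-waves of the 0.1-5 Hz filtered, z-scored trace,
#' delimited by consecutive zero crossings, lasting 150-500 ms (inclusive)
#' with extremum |z| above 2.
#'
#' @param band Passband in Hz.
#' @param peak_threshold_sd Extremum criterion in SD units.
#' @param min_dur_ms,max_dur_ms Half-wave duration bounds in ms, inclusive.
#' @param polarity `"POS"`, `"NEG"` or `"BOTH"` half-waves.
#' @param filter_order Butterworth order.
#' @return A list of class `delta_params`.
#' @export
delta_params <- function(band = c(0.1, 5), peak_threshold_sd = 2,
                         min_dur_ms = 150, max_dur_ms = 500,
                         polarity = c("BOTH", "POS", "NEG"),
                         filter_order = 2) {
  structure(list(band = band, peak_threshold_sd = peak_threshold_sd,
                 min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
                 polarity = match.arg(polarity), filter_order = filter_order),
            class = "delta_params")
}

#' Spindle detector parameters
#'
#' Spindles are runs of the 9-17 Hz smoothed, z-scored envelope staying
#' above `sustain_threshold_sd` for more than `min_dur_ms` (strict) whose
#' maximum reaches `peak_threshold_sd`. The maximum-duration cap bounds
#' pathological runs and can be disabled with `Inf`.
#'
#' @param band Passband in Hz.
#' @param sustain_threshold_sd Run boundary criterion in SD units.
#' @param peak_threshold_sd Run maximum criterion in SD units.
#' @param min_dur_ms Minimum duration in ms (strictly greater than).
#' @param max_dur_ms Maximum duration cap in ms (inclusive).
#' @param smoothing_ms Gaussian smoothing SD for the envelope, ms.
#' @param filter_order Butterworth order.
#' @return A list of class `spindle_params`.
#' @export
spindle_params <- function(band = c(9, 17), sustain_threshold_sd = 2.5,
                           peak_threshold_sd = 5, min_dur_ms = 500,
                           max_dur_ms = 3000, smoothing_ms = 100,
                           filter_order = 4) {
  structure(list(band = band, sustain_threshold_sd = sustain_threshold_sd,
                 peak_threshold_sd = peak_threshold_sd,
                 min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
                 smoothing_ms = smoothing_ms, filter_order = filter_order),
            class = "spindle_params")
}

as_samples <- function(trace) {
  if (inherits(trace, "channel_trace")) trace$samples else as.numeric(trace)
}

trace_rate <- function(trace, rate = NULL) {
  if (inherits(trace, "channel_trace")) trace$sampling_rate_hz
  else if (!is.null(rate)) rate
  else stop("sampling rate required for bare numeric input", call. = FALSE)
}

# Forward-backward IIR filtering with odd-reflection padding at both
# ends, so the operation commutes with time reversal (the stock
# single-ended padding leaves an asymmetric edge transient). The input
# is pre-scaled to unit SD before filtering: narrow-band recursions
# amplify rounding noise, and a scale-free input keeps the result
# exactly invariant under positive rescaling of the trace.
filtfilt_sym <- function(bf, x) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: trace has zero variance", call. = FALSE)
  }
  xs <- x / s
  k <- max(length(bf$b), length(bf$a))
  pad <- min(n - 1, 30 * (k - 1))
  ext <- c(2 * xs[1] - xs[(pad + 1):2],
           xs,
           2 * xs[n] - xs[(n - 1):(n - pad)])
  y <- signal::filter(bf, ext)
  y <- rev(signal::filter(bf, rev(y)))
  s * y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filter
#'
#' Butterworth filter applied forward and backward with symmetric
#' reflection padding, giving zero phase distortion so that event peak
#' times are unbiased for lag analysis. Pass-band gain is ~1 in mid band
#' and the operation commutes with time reversal.
#'
#' @param trace A [channel_trace()] or numeric vector.
#' @param band `c(lo, hi)` in Hz, `0 < lo < hi < Nyquist`.
#' @param order Butterworth order (default 4; use 2 for very low bands).
#' @param rate Sampling rate in Hz (required for bare numeric input).
#' @return Filtered object of the same type as the input.
#' @export
bandpass_zero_phase <- function(trace, band, order = 4, rate = NULL) {
  fs <- trace_rate(trace, rate)
  x <- as_samples(trace)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop("band [", band[1], ", ", band[2], "] Hz outside (0, Nyquist=",
         fs / 2, ")", call. = FALSE)
  }
  bf <- signal::butter(order, band * 2 / fs, type = "pass")
  y <- filtfilt_sym(bf, x)
  if (inherits(trace, "channel_trace")) {
    trace$samples <- y
    trace
  } else y
}

lowpass_zero_phase <- function(x, cutoff_hz, fs, order = 4) {
  bf <- signal::butter(order, cutoff_hz * 2 / fs, type = "low")
  filtfilt_sym(bf, x)
}

gauss_smooth <- function(x, sd_samples) {
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  np <- length(xp)
  if (as.numeric(np) * length(k) < 5e7) {
    return(as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):
                                                         (half + n)])
  }
  # FFT convolution for long traces (direct convolution is O(n * k))
  m <- np + length(k) - 1L
  kf <- stats::fft(c(k, rep(0, m - length(k))))
  xf <- stats::fft(c(xp, rep(0, m - np)))
  y <- Re(stats::fft(xf * kf, inverse = TRUE)) / m
  y[(2 * half + 1):(2 * half + n)]
}

# Raw (un-normalized) detector envelopes; the z-scored versions divide by
# mean/SD over ALL samples of the transformed trace.
envelope_raw <- function(x, fs, method, band, lowpass_hz = 20,
                         smoothing_ms = 100, order = 4) {
  y <- bandpass_zero_phase(x, band, order = order, rate = fs)
  if (method == "square_lowpass") {
    lowpass_zero_phase(y^2, lowpass_hz, fs)
  } else if (method == "rms_gauss") {
    sq <- gauss_smooth(y^2, smoothing_ms / 1000 * fs)
    sqrt(pmax(sq, 0))
  } else stop("unknown envelope method: ", method, call. = FALSE)
}

#' Normalized (z-scored) detection envelope
#'
#' Band-pass filters the trace, forms an amplitude envelope (squared +
#' low-pass for ripples; Gaussian-smoothed RMS for spindles) and z-scores
#' it using the mean and SD over all samples of the transformed trace.
#'
#' @param trace A [channel_trace()] or numeric vector.
#' @param band Passband in Hz.
#' @param method `"square_lowpass"` or `"rms_gauss"`.
#' @param lowpass_hz Envelope low-pass cutoff (square_lowpass), Hz.
#' @param smoothing_ms Gaussian SD (rms_gauss), ms.
#' @param order Butterworth order.
#' @param rate Sampling rate (bare numeric input only).
#' @return Numeric z-scored envelope, same length as the input.
#' @export
normalized_envelope <- function(trace, band,
                                method = c("square_lowpass", "rms_gauss"),
                                lowpass_hz = 20, smoothing_ms = 100,
                                order = 4, rate = NULL) {
  method <- match.arg(method)
  fs <- trace_rate(trace, rate)
  x <- as_samples(trace)
  env <- envelope_raw(x, fs, method, band, lowpass_hz, smoothing_ms, order)
  s <- stats::sd(env)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: envelope has zero variance", call. = FALSE)
  }
  (env - mean(env)) / s
}

# Maximal runs where cond is TRUE -> first/last sample indices.
threshold_runs <- function(cond) {
  r <- rle(as.logical(cond))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(first = starts[keep], last = ends[keep])
}

# Convert run sample indices into event rows. Boundary times sit at the
# half-sample threshold crossings so the peak is strictly interior.
runs_to_events <- function(runs, env, fs, kind, region, session_id,
                           peak_sign = NULL) {
  if (nrow(runs) == 0L) return(event_table())
  rows <- lapply(seq_len(nrow(runs)), function(k) {
    a <- runs$first[k]; b <- runs$last[k]
    seg <- env[a:b]
    if (!is.null(peak_sign) && peak_sign < 0) seg <- -seg
    pk <- a + which.max(seg) - 1L
    data.frame(
      session_id = session_id, region = region, kind = kind,
      start_s = max((a - 1.5) / fs, (a - 1) / fs - 0.5 / fs, 0),
      peak_s = (pk - 1) / fs,
      end_s = (b - 0.5) / fs,
      peak_z = if (is.null(peak_sign)) env[pk] else abs(env[pk])
    )
  })
  event_table(do.call(rbind, rows))
}

dur_ok <- function(first, last, fs, min_ms, max_ms,
                   min_strict = FALSE) {
  dur_ms <- (last - first + 1) / fs * 1000
  lo <- if (min_strict) dur_ms > min_ms + 1e-9 else dur_ms >= min_ms - 1e-9
  lo & dur_ms <= max_ms + 1e-9
}

#' Detect hippocampal sharp-wave ripples
#'
#' @param lfp CA1 LFP [channel_trace()] (rate must be at least twice the
#'   upper band edge).
#' @param params A [ripple_params()].
#' @param session_id Session label for the output rows.
#' @return An [event_table()] of kind `RIPPLE`.
#' @export
detect_ripples <- function(lfp, params = ripple_params(),
                           session_id = "session") {
  fs <- trace_rate(lfp)
  if (fs < 2 * params$band[2]) {
    stop("sampling rate ", fs, " Hz too low for band up to ",
         params$band[2], " Hz", call. = FALSE)
  }
  env <- normalized_envelope(lfp, params$band, "square_lowpass",
                             lowpass_hz = params$envelope_lowpass_hz,
                             order = params$filter_order)
  runs <- threshold_runs(env >= params$boundary_threshold_sd)
  if (nrow(runs)) {
    mx <- vapply(seq_len(nrow(runs)), function(k)
      max(env[runs$first[k]:runs$last[k]]), numeric(1))
    keep <- mx >= params$peak_threshold_sd &
      dur_ok(runs$first, runs$last, fs, params$min_dur_ms, params$max_dur_ms)
    runs <- runs[keep, , drop = FALSE]
  }
  region <- if (inherits(lfp, "channel_trace")) lfp$region else "CA1"
  runs_to_events(runs, env, fs, "RIPPLE", region, session_id)
}

#' Detect prefrontal delta waves
#'
#' Candidates are half-waves of the band-filtered, z-scored trace delimited
#' by consecutive zero crossings; a half-wave is kept when its extremum
#' |z| exceeds the threshold and its duration lies within the bounds.
#'
#' @param lfp mPFC LFP [channel_trace()].
#' @param params A [delta_params()].
#' @param session_id Session label for the output rows.
#' @return An [event_table()] of kind `DELTA`; `peak_z` is the absolute
#'   extremum.
#' @export
detect_delta <- function(lfp, params = delta_params(),
                         session_id = "session") {
  fs <- trace_rate(lfp)
  y <- bandpass_zero_phase(as_samples(lfp), params$band,
                           order = params$filter_order, rate = fs)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: filtered trace has zero variance", call. = FALSE)
  }
  z <- (y - mean(y)) / s
  sgn <- sign(z)
  sgn[sgn == 0] <- 1
  # half-wave k spans samples cross[k]+1 .. cross[k+1]
  cross <- which(diff(sgn) != 0)
  if (length(cross) < 2L) return(event_table())
  first <- cross[-length(cross)] + 1L
  last <- cross[-1]
  pol <- vapply(seq_along(first), function(k) sgn[first[k]], numeric(1))
  keep_pol <- switch(params$polarity,
                     BOTH = rep(TRUE, length(first)),
                     POS = pol > 0, NEG = pol < 0)
  # boundaries at the zero crossings (half-sample convention)
  dur_ms <- (last - first + 1) / fs * 1000
  ext <- vapply(seq_along(first), function(k)
    max(abs(z[first[k]:last[k]])), numeric(1))
  keep <- keep_pol & ext > params$peak_threshold_sd &
    dur_ms >= params$min_dur_ms - 1e-9 & dur_ms <= params$max_dur_ms + 1e-9
  runs <- data.frame(first = first[keep], last = last[keep])
  if (nrow(runs) == 0L) return(event_table())
  region <- if (inherits(lfp, "channel_trace")) lfp$region else "MPFC"
  rows <- lapply(seq_len(nrow(runs)), function(k) {
    a <- runs$first[k]; b <- runs$last[k]
    pk <- a + which.max(abs(z[a:b])) - 1L
    data.frame(session_id = session_id, region = region, kind = "DELTA",
               start_s = max((a - 1.5) / fs, 0), peak_s = (pk - 1) / fs,
               end_s = (b - 0.5) / fs, peak_z = abs(z[pk]))
  })
  event_table(do.call(rbind, rows))
}

#' Detect prefrontal sleep spindles
#'
#' @param lfp mPFC LFP [channel_trace()].
#' @param params A [spindle_params()].
#' @param session_id Session label for the output rows.
#' @return An [event_table()] of kind `SPINDLE`.
#' @export
detect_spindles <- function(lfp, params = spindle_params(),
                            session_id = "session") {
  fs <- trace_rate(lfp)
  env <- normalized_envelope(lfp, params$band, "rms_gauss",
                             smoothing_ms = params$smoothing_ms,
                             order = params$filter_order)
  runs <- threshold_runs(env >= params$sustain_threshold_sd)
  if (nrow(runs)) {
    mx <- vapply(seq_len(nrow(runs)), function(k)
      max(env[runs$first[k]:runs$last[k]]), numeric(1))
    keep <- mx >= params$peak_threshold_sd &
      dur_ok(runs$first, runs$last, fs, params$min_dur_ms, params$max_dur_ms,
             min_strict = TRUE)
    runs <- runs[keep, , drop = FALSE]
  }
  region <- if (inherits(lfp, "channel_trace")) lfp$region else "MPFC"
  runs_to_events(runs, env, fs, "SPINDLE", region, session_id)
}

#' Restrict events to epochs of given sleep stages
#'
#' Coupling analyses are performed during sleep only; this keeps events
#' whose peak falls in an epoch of the requested stage set.
#'
#' @param events An [event_table()].
#' @param hypnogram A [hypnogram()] covering every event peak.
#' @param stages Character vector of stages to keep (default `"NREM"`).
#' @return Filtered [event_table()].
#' @export
restrict_to_sleep <- function(events, hypnogram, stages = "NREM") {
  if (nrow(events) == 0L) return(events)
  st <- stage_at(hypnogram, events$peak_s)
  if (anyNA(st)) {
    stop("event peak outside hypnogram span", call. = FALSE)
  }
  out <- events[st %in% toupper(stages), , drop = FALSE]
  event_table(out, provenance = attr(events, "provenance"))
}

#' Per-stage event incidence, amplitude and density
#'
#' @param events An [event_table()] (one or several kinds).
#' @param hypnogram A [hypnogram()].
#' @param stages Stages defining the time base (default `"NREM"`).
#' @return Data frame with one row per kind: `n`, `incidence_per_min`
#'   (count / minutes in stages), `mean_peak_z` (NA when no events) and
#'   `density` (fraction of all retained events that are of that kind).
#' @export
event_rates <- function(events, hypnogram, stages = "NREM") {
  mins <- stage_minutes(hypnogram, stages)
  if (mins <= 0) stop("zero time in requested stages", call. = FALSE)
  events <- restrict_to_sleep(events, hypnogram, stages)
  kinds <- EVENT_KINDS[EVENT_KINDS %in% unique(events$kind)]
  if (length(kinds) == 0L) kinds <- unique(events$kind)
  total <- nrow(events)
  rows <- lapply(kinds, function(k) {
    sub <- events[events$kind == k, , drop = FALSE]
    data.frame(kind = k, n = nrow(sub),
               incidence_per_min = nrow(sub) / mins,
               mean_peak_z = if (nrow(sub)) mean(sub$peak_z) else NA_real_,
               density = if (total) nrow(sub) / total else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(kind = character(), n = integer(),
                      incidence_per_min = numeric(),
                      mean_peak_z = numeric(), density = numeric())
  }
  out
}
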