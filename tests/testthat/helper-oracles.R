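# Independent brute-force references used to cross-check the vectorized
# implementations. These deliberately use plain sample-by-sample loops
# and exhaustive enumeration.

# 1/f^alpha noise for fixtures (independent of the package generator).
fixture_noise <- function(n, fs, alpha = 2, sd_uv = 60, seed = 1) {
  set.seed(seed)
  w <- rnorm(n)
  W <- fft(w)
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k) * fs / n
  sc <- ifelse(f > 0, f^(-alpha / 2), 0)
  x <- Re(fft(W * sc, inverse = TRUE)) / n
  sd_uv * x / sd(x)
}

# Sample-scan run finder: walks the envelope one sample at a time.
bf_threshold_runs <- function(env, thr) {
  runs <- list()
  inside <- FALSE
  first <- NA
  for (i in seq_along(env)) {
    if (!inside && env[i] >= thr) {
      inside <- TRUE
      first <- i
    } else if (inside && env[i] < thr) {
      runs[[length(runs) + 1]] <- c(first, i - 1)
      inside <- FALSE
    }
  }
  if (inside) runs[[length(runs) + 1]] <- c(first, length(env))
  runs
}

# Brute-force ripple detector: same envelope, sample-scan runs, explicit
# per-run criteria.
bf_detect_ripples <- function(lfp, params) {
  fs <- lfp$sampling_rate_hz
  env <- normalized_envelope(lfp, params$band, "square_lowpass",
                             lowpass_hz = params$envelope_lowpass_hz,
                             order = params$filter_order)
  out <- list()
  for (run in bf_threshold_runs(env, params$boundary_threshold_sd)) {
    a <- run[1]; b <- run[2]
    dur_ms <- (b - a + 1) / fs * 1000
    if (max(env[a:b]) >= params$peak_threshold_sd &&
        dur_ms >= params$min_dur_ms - 1e-9 &&
        dur_ms <= params$max_dur_ms + 1e-9) {
      pk <- a + which.max(env[a:b]) - 1
      out[[length(out) + 1]] <- c(a, pk, b)
    }
  }
  out
}

bf_detect_spindles <- function(lfp, params) {
  fs <- lfp$sampling_rate_hz
  env <- normalized_envelope(lfp, params$band, "rms_gauss",
                             smoothing_ms = params$smoothing_ms,
                             order = params$filter_order)
  out <- list()
  for (run in bf_threshold_runs(env, params$sustain_threshold_sd)) {
    a <- run[1]; b <- run[2]
    dur_ms <- (b - a + 1) / fs * 1000
    if (max(env[a:b]) >= params$peak_threshold_sd &&
        dur_ms > params$min_dur_ms + 1e-9 &&
        dur_ms <= params$max_dur_ms + 1e-9) {
      pk <- a + which.max(env[a:b]) - 1
      out[[length(out) + 1]] <- c(a, pk, b)
    }
  }
  out
}

bf_detect_delta <- function(lfp, params) {
  fs <- lfp$sampling_rate_hz
  y <- bandpass_zero_phase(lfp$samples, params$band,
                           order = params$filter_order, rate = fs)
  z <- (y - mean(y)) / sd(y)
  sgn <- sign(z)
  sgn[sgn == 0] <- 1
  out <- list()
  first <- 1
  for (i in seq_len(length(z) - 1)) {
    if (sgn[i + 1] != sgn[i]) {
      a <- first; b <- i
      first <- i + 1
      if (a == 1) next   # leading partial half-wave has no left crossing
      dur_ms <- (b - a + 1) / fs * 1000
      pol_ok <- switch(params$polarity,
                       BOTH = TRUE, POS = sgn[a] > 0, NEG = sgn[a] < 0)
      if (pol_ok && max(abs(z[a:b])) > params$peak_threshold_sd &&
          dur_ms >= params$min_dur_ms - 1e-9 &&
          dur_ms <= params$max_dur_ms + 1e-9) {
        pk <- a + which.max(abs(z[a:b])) - 1
        out[[length(out) + 1]] <- c(a, pk, b)
      }
    }
  }
  out
}

# Expected event times from brute-force (first, peak, last) sample
# triples, using the same half-sample crossing convention as the package.
bf_times <- function(triples, fs) {
  if (length(triples) == 0) {
    return(data.frame(start_s = numeric(), peak_s = numeric(),
                      end_s = numeric()))
  }
  do.call(rbind, lapply(triples, function(tr) {
    data.frame(start_s = max((tr[1] - 1.5) / fs, 0),
               peak_s = (tr[2] - 1) / fs,
               end_s = (tr[3] - 0.5) / fs)
  }))
}

# Exhaustive pairing oracle.
bf_pair <- function(lt, ft, lo, hi, greedy = TRUE, eps = 1e-9) {
  pairs <- list()
  if (greedy) {
    used <- rep(FALSE, length(ft))
    for (i in seq_along(lt)) {
      for (j in seq_along(ft)) {
        lag <- ft[j] - lt[i]
        if (!used[j] && lag > lo + eps && lag <= hi + eps) {
          used[j] <- TRUE
          pairs[[length(pairs) + 1]] <- c(i, j)
          break
        }
      }
    }
  } else {
    for (i in seq_along(lt)) {
      for (j in seq_along(ft)) {
        lag <- ft[j] - lt[i]
        if (lag > lo + eps && lag <= hi + eps) {
          pairs[[length(pairs) + 1]] <- c(i, j)
        }
      }
    }
  }
  pairs
}

# Point-event table (zero-duration events) for coupling tests.
point_events <- function(times, kind, region = "MPFC",
                         session_id = "s") {
  times <- sort(times)
  n <- length(times)
  event_table(data.frame(
    session_id = rep(session_id, n), region = rep(region, n),
    kind = rep(kind, n),
    start_s = times, peak_s = times, end_s = times,
    peak_z = rep(3, n),
    event_id = sprintf("%s_%04d", tolower(kind), seq_len(n))))
}

# Recall/precision of detections against ground truth by peak matching.
match_metrics <- function(detected, truth, tol_s) {
  if (nrow(truth) == 0) return(c(recall = NA, precision = NA))
  rec <- if (nrow(detected)) {
    mean(vapply(truth$peak_s, function(t)
      any(abs(detected$peak_s - t) <= tol_s), logical(1)))
  } else 0
  prec <- if (nrow(detected)) {
    mean(vapply(detected$peak_s, function(t)
      any(abs(truth$peak_s - t) <= tol_s), logical(1)))
  } else NA
  c(recall = rec, precision = prec)
}

# One small cached synthetic session shared across test files.
shared_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_session(sim_params(duration_s = 480), seed = 421,
                                 session_id = "shared")
    }
    cache
  }
})
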