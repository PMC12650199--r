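#' @keywords internal
"_PACKAGE"

MODALITIES <- c("EEG", "EMG", "LFP", "OTHER")
REGIONS <- c("CA1", "MPFC", "PARIETAL", "CEREBELLUM", "NECK", "OTHER")
STAGES <- c("WAKE", "NREM", "REM")
EVENT_KINDS <- c("RIPPLE", "DELTA", "SPINDLE")

#' Construct a single uniformly sampled channel
#'
#' A channel trace is one recorded signal: a numeric sample vector in
#' microvolts together with its sampling rate and metadata describing what
#' was recorded (modality) and where (brain region or muscle). Sample `i`
#' (1-based) is located at time `(i - 1) / sampling_rate_hz` seconds from
#' the start of the record; sample intervals are half-open `[start, end)`.
#'
#' @param name Channel label (free text, e.g. `"EEG_parietal"`).
#' @param modality One of `"EEG"`, `"EMG"`, `"LFP"`, `"OTHER"`.
#' @param region One of `"CA1"`, `"MPFC"`, `"PARIETAL"`, `"CEREBELLUM"`,
#'   `"NECK"`, `"OTHER"`.
#' @param sampling_rate_hz Sampling rate in Hz, > 0.
#' @param samples Numeric vector of finite sample values (microvolts).
#' @return An object of class `channel_trace`.
#' @export
channel_trace <- function(name, modality, region, sampling_rate_hz, samples) {
  modality <- match.arg(toupper(modality), MODALITIES)
  region <- match.arg(toupper(region), REGIONS)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("channel '", name, "' has zero samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("channel '", name, "' contains non-finite samples", call. = FALSE)
  }
  structure(
    list(name = as.character(name), modality = modality, region = region,
         sampling_rate_hz = as.numeric(sampling_rate_hz), samples = samples),
    class = "channel_trace"
  )
}

#' Duration of a channel trace in seconds
#' @param trace A `channel_trace`.
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) {
  length(trace$samples) / trace$sampling_rate_hz
}

#' Construct a multi-channel signal record
#'
#' Bundles several [channel_trace()] objects recorded simultaneously. All
#' channels must span one common duration (sample counts may differ when
#' sampling rates differ).
#'
#' @param channels List of `channel_trace` objects.
#' @param session_id Session identifier string.
#' @param start_offset Offset of the record start in seconds (default 0).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(channels, session_id = "session",
                          start_offset = 0) {
  if (!is.list(channels) || length(channels) == 0L) {
    stop("signal_record needs at least one channel", call. = FALSE)
  }
  if (!all(vapply(channels, inherits, logical(1), "channel_trace"))) {
    stop("all channels must be channel_trace objects", call. = FALSE)
  }
  durs <- vapply(channels, trace_duration, numeric(1))
  if (diff(range(durs)) > 1 / max(vapply(channels, `[[`, numeric(1),
                                         "sampling_rate_hz"))) {
    stop("channels disagree on record duration: ",
         paste(signif(durs, 6), collapse = ", "), call. = FALSE)
  }
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  structure(
    list(channels = channels, session_id = as.character(session_id),
         start_offset = as.numeric(start_offset)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat("signal_record '", x$session_id, "': ", length(x$channels),
      " channel(s), ", signif(trace_duration(x$channels[[1]]), 6),
      " s\n", sep = "")
  for (ch in x$channels) {
    cat(sprintf("  %-16s %-5s %-10s %g Hz, %d samples\n", ch$name,
                ch$modality, ch$region, ch$sampling_rate_hz,
                length(ch$samples)))
  }
  invisible(x)
}

#' Select the first channel matching modality/region
#'
#' @param record A `signal_record`.
#' @param modality Optional modality to match.
#' @param region Optional region to match.
#' @return A `channel_trace`; errors if no channel matches.
#' @export
get_channel <- function(record, modality = NULL, region = NULL) {
  for (ch in record$channels) {
    if (!is.null(modality) && ch$modality != toupper(modality)) next
    if (!is.null(region) && ch$region != toupper(region)) next
    return(ch)
  }
  stop("no channel with modality=", modality %||% "*", " region=",
       region %||% "*", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
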