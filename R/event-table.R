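EVENT_CORE_COLS <- c("session_id", "region", "kind", "start_s", "peak_s",
                     "end_s", "peak_z", "duration_ms")

#' Construct a validated table of detected oscillatory events
#'
#' Rows describe one event each (ripple, delta wave or spindle) with start,
#' peak and end times in seconds from session start and the peak amplitude
#' in SD units of the detector envelope. Construction sorts rows by peak
#' time and enforces that events of the same kind in the same region do not
#' overlap.
#'
#' @param df Data frame with at least columns `session_id`, `region`,
#'   `kind`, `start_s`, `peak_s`, `end_s`, `peak_z`. A `duration_ms` column
#'   is recomputed from `end_s - start_s`. Extra columns (e.g. ground-truth
#'   lineage) are preserved.
#' @param provenance Optional list snapshot of the parameters that produced
#'   the table, stored as an attribute.
#' @return A data frame of class `event_table`, sorted by `peak_s`.
#' @export
event_table <- function(df = NULL, provenance = NULL) {
  if (is.null(df)) {
    df <- data.frame(session_id = character(), region = character(),
                     kind = character(), start_s = numeric(),
                     peak_s = numeric(), end_s = numeric(),
                     peak_z = numeric(), duration_ms = numeric())
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- setdiff(EVENT_CORE_COLS, "duration_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("event table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df)) {
    df$kind <- toupper(df$kind)
    bad <- setdiff(unique(df$kind), EVENT_KINDS)
    if (length(bad)) {
      stop("unknown event kind(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(df$start_s > df$end_s)) {
      stop("event with start_s > end_s", call. = FALSE)
    }
    if (any(df$peak_s < df$start_s | df$peak_s > df$end_s)) {
      stop("event peak outside [start_s, end_s]", call. = FALSE)
    }
    df$duration_ms <- (df$end_s - df$start_s) * 1000
    df <- df[order(df$peak_s, df$start_s), , drop = FALSE]
    rownames(df) <- NULL
    for (key in unique(paste(df$kind, df$region))) {
      sub <- df[paste(df$kind, df$region) == key, , drop = FALSE]
      sub <- sub[order(sub$start_s), , drop = FALSE]
      if (nrow(sub) > 1L &&
          any(sub$start_s[-1] < sub$end_s[-nrow(sub)] - 1e-9)) {
        stop("overlapping events of kind/region ", key, call. = FALSE)
      }
    }
  } else {
    df$duration_ms <- numeric()
  }
  front <- intersect(EVENT_CORE_COLS, names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  attr(df, "provenance") <- provenance
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read an event table from tab-separated text
#'
#' Validates the core column set, that `duration_ms` is consistent with
#' `end_s - start_s` to within 1e-6 ms, and the sorting and same-kind
#' non-overlap invariants.
#'
#' @param path Path to a TSV file.
#' @return An `event_table`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(EVENT_CORE_COLS, names(df))
  if (length(miss)) {
    stop("event file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) &&
      max(abs(df$duration_ms - (df$end_s - df$start_s) * 1000)) > 1e-6) {
    stop("duration_ms inconsistent with end_s - start_s", call. = FALSE)
  }
  event_table(df)
}

#' Write an event table to tab-separated text
#' @param table An `event_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  table <- event_table(table, provenance = attr(table, "provenance"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
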