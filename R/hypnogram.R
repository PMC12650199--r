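#' Construct a hypnogram
#'
#' A hypnogram is a sequence of fixed-length epochs, each labelled with a
#' vigilance stage. Epoch `k` (1-based) covers the half-open interval
#' `[start_s + (k-1) * epoch_length_s, start_s + k * epoch_length_s)`.
#'
#' @param stages Character vector of stage labels, each one of `"WAKE"`,
#'   `"NREM"`, `"REM"`.
#' @param epoch_length_s Epoch length in seconds (default 4).
#' @param start_s Time of the first epoch's start, seconds (default 0).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length_s = 4, start_s = 0) {
  stages <- toupper(as.character(stages))
  if (length(stages) == 0L) stop("hypnogram needs >= 1 epoch", call. = FALSE)
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(epoch_length_s) || epoch_length_s <= 0) {
    stop("epoch_length_s must be > 0", call. = FALSE)
  }
  structure(list(stages = stages, epoch_length_s = as.numeric(epoch_length_s),
                 start_s = as.numeric(start_s)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$stages, levels = STAGES))
  cat("hypnogram: ", length(x$stages), " epochs x ", x$epoch_length_s,
      " s (", sum(tb) * x$epoch_length_s / 60, " min)\n  ", sep = "")
  cat(paste(names(tb), tb, sep = "="), sep = "  ")
  cat("\n")
  invisible(x)
}

#' Total duration covered by a hypnogram, in seconds
#' @param h A `hypnogram`.
#' @return Duration in seconds.
#' @export
hypnogram_duration <- function(h) length(h$stages) * h$epoch_length_s

#' Stage label at given times
#'
#' @param h A `hypnogram`.
#' @param times_s Numeric vector of times in seconds.
#' @return Character vector of stage labels; `NA` outside the hypnogram span.
#' @export
stage_at <- function(h, times_s) {
  idx <- floor((times_s - h$start_s) / h$epoch_length_s) + 1L
  out <- rep(NA_character_, length(times_s))
  ok <- idx >= 1L & idx <= length(h$stages)
  out[ok] <- h$stages[idx[ok]]
  out
}

#' Minutes spent in a set of stages
#' @param h A `hypnogram`.
#' @param stages Character vector of stages to total (default all three).
#' @return Minutes as a single number.
#' @export
stage_minutes <- function(h, stages = STAGES) {
  sum(h$stages %in% toupper(stages)) * h$epoch_length_s / 60
}

#' Read a hypnogram from tab-separated text
#'
#' The file must have a header line with columns `epoch_index`, `start_s`
#' and `stage`; epoch indices must be contiguous starting at 1 and stage
#' labels must be WAKE/NREM/REM.
#'
#' @param path Path to a TSV file.
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("epoch_index", "start_s", "stage")
  if (!all(need %in% names(df))) {
    stop("hypnogram file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("hypnogram file has no epochs", call. = FALSE)
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)))) {
    stop("epoch_index must be contiguous 1..n", call. = FALSE)
  }
  el <- if (nrow(df) >= 2L) df$start_s[2] - df$start_s[1] else
    attr(df, "epoch_length_s") %||% 4
  starts <- df$start_s[1] + (seq_len(nrow(df)) - 1) * el
  if (max(abs(starts - df$start_s)) > 1e-6) {
    stop("start_s column is not an arithmetic grid of epoch starts",
         call. = FALSE)
  }
  hypnogram(df$stage, epoch_length_s = el, start_s = df$start_s[1])
}

#' Write a hypnogram to tab-separated text
#' @param h A `hypnogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  df <- data.frame(
    epoch_index = seq_along(h$stages),
    start_s = h$start_s + (seq_along(h$stages) - 1) * h$epoch_length_s,
    stage = h$stages
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
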