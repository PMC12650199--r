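# Cross-regional coupled sequences: delta-spindle (D-S), ripple-delta
# (R-D) and ripple-delta-spindle (R-D-S), counted during sleep and
# normalized per minute.

#' Coupling parameters
#'
#' Lag windows are half-open `(lo, hi]` seconds, peak to peak: a spindle
#' couples to a delta when its peak occurs between 100 ms and 1300 ms
#' after the delta peak; a delta couples to a ripple when its peak occurs
#' between 50 ms and 250 ms after the ripple peak.
#'
#' @param ds_window_s Delta-to-spindle window `(lo, hi]` in seconds.
#' @param rd_window_s Ripple-to-delta window `(lo, hi]` in seconds.
#' @param pairing `"GREEDY_ONE_TO_ONE"` (each event used at most once;
#'   sequences as discrete joint occurrences) or `"ALL_PAIRS"`.
#' @param stages Stages defining "sleep" (default `"NREM"`).
#' @return A list of class `coupling_params`.
#' @export
coupling_params <- function(ds_window_s = c(0.100, 1.300),
                            rd_window_s = c(0.050, 0.250),
                            pairing = c("GREEDY_ONE_TO_ONE", "ALL_PAIRS"),
                            stages = "NREM") {
  for (w in list(ds_window_s, rd_window_s)) {
    if (!(w[1] > 0 && w[1] < w[2])) {
      stop("coupling window must satisfy 0 < lo < hi", call. = FALSE)
    }
  }
  structure(list(ds_window_s = ds_window_s, rd_window_s = rd_window_s,
                 pairing = match.arg(pairing), stages = toupper(stages)),
            class = "coupling_params")
}

event_ids <- function(tbl) {
  if (!is.null(tbl$event_id)) as.character(tbl$event_id)
  else as.character(seq_len(nrow(tbl)))
}

#' Pair leader and follower events within a lag window
#'
#' A follower pairs with a leader when `lo < follower - leader <= hi`
#' (peak times). `GREEDY_ONE_TO_ONE` scans leaders in time order and
#' assigns each the earliest unassigned in-window follower, using each
#' event at most once; `ALL_PAIRS` returns every in-window combination.
#'
#' @param leaders,followers [event_table()]s sorted by `peak_s`.
#' @param window `c(lo, hi)` in seconds, half-open `(lo, hi]`.
#' @param pairing Pairing mode.
#' @return Data frame with `leader_id`, `follower_id`, `lag_s`.
#' @export
pair_events <- function(leaders, followers, window,
                        pairing = c("GREEDY_ONE_TO_ONE", "ALL_PAIRS")) {
  pairing <- match.arg(pairing)
  empty <- data.frame(leader_id = character(), follower_id = character(),
                      lag_s = numeric())
  for (tbl in list(leaders, followers)) {
    if (nrow(tbl) > 1L && is.unsorted(tbl$peak_s)) {
      stop("event tables must be sorted by peak_s", call. = FALSE)
    }
  }
  if (nrow(leaders) == 0L || nrow(followers) == 0L) return(empty)
  lid <- event_ids(leaders)
  fid <- event_ids(followers)
  lt <- leaders$peak_s
  ft <- followers$peak_s
  lo <- window[1]; hi <- window[2]
  eps <- 1e-9   # half-open (lo, hi] up to float rounding of times
  if (pairing == "ALL_PAIRS") {
    rows <- lapply(seq_along(lt), function(i) {
      lag <- ft - lt[i]
      j <- which(lag > lo + eps & lag <= hi + eps)
      if (!length(j)) return(NULL)
      data.frame(leader_id = lid[i], follower_id = fid[j],
                 lag_s = lag[j])
    })
    out <- do.call(rbind, rows)
    return(if (is.null(out)) empty else out)
  }
  used <- rep(FALSE, length(ft))
  res_l <- character(0); res_f <- character(0); res_lag <- numeric(0)
  j0 <- 1L
  for (i in seq_along(lt)) {
    j <- j0
    while (j <= length(ft) && ft[j] - lt[i] <= lo + eps) j <- j + 1L
    j0 <- j
    while (j <= length(ft) && ft[j] - lt[i] <= hi + eps) {
      if (!used[j]) {
        used[j] <- TRUE
        res_l <- c(res_l, lid[i])
        res_f <- c(res_f, fid[j])
        res_lag <- c(res_lag, ft[j] - lt[i])
        break
      }
      j <- j + 1L
    }
  }
  data.frame(leader_id = res_l, follower_id = res_f, lag_s = res_lag)
}

#' Ripple-delta-spindle triple sequences
#'
#' An R-D-S sequence is the conjunction of an R-D pair and a D-S pair
#' through the shared delta: the same delta must follow a ripple within
#' the R-D window and lead a spindle within the D-S window. Under greedy
#' pairing each event participates in at most one triple.
#'
#' @param ripples,deltas,spindles [event_table()]s sorted by `peak_s`.
#' @param params A [coupling_params()].
#' @return Data frame with `ripple_id`, `delta_id`, `spindle_id`.
#' @export
triple_sequences <- function(ripples, deltas, spindles,
                             params = coupling_params()) {
  rd <- pair_events(ripples, deltas, params$rd_window_s, params$pairing)
  ds <- pair_events(deltas, spindles, params$ds_window_s, params$pairing)
  m <- merge(rd, ds, by.x = "follower_id", by.y = "leader_id")
  if (nrow(m) == 0L) {
    return(data.frame(ripple_id = character(), delta_id = character(),
                      spindle_id = character()))
  }
  data.frame(ripple_id = m$leader_id, delta_id = m$follower_id.x %||%
               m$follower_id, spindle_id = m$follower_id.y)
}

#' Coupled-sequence counts and rates for one session window
#'
#' Restricts each event table to the configured sleep stages, counts D-S,
#' R-D and R-D-S sequences and normalizes per minute spent in those
#' stages. Alternative denominators (per recording minute, per leader
#' event) are included in the result for sensitivity.
#'
#' @param ripples,deltas,spindles [event_table()]s for the window.
#' @param hypnogram A [hypnogram()] covering the window.
#' @param params A [coupling_params()].
#' @param phase `"PRE"` or `"POST"` (encoding phase label).
#' @param session_id Session label.
#' @return A list of class `coupling_result` with `counts`, `rates_per_min`
#'   (per sleep minute), `rates_per_recording_min`, `fraction_of_leaders`,
#'   `sleep_minutes` and a parameter snapshot.
#' @export
coupling_rates <- function(ripples, deltas, spindles, hypnogram,
                           params = coupling_params(), phase = "PRE",
                           session_id = "session") {
  mins <- stage_minutes(hypnogram, params$stages)
  if (mins <= 0) stop("zero sleep minutes in requested stages",
                      call. = FALSE)
  r <- restrict_to_sleep(ripples, hypnogram, params$stages)
  d <- restrict_to_sleep(deltas, hypnogram, params$stages)
  s <- restrict_to_sleep(spindles, hypnogram, params$stages)
  ds <- pair_events(d, s, params$ds_window_s, params$pairing)
  rd <- pair_events(r, d, params$rd_window_s, params$pairing)
  rds <- triple_sequences(r, d, s, params)
  counts <- c(ds = nrow(ds), rd = nrow(rd), rds = nrow(rds))
  rec_min <- hypnogram_duration(hypnogram) / 60
  structure(list(
    session_id = session_id,
    phase = toupper(phase),
    counts = counts,
    sleep_minutes = mins,
    rates_per_min = counts / mins,
    rates_per_recording_min = counts / rec_min,
    fraction_of_leaders = c(
      ds = if (nrow(d)) nrow(ds) / nrow(d) else NA_real_,
      rd = if (nrow(r)) nrow(rd) / nrow(r) else NA_real_,
      rds = if (nrow(r)) nrow(rds) / nrow(r) else NA_real_),
    params = unclass(params)
  ), class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat("coupling_result ", x$session_id, " [", x$phase, "]: ",
      x$sleep_minutes, " sleep min\n", sep = "")
  print(round(rbind(counts = x$counts, per_min = x$rates_per_min), 4))
  invisible(x)
}

#' Compare pre- vs post-encoding coupling rates across replicates
#'
#' Computes the post minus pre per-minute rate for each replicate (animal)
#' and sequence type, the group mean difference, and a seeded bootstrap
#' percentile confidence interval over replicates. With a single
#' replicate the CI is flagged undefined (NA).
#'
#' @param pre,post Lists of [coupling_rates()] results, matched by
#'   position (same animal order).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame with one row per sequence type: `mean_pre`,
#'   `mean_post`, `mean_diff`, `ci_lo`, `ci_hi`, `n`.
#' @export
compare_phases <- function(pre, post, n_boot = 2000, conf = 0.95,
                           seed = 1L) {
  if (length(pre) == 0L || length(post) == 0L) {
    stop("need at least one replicate per phase", call. = FALSE)
  }
  if (length(pre) != length(post)) {
    stop("pre and post replicate sets must be matched (equal length)",
         call. = FALSE)
  }
  types <- c("ds", "rd", "rds")
  pre_m <- sapply(pre, function(x) x$rates_per_min[types])
  post_m <- sapply(post, function(x) x$rates_per_min[types])
  pre_m <- matrix(pre_m, nrow = 3, dimnames = list(types, NULL))
  post_m <- matrix(post_m, nrow = 3, dimnames = list(types, NULL))
  diffs <- post_m - pre_m
  n <- ncol(diffs)
  set.seed(seed)
  rows <- lapply(types, function(tp) {
    d <- diffs[tp, ]
    if (n > 1) {
      bm <- vapply(seq_len(n_boot), function(b)
        mean(d[sample.int(n, n, replace = TRUE)]), numeric(1))
      qs <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            names = FALSE)
    } else {
      qs <- c(NA_real_, NA_real_)
    }
    data.frame(sequence_type = toupper(tp),
               mean_pre = mean(pre_m[tp, ]), mean_post = mean(post_m[tp, ]),
               mean_diff = mean(d), ci_lo = qs[1], ci_hi = qs[2], n = n)
  })
  do.call(rbind, rows)
}
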