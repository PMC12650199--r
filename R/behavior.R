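# Behavioral readouts: object-location discrimination index and zero-maze
# zone summaries from labelled position tracks.

#' Object-location discrimination index
#'
#' `DI = (t_displaced - t_stationary) / (t_displaced + t_stationary) * 100`,
#' the normalized preference for the displaced object on a -100..100
#' scale. Antisymmetric: swapping the arguments flips the sign.
#'
#' @param t_displaced_s Time exploring the displaced object, seconds.
#' @param t_stationary_s Time exploring the non-displaced object, seconds.
#' @return DI value(s) in `[-100, 100]`. Vectorized.
#' @export
discrimination_index <- function(t_displaced_s, t_stationary_s) {
  if (any(t_displaced_s < 0 | t_stationary_s < 0)) {
    stop("exploration times must be >= 0", call. = FALSE)
  }
  tot <- t_displaced_s + t_stationary_s
  if (any(tot == 0)) {
    stop("DI undefined: total exploration time is zero", call. = FALSE)
  }
  (t_displaced_s - t_stationary_s) / tot * 100
}

#' Zero-maze zone summary from a labelled position track
#'
#' Time is attributed interval-wise to the zone of the interval's starting
#' sample; distance is the Euclidean step length, attributed the same way
#' (zone-crossing steps count toward the starting zone).
#'
#' @param track Data frame with columns `t_s` (strictly increasing),
#'   `x_cm`, `y_cm`, `zone` (`"OPEN"` or `"CLOSED"`).
#' @return Named list: `open_time_s`, `closed_time_s`, `open_distance_cm`,
#'   `closed_distance_cm`.
#' @export
zone_summary <- function(track) {
  need <- c("t_s", "x_cm", "y_cm", "zone")
  if (!all(need %in% names(track))) {
    stop("track needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(track) < 2L) stop("track needs >= 2 samples", call. = FALSE)
  if (any(diff(track$t_s) <= 0)) {
    stop("track time must be strictly increasing", call. = FALSE)
  }
  zone <- toupper(track$zone)
  n <- nrow(track)
  dt <- diff(track$t_s)
  step <- sqrt(diff(track$x_cm)^2 + diff(track$y_cm)^2)
  zstart <- zone[-n]
  list(
    open_time_s = sum(dt[zstart == "OPEN"]),
    closed_time_s = sum(dt[zstart == "CLOSED"]),
    open_distance_cm = sum(step[zstart == "OPEN"]),
    closed_distance_cm = sum(step[zstart == "CLOSED"])
  )
}

#' Per-animal behavioral metric table
#'
#' One row per animal with its group label and discrimination index; no
#' aggregation beyond the per-animal metric, so the output feeds directly
#' into standard group statistics.
#'
#' @param trials Data frame with columns `animal_id`, `group`,
#'   `t_displaced_s`, `t_stationary_s` (as written by
#'   [generate_behavior_table()]).
#' @return Data frame with `animal_id`, `group`, `t_displaced_s`,
#'   `t_stationary_s`, `di`.
#' @export
group_table <- function(trials) {
  need <- c("animal_id", "group", "t_displaced_s", "t_stationary_s")
  if (!all(need %in% names(trials))) {
    stop("trials needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(trials$group, trials$animal_id)
  if (anyDuplicated(key)) {
    stop("duplicate animal_id within group", call. = FALSE)
  }
  out <- trials[, need]
  out$di <- discrimination_index(trials$t_displaced_s,
                                 trials$t_stationary_s)
  out
}
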