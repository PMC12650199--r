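# Pipeline configuration: one nested list holding staging, detector,
# coupling, spectra and simulation parameters plus the master seed.
# Round-trips losslessly through YAML.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every default filled in.
#' Detector thresholds and coupling windows default to the published
#' filter/threshold/duration rules; staging, spectra and simulation
#' defaults are documented in the package vignette.
#'
#' @param seed Master random seed (integer).
#' @return Named list with components `seed`, `staging`, `detectors`
#'   (blocks `ripple`, `delta`, `spindle`), `coupling`, `spectra`,
#'   `simulation`.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    staging = unclass(staging_params()),
    detectors = list(
      ripple = unclass(ripple_params()),
      delta = unclass(delta_params()),
      spindle = unclass(spindle_params())
    ),
    coupling = unclass(coupling_params()),
    spectra = list(band = c(0.5, 30),
                   bands = list(delta = c(0.5, 4), theta = c(6, 9),
                                alpha = c(9, 12), beta = c(12, 30))),
    simulation = unclass(sim_params())
  )
}

# YAML maps come back as named lists; fields that are named numeric
# vectors in R are coerced back so round-trips are lossless in value.
normalize_config <- function(cfg) {
  vec_fields <- c("bout_means_s", "densities_per_min", "amplitude_sd",
                  "eeg_delta_uv", "eeg_theta_uv", "emg_uv")
  sim <- cfg$simulation
  if (!is.null(sim)) {
    for (f in vec_fields) {
      if (is.list(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
    }
    if (is.list(sim$event_dur_ms)) {
      sim$event_dur_ms <- lapply(sim$event_dur_ms, unlist)
    }
    cfg$simulation <- sim
  }
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file.
#' @return Configuration list (validated).
#' @export
read_config <- function(path) {
  cfg <- normalize_config(yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

named_to_list <- function(x) {
  if (is.list(x)) {
    lapply(x, named_to_list)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else x
}

#' Write a pipeline configuration to YAML
#'
#' Named vectors are written as YAML maps so their names survive the
#' round trip; [read_config()] folds them back into vectors.
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(named_to_list(config), path, precision = 15)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks the presence of every required block and elementary value
#' constraints; errors name the offending field path.
#'
#' @param config Configuration list.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  need <- function(block, path) {
    if (is.null(block)) stop("config error at '", path, "': missing",
                             call. = FALSE)
    block
  }
  need(config$seed, "seed")
  st <- need(config$staging, "staging")
  if (st$epoch_length_s <= 0) stop("config error at 'staging.epoch_length_s'",
                                   call. = FALSE)
  det <- need(config$detectors, "detectors")
  for (b in c("ripple", "delta", "spindle")) {
    blk <- need(det[[b]], paste0("detectors.", b))
    if (blk$band[1] <= 0 || blk$band[1] >= blk$band[2]) {
      stop("config error at 'detectors.", b, ".band'", call. = FALSE)
    }
  }
  cp <- need(config$coupling, "coupling")
  for (w in c("ds_window_s", "rd_window_s")) {
    win <- need(cp[[w]], paste0("coupling.", w))
    if (!(win[1] > 0 && win[1] < win[2])) {
      stop("config error at 'coupling.", w, "'", call. = FALSE)
    }
  }
  need(config$simulation, "simulation")
  sim <- config$simulation
  for (p in c("coupling_prob_rd", "coupling_prob_ds")) {
    v <- sim[[p]]
    if (!is.null(v) && (v < 0 || v > 1)) {
      stop("config error at 'simulation.", p, "': must be in [0,1]",
           call. = FALSE)
    }
  }
  invisible(config)
}

# Deterministic child seed derived from a parent seed and a stage tag, so
# inserting a stage does not reshuffle other stages' randomness. Kept
# below 2^31 - 1.
seed_child <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}
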