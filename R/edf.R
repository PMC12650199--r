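# Minimal EDF (16-bit European Data Format) carrier for multi-channel
# signals. Header fields are fixed-width ASCII; data records hold int16
# little-endian samples channel by channel. One data record spans 1 s, so
# every sampling rate must be a whole number of samples per second.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'",
                             call. = FALSE)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

#' Write a signal record to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range chosen
#' to cover the observed data, so the maximum round-trip error is
#' `(physMax - physMin) / 65535` per channel. Channel modality/region
#' metadata is not representable in EDF labels; use
#' [write_channel_map()] to store it alongside.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(record, path) {
  if (!inherits(record, "signal_record")) {
    stop("record must be a signal_record", call. = FALSE)
  }
  chans <- record$channels
  rates <- vapply(chans, `[[`, numeric(1), "sampling_rate_hz")
  if (any(abs(rates - round(rates)) > 1e-9)) {
    stop("EDF layout requires an integer number of samples per 1 s record; ",
         "got rates ", paste(rates, collapse = ", "), call. = FALSE)
  }
  for (ch in chans) {
    if (!all(is.finite(ch$samples))) {
      stop("channel '", ch$name, "' contains non-finite samples",
           call. = FALSE)
    }
  }
  n_rec <- max(vapply(chans, function(ch)
    ceiling(length(ch$samples) / ch$sampling_rate_hz), numeric(1)))
  ns <- length(chans)

  phys <- lapply(chans, function(ch) {
    m <- max(abs(range(ch$samples)), 1e-6)
    # physical limits are written as fixed-width ASCII; quantize against
    # the value the header actually carries, not the full-precision one
    mr <- as.numeric(sprintf("%.5g", m))
    while (mr < m) mr <- as.numeric(sprintf("%.5g", mr * 1.0001))
    c(-mr, mr)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste("session", record$session_id), 80),
    edf_pad("sleepcoupler synthetic/analysis record", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  field <- function(f, width) {
    for (i in seq_len(ns)) writeChar(edf_pad(f(i), width), con, eos = NULL,
                                     useBytes = TRUE)
  }
  field(function(i) chans[[i]]$name, 16)
  field(function(i) paste(chans[[i]]$modality, chans[[i]]$region), 80)
  field(function(i) "uV", 8)
  field(function(i) edf_num(phys[[i]][1], 8), 8)
  field(function(i) edf_num(phys[[i]][2], 8), 8)
  field(function(i) "-32768", 8)
  field(function(i) "32767", 8)
  field(function(i) "", 80)
  field(function(i) round(chans[[i]]$sampling_rate_hz), 8)
  field(function(i) "", 32)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    ch <- chans[[i]]
    spr <- round(ch$sampling_rate_hz)
    x <- ch$samples
    pad <- n_rec * spr - length(x)
    if (pad > 0) x <- c(x, rep(0, pad))
    pmin_ <- phys[[i]][1]; pmax_ <- phys[[i]][2]
    d <- round((x - pmin_) / (pmax_ - pmin_) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  sprs <- vapply(chans, function(ch) round(ch$sampling_rate_hz), numeric(1))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * sprs[i] + 1):(r * sprs[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a signal record
#'
#' @param path Path to an EDF/EDF+ file.
#' @param channel_map Optional named list mapping channel labels to
#'   `list(modality =, region =)`, as produced by [read_channel_map()].
#'   Unmapped channels get modality and region `"OTHER"`.
#' @return A [signal_record()] with samples in physical units (microvolts
#'   when the file's physical dimension is uV; EDF physical scaling is
#'   applied as declared in the header).
#' @export
read_signals <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("corrupt EDF header: file too short",
                                  call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", width)
    trimws(rawToChar(raw))
  }
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, rec_dur, ns))) {
    stop("corrupt EDF header: non-numeric header fields", call. = FALSE)
  }
  if (ns < 1L) stop("EDF file declares zero signals", call. = FALSE)
  if (hdr_bytes != 256 * (ns + 1)) {
    stop("corrupt EDF header: header byte count inconsistent with ns",
         call. = FALSE)
  }
  rdn <- function(width) vapply(seq_len(ns), function(i) rd(width),
                                character(1))
  labels <- rdn(16)
  rdn(80)
  rdn(8)                                 # physical dimension
  pmin_ <- as.numeric(rdn(8)); pmax_ <- as.numeric(rdn(8))
  dmin_ <- as.numeric(rdn(8)); dmax_ <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr))) {
    stop("corrupt EDF header: non-numeric signal fields", call. = FALSE)
  }
  expected <- hdr_bytes + n_rec * sum(spr) * 2
  if (sz != expected) {
    stop("EDF record count mismatch: file has ", sz, " bytes, header ",
         "implies ", expected, call. = FALSE)
  }
  raw_all <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                     signed = TRUE, endian = "little")
  offs <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  mat <- matrix(raw_all, nrow = per_rec)
  chans <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- as.vector(mat[(offs[i] + 1L):offs[i + 1L], , drop = FALSE])
    x <- (d - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i]) +
      pmin_[i]
    map <- channel_map[[labels[i]]]
    chans[[i]] <- channel_trace(
      name = labels[i],
      modality = map$modality %||% "OTHER",
      region = map$region %||% "OTHER",
      sampling_rate_hz = spr[i] / rec_dur,
      samples = x
    )
  }
  signal_record(chans, session_id = sub("^session ", "",
                                        basename(path)))
}

#' Write a channel map sidecar (JSON)
#'
#' EDF labels are free text, so modality and region are stored in a JSON
#' sidecar keyed by channel label.
#'
#' @param record A [signal_record()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_channel_map <- function(record, path) {
  m <- lapply(record$channels, function(ch)
    list(modality = ch$modality, region = ch$region))
  names(m) <- vapply(record$channels, `[[`, character(1), "name")
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a channel map sidecar (JSON)
#' @param path Path to a JSON channel map.
#' @return Named list of `list(modality, region)` keyed by channel label.
#' @export
read_channel_map <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
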