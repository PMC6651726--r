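#' Write / read a session recording in the native container
#'
#' The native on-disk format is a versioned single-file R serialization
#' holding named fields `eeg` (8 x N, microvolts), `imu` (6 x N, counts),
#' `fs` (Hz), `channel_names`, optional `truth_events`
#' (columns `stimulus_time_s`, `braking_time_s`) and `schema` (format
#' version string). `read_session()` validates every field and names the
#' first missing or malformed one.
#'
#' @param session A `brake_session`.
#' @param path File path (conventionally `.brakesession.rds`).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns a `brake_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "brake_session"))
  payload <- list(
    schema = "brakeintent-session-v1",
    eeg = session$eeg,
    imu = session$imu,
    fs = session$fs,
    channel_names = session$channel_names,
    truth_events = session$truth_events
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, "brakeintent-session-v1")) {
    stop("not a brakeintent session file: missing or unknown `schema` field")
  }
  for (field in c("eeg", "imu", "fs")) {
    if (is.null(payload[[field]])) stop(sprintf("malformed session file: missing field `%s`", field))
  }
  if (!is.matrix(payload$eeg) || nrow(payload$eeg) != 8) {
    stop(sprintf("expected 8 EEG channels, found %s",
                 if (is.matrix(payload$eeg)) nrow(payload$eeg) else "none"))
  }
  if (!is.matrix(payload$imu) || nrow(payload$imu) != 6) {
    stop("expected 6 IMU channels")
  }
  new_brake_session(payload$eeg, payload$imu, payload$fs, payload$truth_events)
}

#' Construct a session from raw arrays
#'
#' @param eeg 8 x N numeric matrix (microvolts), rows in montage order
#'   F3, F4, C3, C4, P3, P4, O1, O2.
#' @param imu 6 x N numeric matrix (rows accel_x/y/z, gyro_x/y/z, counts).
#' @param fs Sampling rate in Hz (shared EEG/IMU clock).
#' @param truth_events Optional tibble with `stimulus_time_s`,
#'   `braking_time_s` (strictly increasing, braking after stimulus).
#' @return A `brake_session`.
#' @export
new_session <- function(eeg, imu, fs = 128, truth_events = NULL) {
  if (is.null(rownames(eeg))) rownames(eeg) <- eeg_channel_names()
  if (is.null(rownames(imu))) {
    rownames(imu) <- c("accel_x", "accel_y", "accel_z", "gyro_x", "gyro_y", "gyro_z")
  }
  new_brake_session(eeg, imu, fs, truth_events)
}

#' Export the EEG of a session as an EDF file
#'
#' Writes a standard European Data Format (EDF) file: one 1-s data record per
#' second of signal, 8 channels at the session rate, 16-bit samples scaled
#' to each channel's physical range in microvolts. Channel labels are the
#' 10-20 names F3..O2. Intended for third-party viewers; the quantization of
#' the 16-bit encoding limits round-trip fidelity to about 1 part in 10^4 of
#' the channel range.
#'
#' @param session A `brake_session` with at least one full second of data.
#' @param path Output path (`.edf`).
#' @return `path`, invisibly.
#' @export
export_eeg_edf <- function(session, path) {
  stopifnot(inherits(session, "brake_session"))
  fs <- session$fs
  n_rec <- floor(ncol(session$eeg) / fs)
  if (n_rec < 1) stop("session holds less than one EDF data record (1 s)")
  eeg <- session$eeg[, seq_len(n_rec * fs), drop = FALSE]
  nch <- nrow(eeg)

  phys_min <- floor(apply(eeg, 1, min))
  phys_max <- ceiling(apply(eeg, 1, max))
  same <- phys_max <= phys_min
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768
  dig_max <- 32767

  pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8),                                   # version
    pad("X X X X", 80),                            # patient id (anonymous)
    pad("Startdate X X X X", 80),                  # recording id
    "01.01.00", "00.00.00",                        # start date/time
    pad(256 + nch * 256, 8),                       # header bytes
    pad("", 44),                                   # reserved
    pad(n_rec, 8),
    pad("1", 8),                                   # record duration (s)
    pad(nch, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste0(vapply(rownames(eeg), pad, "", width = 16), collapse = ""),
    paste0(rep(pad("AgAgCl electrode", 80), nch), collapse = ""),
    paste0(rep(pad("uV", 8), nch), collapse = ""),
    paste0(vapply(phys_min, pad, "", width = 8), collapse = ""),
    paste0(vapply(phys_max, pad, "", width = 8), collapse = ""),
    paste0(rep(pad(dig_min, 8), nch), collapse = ""),
    paste0(rep(pad(dig_max, 8), nch), collapse = ""),
    paste0(rep(pad("", 80), nch), collapse = ""),  # prefiltering
    paste0(rep(pad(fs, 8), nch), collapse = ""),   # samples per record
    paste0(rep(pad("", 32), nch), collapse = "")   # reserved
  ), con, eos = NULL)

  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((eeg[ch, idx] - phys_min[ch]) * gain[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read back the EEG channels of an EDF file
#'
#' Minimal reader for the continuous 16-bit EDF layout written by
#' [export_eeg_edf()] (and standard single-rate EDF recordings generally).
#'
#' @param path EDF file path.
#' @return List: `signals` (channels x samples matrix with channel-label
#'   rownames, physical units), `fs` (per-record sample count / record
#'   duration).
#' @export
read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  nch <- as.integer(substr(hdr, 253, 256))
  chdr <- readChar(con, 256 * nch, useBytes = TRUE)
  fld <- function(width, offset) {
    vapply(seq_len(nch), function(i) {
      substr(chdr, offset + (i - 1) * width + 1, offset + i * width)
    }, "")
  }
  labels <- trimws(fld(16, 0))
  off <- 16 * nch + 80 * nch + 8 * nch
  phys_min <- as.numeric(fld(8, off))
  phys_max <- as.numeric(fld(8, off + 8 * nch))
  dig_min <- as.numeric(fld(8, off + 16 * nch))
  dig_max <- as.numeric(fld(8, off + 24 * nch))
  spr <- as.integer(fld(8, off + 32 * nch + 80 * nch))
  sig <- vector("list", nch)
  for (i in seq_len(nch)) sig[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      raw <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      phys <- (raw - dig_min[ch]) / (dig_max[ch] - dig_min[ch]) *
        (phys_max[ch] - phys_min[ch]) + phys_min[ch]
      sig[[ch]][((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  out <- do.call(rbind, sig)
  rownames(out) <- labels
  list(signals = out, fs = spr[1] / rec_dur)
}
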