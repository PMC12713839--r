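## Minimal EDF (European Data Format) support: continuous recordings,
## 16-bit samples, one sampling rate across channels, 1-s data records.
## This is deliberately a small subset of the format -- enough to carry
## EEG/EMG polysomnography between tools -- not a general EDF library.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1, nchar(s) - width + 6), width = 1)
    if (nchar(s) <= width) break
    x <- signif(x, 6)
    s <- formatC(x, format = "g", digits = 6, width = 1)
    break
  }
  if (nchar(s) > width) stop("cannot format ", x, " in ", width, " chars")
  edf_pad(s, width)
}

#' Write a signal record to an EDF file
#'
#' Writes a [signal_record()] as a continuous EDF file with 1-second data
#' records and 16-bit samples.  Each channel is scaled independently to
#' its own physical range, so the round-trip error is bounded by
#' `max(abs(x)) / 32767` per channel (writer precision).  Zeitgeber
#' alignment and the light schedule are stored in the recording
#' identification field; the nominal start clock time is written as
#' `09:00 + start_zt` (lights-on at 9 am).
#'
#' @param record A [signal_record()] whose duration is a whole number of
#'   seconds and whose sampling rate is a positive integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signal_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n <- length(record$channels[[1]])
  if (n %% fs != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- n %/% fs
  ns <- length(record$channels)

  phys_max <- vapply(record$channels, function(x) {
    a <- max(abs(x), 1e-6)
    signif(a * 1.0001, 6)
  }, numeric(1))
  dig_max <- 32767L

  clock <- (9 + record$start_zt) %% 24
  hh <- floor(clock); mm <- floor((clock - hh) * 60)
  ss <- round(((clock - hh) * 60 - mm) * 60)
  rec_id <- sprintf("startZT=%.6f sched=%s", record$start_zt,
                    if (record$schedule$dd) "DD" else "LD")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad(rec_id, 80))
  wr(edf_pad("01.01.26", 8))
  wr(edf_pad(sprintf("%02d.%02d.%02d", hh, mm, ss), 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad(1, 8))
  wr(edf_pad(ns, 4))

  for (lab in names(record$channels)) wr(edf_pad(lab, 16))
  for (i in seq_len(ns)) wr(edf_pad(record$roles[i], 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_num(-phys_max[i]))
  for (i in seq_len(ns)) wr(edf_num(phys_max[i]))
  for (i in seq_len(ns)) wr(edf_pad(-dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(fs, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  # digitize once per channel, then interleave record by record
  dig <- lapply(seq_len(ns), function(i) {
    as.integer(round(record$channels[[i]] / phys_max[i] * dig_max))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", width)))
}

#' Read a signal record from an EDF file
#'
#' Reads a continuous 16-bit EDF file into a [signal_record()].  Channel
#' roles are inferred from the label prefix (`"EEG"`/`"EMG"`) unless
#' `roles` is supplied.  All channels must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @param roles Optional explicit channel roles (overrides label
#'   inference).
#' @return A [signal_record()] with samples in the file's physical units
#'   (microvolts as written by [write_signal_record()]).
#' @export
read_signal_record <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8)
  if (version != "0") stop("unsupported format: not an EDF file (version '",
                           version, "')")
  read_edf_field(con, 80)                     # patient id
  rec_id <- read_edf_field(con, 80)
  read_edf_field(con, 8)                      # start date
  start_time <- read_edf_field(con, 8)
  read_edf_field(con, 8)                      # header bytes
  read_edf_field(con, 44)                     # reserved
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))

  fields <- function(width) vapply(seq_len(ns), function(i)
    read_edf_field(con, width), character(1))
  labels <- fields(16)
  fields(80)                                  # transducer
  fields(8)                                   # physical dimension
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)                                  # prefiltering
  nr <- as.integer(fields(8))
  fields(32)                                  # reserved

  if (length(unique(nr / rec_dur)) != 1L)
    stop("unsupported format: channels have mixed sampling rates (",
         paste(unique(nr / rec_dur), collapse = ", "), " Hz)")
  fs <- nr[1] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * sum(nr), size = 2,
                 endian = "little")
  # de-interleave: records are [ch1 block, ch2 block, ...] repeated
  per_rec <- sum(nr)
  offs <- c(0, cumsum(nr))
  channels <- vector("list", ns)
  for (i in seq_len(ns)) {
    sel <- as.vector(outer((offs[i] + 1):offs[i + 1],
                           (seq_len(n_rec) - 1) * per_rec, `+`))
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    channels[[i]] <- (raw[sel] - dig_min[i]) * gain + phys_min[i]
  }
  names(channels) <- labels

  start_zt <- NA_real_
  dd <- FALSE
  m <- regmatches(rec_id, regexec("startZT=([0-9.]+) sched=(LD|DD)", rec_id))[[1]]
  if (length(m) == 3) {
    start_zt <- as.numeric(m[2])
    dd <- m[3] == "DD"
  } else {
    tp <- as.numeric(strsplit(start_time, ".", fixed = TRUE)[[1]])
    if (length(tp) == 3 && !anyNA(tp))
      start_zt <- (tp[1] + tp[2] / 60 + tp[3] / 3600 - 9) %% 24
  }
  if (is.na(start_zt)) start_zt <- 0

  if (is.null(roles)) roles <- infer_channel_roles(labels)
  if (!any(roles == "EEG") || !any(roles == "EMG"))
    stop("role assignment failed: need at least one EEG and one EMG channel, ",
         "got labels: ", paste(labels, collapse = ", "))
  signal_record(channels, roles = roles, sampling_rate = fs,
                start_zt = start_zt,
                schedule = light_schedule(dd = dd))
}
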