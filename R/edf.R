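#' Read an EDF/EDF+ file
#'
#' Minimal reader for the European Data Format, the distribution format of
#' the PhysioNet 64-channel motor movement/imagery recordings. All signals
#' are returned at their native sampling rate; annotation signals ("EDF
#' Annotations") are dropped; sample values are converted from digital to
#' physical units using the per-signal header calibration.
#'
#' All data signals must share one sampling rate (equal samples per data
#' record); a signal whose calibration gain is zero (degenerate physical or
#' digital range) raises an error rather than being passed through silently.
#'
#' @param path path to an EDF/EDF+ file.
#' @param subject_id,task_id optional integer labels to attach (EDF itself
#'   carries no such labels).
#' @return An [eeg_recording] with K channels at the native sampling rate.
#' @export
read_edf <- function(path, subject_id = NA_integer_, task_id = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  fixed <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256L)
    stop("format error: truncated EDF header")
  fld <- function(from, len) substr(fixed, from, from + len - 1L)
  num <- function(s, name) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop("format error: non-numeric EDF header field '",
                       name, "': '", trimws(s), "'")
    v
  }
  version <- trimws(fld(1L, 8L))
  if (version != "0")
    stop("format error: unsupported EDF version field '", version, "'")
  n_records <- num(fld(237L, 8L), "number of data records")
  rec_dur   <- num(fld(245L, 8L), "data record duration")
  ns        <- num(fld(253L, 4L), "number of signals")
  if (ns < 1L) stop("format error: EDF header declares 0 signals")
  if (n_records < 1L)
    stop("format error: EDF header declares ", n_records, " data records")
  if (rec_dur <= 0)
    stop("format error: non-positive data record duration")
  ns <- as.integer(ns)

  per <- function(len, name, numeric = FALSE) {
    raw <- readChar(con, rep(len, ns), useBytes = TRUE)
    if (numeric) vapply(raw, num, 0, name = name, USE.NAMES = FALSE)
    else trimws(raw)
  }
  labels    <- per(16L, "label")
  per(80L, "transducer")
  per(8L, "physical dimension")
  phys_min  <- per(8L, "physical minimum", numeric = TRUE)
  phys_max  <- per(8L, "physical maximum", numeric = TRUE)
  dig_min   <- per(8L, "digital minimum",  numeric = TRUE)
  dig_max   <- per(8L, "digital maximum",  numeric = TRUE)
  per(80L, "prefiltering")
  nr        <- per(8L, "samples per record", numeric = TRUE)
  per(32L, "reserved")

  is_annot <- labels == "EDF Annotations"
  keep <- which(!is_annot)
  if (length(keep) == 0L)
    stop("format error: EDF file contains no data signals")
  if (length(unique(nr[keep])) != 1L)
    stop("format error: unequal channel lengths (samples per record: ",
         paste(unique(nr[keep]), collapse = "/"), ")")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  bad <- keep[!is.finite(gain[keep]) | gain[keep] == 0]
  if (length(bad))
    stop("format error: zero calibration gain for signal(s) ",
         paste(labels[bad], collapse = ", "))

  n_records <- as.integer(n_records)
  nr <- as.integer(nr)
  out <- matrix(0, nrow = length(keep), ncol = nr[keep[1L]] * n_records)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nr[s], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(dig) != nr[s])
        stop("format error: truncated data record ", r)
      j <- match(s, keep)
      if (!is.na(j)) {
        idx <- ((r - 1L) * nr[s] + 1L):(r * nr[s])
        out[j, idx] <- (dig - dig_min[s]) * gain[s] + phys_min[s]
      }
    }
  }
  fs <- nr[keep[1L]] / rec_dur
  eeg_recording(out, fs = fs, subject_id = subject_id, task_id = task_id,
                channel_names = labels[keep])
}

#' Write an EDF file
#'
#' Writes an [eeg_recording] as a single-data-record EDF file with 16-bit
#' quantization over each channel's observed amplitude range. Intended for
#' fixtures and interchange, not archival: quantization error is bounded by
#' half a digital step per sample.
#'
#' @param rec an [eeg_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  K <- n_channels(rec); L <- n_samples(rec)
  pad <- function(s, len) {
    s <- as.character(s)
    if (nchar(s) > len) stop("EDF header field too long: '", s, "'")
    formatC(s, width = -len)
  }
  fnum <- function(x, len) {
    s <- formatC(x, format = "g", digits = len - 2L, width = 1L)
    if (nchar(s) > len) s <- formatC(x, format = "g", digits = 3L)
    pad(s, len)
  }
  phys_min <- apply(rec$data, 1L, min)
  phys_max <- apply(rec$data, 1L, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767

  header_bytes <- 256L + 256L * K
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  w(pad("0", 8L))                                   # version
  w(pad("X X X X", 80L))                            # patient id
  w(pad("Startdate X X X X", 80L))                  # recording id
  w(pad("01.01.00", 8L)); w(pad("00.00.00", 8L))    # date, time
  w(pad(header_bytes, 8L))
  w(pad("", 44L))
  w(pad(1L, 8L))                                    # one data record
  w(fnum(L / rec$fs, 8L))                           # record duration (s)
  w(pad(K, 4L))
  for (s in rec$channel_names) w(pad(substr(s, 1L, 16L), 16L))
  for (i in seq_len(K)) w(pad("", 80L))             # transducer
  for (i in seq_len(K)) w(pad("uV", 8L))
  for (i in seq_len(K)) w(fnum(phys_min[i], 8L))
  for (i in seq_len(K)) w(fnum(phys_max[i], 8L))
  for (i in seq_len(K)) w(pad(dig_min, 8L))
  for (i in seq_len(K)) w(pad(dig_max, 8L))
  for (i in seq_len(K)) w(pad("", 80L))             # prefiltering
  for (i in seq_len(K)) w(pad(L, 8L))
  for (i in seq_len(K)) w(pad("", 32L))

  # re-read the header's rounded physical range so read(write(x)) uses the
  # exact calibration the file declares
  rnum <- function(x, len) as.numeric(trimws(fnum(x, len)))
  for (i in seq_len(K)) {
    pmin <- rnum(phys_min[i], 8L); pmax <- rnum(phys_max[i], 8L)
    gain <- (pmax - pmin) / (dig_max - dig_min)
    dig <- round((rec$data[i, ] - pmin) / gain + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}
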