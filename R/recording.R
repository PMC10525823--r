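#' Construct an EEG recording
#'
#' The basic container of the package: a channels-by-samples signal matrix
#' together with its sampling rate and its subject/task labels. Values are
#' on whatever amplitude scale the source used (typically microvolts); none
#' of the downstream math depends on the unit.
#'
#' @param data numeric matrix, K channels x L samples.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id integer subject label (1-based), or `NA` if unknown.
#' @param task_id integer task label (1-based), or `NA` if unknown.
#' @param channel_names character vector of length K; defaults to
#'   `"ch1".."chK"`.
#' @return An object of class `eeg_recording`: a list with elements
#'   `data`, `fs`, `subject_id`, `task_id`, `channel_names`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 100), 2), fs = 160)
#' n_channels(rec)
#' n_samples(rec)
#' @export
eeg_recording <- function(data, fs, subject_id = NA_integer_,
                          task_id = NA_integer_, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("recording must have at least 1 channel and 1 sample")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per channel")
  structure(
    list(data = unname(data), fs = as.numeric(fs),
         subject_id = as.integer(subject_id), task_id = as.integer(task_id),
         channel_names = as.character(channel_names)),
    class = "eeg_recording")
}

#' @rdname eeg_recording
#' @param x an `eeg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat(sprintf("  subject: %s  task: %s\n",
              ifelse(is.na(x$subject_id), "?", x$subject_id),
              ifelse(is.na(x$task_id), "?", x$task_id)))
  invisible(x)
}

#' Read an EEG matrix from delimited text
#'
#' Parses a comma-delimited text file with one channel per row into an
#' [eeg_recording]. This is the toy-matrix dialect shared with the
#' synthetic-data generator, so simulated and real recordings go through
#' one loader.
#'
#' @param path path to a comma-delimited text file, one channel per row.
#' @param fs sampling rate in Hz.
#' @param subject_id,task_id integer labels attached to the recording.
#' @return An [eeg_recording].
#' @seealso [write_matrix()] for the inverse, [read_edf()] for EDF files.
#' @export
read_matrix <- function(path, fs, subject_id = NA_integer_,
                        task_id = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("format error: empty matrix file: ", path)
  rows <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("format error: ragged rows in %s (row lengths %s)",
                 path, paste(unique(ncols), collapse = "/")))
  vals <- suppressWarnings(lapply(rows, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]))
    if (length(bad))
      stop(sprintf("format error: non-numeric token at row %d, column %d of %s",
                   i, bad[1L], path))
  }
  eeg_recording(do.call(rbind, vals), fs = fs,
                subject_id = subject_id, task_id = task_id)
}

#' Write an EEG matrix as delimited text
#'
#' @param rec an [eeg_recording].
#' @param path output path; one channel per comma-delimited row.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(rec$data, 1L, function(r)
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = ",")), con)
  invisible(path)
}
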