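#' Dataset manifests
#'
#' A manifest is a flat table describing a dataset: one row per recording,
#' with the file path and the subject/task labels. Synthetic and real
#' datasets share this one dialect, stored as a TSV with columns
#' `path`, `subject`, `task`.
#'
#' @param entries data.frame with columns `path` (character), `subject`
#'   (integer), `task` (integer).
#' @return An object of class `eeg_manifest`: the entries data.frame with
#'   attributes `n_subjects` and `n_tasks`.
#' @export
eeg_manifest <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("path", "subject", "task") %in% names(entries)))
  entries$subject <- as.integer(entries$subject)
  entries$task <- as.integer(entries$task)
  if (anyNA(entries$subject) || anyNA(entries$task))
    stop("manifest subject/task labels must be integers")
  key <- paste(entries$subject, entries$task)
  if (anyDuplicated(key))
    stop("manifest contains duplicate (subject, task) pairs")
  subj <- sort(unique(entries$subject))
  if (!identical(subj, seq_along(subj)))
    stop("subject ids must be contiguous from 1 (got ",
         paste(subj, collapse = ","), ")")
  structure(entries[c("path", "subject", "task")],
            n_subjects = length(subj),
            n_tasks = length(unique(entries$task)),
            class = c("eeg_manifest", "data.frame"))
}

#' @rdname eeg_manifest
#' @param path path of a manifest TSV (columns `path`, `subject`, `task`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("path", "subject", "task") %in% names(df)))
    stop("format error: manifest must have columns path, subject, task")
  # relative paths resolve against the manifest's own directory
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  eeg_manifest(df)
}

#' @rdname eeg_manifest
#' @param manifest an `eeg_manifest`.
#' @param file output TSV path; recording paths are stored relative to its
#'   directory when possible.
#' @export
write_manifest <- function(manifest, file) {
  df <- as.data.frame(manifest)
  base <- normalizePath(dirname(file), mustWork = FALSE)
  df$path <- vapply(df$path, function(p) {
    ap <- normalizePath(p, mustWork = FALSE)
    if (startsWith(ap, paste0(base, "/"))) substring(ap, nchar(base) + 2L)
    else ap
  }, "")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Load every recording listed in a manifest
#'
#' @param manifest an [eeg_manifest].
#' @param fs sampling rate passed to [read_matrix()] for CSV entries
#'   (EDF entries carry their own rate).
#' @return A list of [eeg_recording] objects, one per manifest row.
#' @export
load_recordings <- function(manifest, fs) {
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (grepl("\\.edf$", p, ignore.case = TRUE))
      read_edf(p, subject_id = manifest$subject[i], task_id = manifest$task[i])
    else
      read_matrix(p, fs = fs, subject_id = manifest$subject[i],
                  task_id = manifest$task[i])
  })
}
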