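#' Segmentation specifications and segment batches
#'
#' Two segmentation modes feed the two models:
#' \describe{
#'   \item{horizontal}{time-wise: a K x L recording is cut into
#'     `r = floor(L / l_tilde)` consecutive non-overlapping blocks of
#'     `l_tilde` samples (trailing remainder dropped), optionally keeping
#'     only `k_tilde` evenly spaced channels. Used for subject
#'     identification, where many short segments per recording multiply the
#'     training data.}
#'   \item{vertical}{channel-wise: the recording is cut into K single-channel
#'     full-length sequences. Used for task classification, where cutting
#'     time would destroy the task structure the classifier needs.}
#' }
#'
#' @param mode `"horizontal"` or `"vertical"`.
#' @param l_tilde segment length in samples (horizontal only; >= 1).
#' @param k_tilde number of channels retained (`NULL` = all).
#' @return A `segmentation_spec` object.
#' @export
segmentation_spec <- function(mode = c("horizontal", "vertical"),
                              l_tilde = 150L, k_tilde = NULL) {
  mode <- match.arg(mode)
  if (mode == "horizontal" && (!is.numeric(l_tilde) || l_tilde < 1L))
    stop("`l_tilde` must be >= 1")
  structure(list(mode = mode, l_tilde = as.integer(l_tilde),
                 k_tilde = if (!is.null(k_tilde)) as.integer(k_tilde)),
            class = "segmentation_spec")
}

new_segment_batch <- function(segments, labels, provenance) {
  stopifnot(length(segments) == nrow(labels))
  structure(list(segments = segments, labels = labels,
                 provenance = provenance),
            class = "segment_batch")
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$segments[[1L]])
  cat(sprintf("<segment_batch> %d segments of %d x %d (%d subjects, %d tasks)\n",
              length(x$segments), d[1L], d[2L],
              length(unique(x$labels$subject)),
              length(unique(x$labels$task))))
  invisible(x)
}

#' Subset a segment batch
#'
#' @param batch a `segment_batch`.
#' @param keep logical or integer index over segments.
#' @return The `segment_batch` restricted to `keep`.
#' @export
subset_batch <- function(batch, keep) {
  new_segment_batch(batch$segments[keep],
                    batch$labels[keep, , drop = FALSE],
                    batch$provenance[keep, , drop = FALSE])
}

#' Combine segment batches
#'
#' @param ... `segment_batch` objects with identically shaped segments.
#' @return A single `segment_batch`.
#' @export
bind_batches <- function(...) {
  bs <- list(...)
  if (length(bs) == 1L && is.list(bs[[1L]]) &&
      !inherits(bs[[1L]], "segment_batch")) bs <- bs[[1L]]
  new_segment_batch(
    do.call(c, lapply(bs, `[[`, "segments")),
    do.call(rbind, lapply(bs, `[[`, "labels")),
    do.call(rbind, lapply(bs, `[[`, "provenance")))
}

#' Retain evenly spaced channels
#'
#' Keeps `k_tilde` channels at evenly spaced indices over 1..K, with the
#' first and last channels always included when `k_tilde >= 2`. Interior
#' positions are placed on a linear grid and rounded half-up, so K=10 with
#' `k_tilde`=3 keeps channels 1, 6, 10. `k_tilde = 1` keeps channel 1.
#'
#' @param rec an [eeg_recording].
#' @param k_tilde number of channels to retain, 1..K.
#' @return An [eeg_recording] with `k_tilde` channels.
#' @export
select_channels <- function(rec, k_tilde) {
  K <- n_channels(rec)
  if (k_tilde < 1L || k_tilde > K)
    stop(sprintf("channel error: k_tilde=%d outside 1..%d", k_tilde, K))
  idx <- if (k_tilde == 1L) 1L
         else floor(1 + (seq_len(k_tilde) - 1L) * (K - 1) / (k_tilde - 1L) + 0.5)
  eeg_recording(rec$data[idx, , drop = FALSE], fs = rec$fs,
                subject_id = rec$subject_id, task_id = rec$task_id,
                channel_names = rec$channel_names[idx])
}

#' Time-wise (horizontal) segmentation
#'
#' @param rec an [eeg_recording].
#' @param spec a horizontal [segmentation_spec()].
#' @param class_id optional class label copied to every segment.
#' @return A `segment_batch` of `floor(L / l_tilde)` segments of shape
#'   `k_tilde x l_tilde`; trailing remainder samples are dropped, and every
#'   segment inherits the recording's subject/task labels. Offsets recorded
#'   in `provenance` are 0-based sample offsets, multiples of `l_tilde`.
#' @export
horizontal_split <- function(rec, spec, class_id = NA_integer_) {
  stopifnot(inherits(spec, "segmentation_spec"))
  if (spec$mode != "horizontal") stop("spec mode must be 'horizontal'")
  if (!is.null(spec$k_tilde)) rec <- select_channels(rec, spec$k_tilde)
  L <- n_samples(rec); l <- spec$l_tilde
  if (l > L)
    stop(sprintf("empty-batch error: l_tilde=%d exceeds recording length %d",
                 l, L))
  r <- L %/% l
  segs <- lapply(seq_len(r), function(i)
    rec$data[, ((i - 1L) * l + 1L):(i * l), drop = FALSE])
  new_segment_batch(
    segs,
    data.frame(subject = rep(rec$subject_id, r), task = rep(rec$task_id, r),
               class = rep(as.integer(class_id), r)),
    data.frame(recording = rep(NA_integer_, r), offset = (seq_len(r) - 1L) * l))
}

#' Channel-wise (vertical) segmentation
#'
#' @param rec an [eeg_recording].
#' @param class_id optional class label copied to every segment.
#' @return A `segment_batch` of K segments of shape `1 x L`, one per
#'   channel, each labelled with the recording's subject/task (and class).
#' @export
vertical_split <- function(rec, class_id = NA_integer_) {
  K <- n_channels(rec)
  segs <- lapply(seq_len(K), function(k) rec$data[k, , drop = FALSE])
  new_segment_batch(
    segs,
    data.frame(subject = rep(rec$subject_id, K), task = rep(rec$task_id, K),
               class = rep(as.integer(class_id), K)),
    data.frame(recording = rep(NA_integer_, K), offset = rep(0L, K)))
}

#' Segment every recording of a dataset
#'
#' Convenience driver: loads each manifest entry, labels it with its class
#' under `scheme` (or round-robin over `classes`), applies the requested
#' split and binds the batches.
#'
#' @param manifest an [eeg_manifest].
#' @param spec a [segmentation_spec()].
#' @param fs sampling rate for CSV entries.
#' @param scheme optional [class_scheme()] mapping tasks to classes.
#' @param classes optional integer: round-robin class count (the synthetic
#'   generator's labelling) when no scheme applies.
#' @return A `segment_batch` over the whole dataset, with `provenance$recording`
#'   set to the manifest row index.
#' @export
segment_dataset <- function(manifest, spec, fs, scheme = NULL, classes = NULL) {
  recs <- load_recordings(manifest, fs = fs)
  batches <- lapply(seq_along(recs), function(i) {
    cls <- if (!is.null(scheme)) map_task_to_class(recs[[i]]$task_id, scheme)
           else if (!is.null(classes)) round_robin_class(recs[[i]]$task_id, classes)
           else NA_integer_
    b <- if (spec$mode == "horizontal") horizontal_split(recs[[i]], spec, cls)
         else vertical_split(recs[[i]], cls)
    b$provenance$recording <- i
    b
  })
  bind_batches(batches)
}
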