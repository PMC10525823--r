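#' Synthetic multichannel EEG
#'
#' The generator emulates the two properties the linking models rely on:
#' \itemize{
#'   \item \strong{subject-specific spectral signatures}, stable across
#'     tasks: each subject gets (i) a personal oscillation peak in the alpha
#'     band (8--13 Hz), stratified so peaks of different subjects stay
#'     separated, and (ii) a personal stationary AR(p) "background" colour
#'     shared (with small perturbations) by all channels;
#'   \item \strong{task-specific band-power modulation}: a task's class
#'     multiplies the alpha oscillation amplitude by a gain on the affected
#'     channels, mimicking event-related (de)synchronization.
#' }
#'
#' Seeds split hierarchically (dataset seed -> subject seed -> task seed),
#' so adding subjects or tasks never perturbs already-generated ones.
#'
#' @name synth
NULL

# deterministic child-seed derivation, kept inside 32-bit integer range
child_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx) %% 2147483647)
}

# reflection (partial autocorrelation) coefficients -> AR coefficients via
# the Levinson-Durbin step; |k_i| < 1 guarantees a stationary AR polynomial
pacf_to_ar <- function(k) {
  a <- numeric(0)
  for (i in seq_along(k)) {
    a_new <- c(a - k[i] * rev(a), k[i])
    a <- a_new
  }
  a
}

#' @rdname synth
#' @param n_subjects number of subjects (>= 1).
#' @param K number of channels.
#' @param p order of the AR background process (default 6).
#' @param seed integer seed; profiles are deterministic given it.
#' @return `make_profiles`: a list of `n_subjects` subject profiles, each a
#'   list with `peak_hz`, `peak_amp`, `chan_amp` (the subject's alpha
#'   topography: per-channel amplitude weights), `noise_sd`,
#'   `innovation_sd` and `ar` (a K x p matrix of per-channel AR
#'   coefficients, all stationary).
#' @export
make_profiles <- function(n_subjects, K, p = 6L, seed = 1L) {
  stopifnot(n_subjects >= 1L, K >= 1L, p >= 1L)
  width <- 5 / n_subjects            # alpha band 8-13 Hz, stratified
  lapply(seq_len(n_subjects), function(i) {
    set.seed(child_seed(seed, i))
    peak <- 8 + (i - 0.5) * width + stats::runif(1, -0.1, 0.1) * width
    base_k <- stats::runif(p, -0.6, 0.6)
    # per-channel AR signatures: each channel's background colour is a
    # subject-stable variation around the subject's base spectrum
    ar <- t(vapply(seq_len(K), function(ch) {
      kk <- base_k + stats::rnorm(p, sd = 0.15)
      pacf_to_ar(pmin(pmax(kk, -0.9), 0.9))
    }, numeric(p)))
    list(subject_id = i,
         peak_hz = peak,
         peak_amp = stats::runif(1, 1.6, 2.4),
         # individual alpha topography: a stable per-channel amplitude
         # pattern, the spatial signature real subjects carry across
         # sessions and tasks
         chan_amp = stats::runif(K, 0.7, 1.3),
         noise_sd = 0.5,
         innovation_sd = 1.0,
         ar = ar)
  })
}

#' @rdname synth
#' @param class_id class label the effect represents.
#' @param gain multiplicative gain (> 0) on the oscillation amplitude.
#' @param channels integer indices of affected channels (`NULL` = all).
#' @return `task_effect`: a list describing the effect.
#' @export
task_effect <- function(class_id, gain = 1, channels = NULL) {
  stopifnot(gain > 0, is.null(channels) || length(channels) >= 1L)
  structure(list(class_id = as.integer(class_id), gain = gain,
                 channels = channels), class = "task_effect")
}

#' @rdname synth
#' @param profile a subject profile from [make_profiles()].
#' @param effect a [task_effect()].
#' @param L recording length in samples.
#' @param fs sampling rate in Hz.
#' @param task_id task label attached to the recording.
#' @return `simulate_recording`: an [eeg_recording] of shape K x L. Each
#'   channel is an AR(p) background process plus the subject's alpha
#'   rhythm — a narrowband stochastic oscillation (an AR(2) resonance at
#'   the subject's peak frequency with slowly drifting phase, as real
#'   alpha behaves), gain-scaled on affected channels — plus white
#'   measurement noise. 10 p burn-in samples are discarded.
#' @export
simulate_recording <- function(profile, effect = task_effect(1L), L, fs,
                               seed = 1L, task_id = NA_integer_) {
  stopifnot(L >= 1L, fs > 0)
  set.seed(seed)
  K <- nrow(profile$ar); p <- ncol(profile$ar)
  burn <- max(10L * p, 200L)
  affected <- if (is.null(effect$channels)) seq_len(K) else effect$channels
  # AR(2) resonance: poles at rho * exp(+-2i pi f / fs); rho sets bandwidth
  rho <- 0.97
  a_osc <- c(2 * rho * cos(2 * pi * profile$peak_hz / fs), -rho^2)
  data <- matrix(0, K, L)
  for (ch in seq_len(K)) {
    innov <- stats::rnorm(L + burn, sd = profile$innovation_sd)
    x <- stats::filter(innov, profile$ar[ch, ], method = "recursive")
    x <- as.numeric(x)[(burn + 1L):(burn + L)]
    osc <- stats::filter(stats::rnorm(L + burn), a_osc, method = "recursive")
    osc <- as.numeric(osc)[(burn + 1L):(burn + L)]
    osc <- osc / stats::sd(osc) / sqrt(2)   # RMS = amp / sqrt(2)
    amp <- profile$peak_amp * profile$chan_amp[ch] *
      if (ch %in% affected) effect$gain else 1
    data[ch, ] <- x + amp * osc + stats::rnorm(L, sd = profile$noise_sd)
  }
  eeg_recording(data, fs = fs, subject_id = profile$subject_id,
                task_id = task_id)
}

#' Generate a synthetic EEG dataset on disk
#'
#' Simulates `n_tasks` recordings for each of `n_subjects` subjects, writes
#' them as CSV matrices (one channel per row) plus a TSV manifest, and
#' returns the manifest. Task classes are assigned round-robin over tasks
#' (task m gets class `((m-1) mod classes) + 1`), and class q scales the
#' alpha oscillation by `gain_ratio^(q-1)`.
#'
#' @param n_subjects,n_tasks dataset dimensions; `n_tasks` must be divisible
#'   by `classes` (balanced design).
#' @param classes number of task classes.
#' @param K channels per recording.
#' @param L samples per recording (default 4800: a 30 s recording at
#'   160 Hz, half the one-minute sessions of the motor-imagery protocol).
#' @param fs sampling rate in Hz.
#' @param seed dataset seed; everything downstream derives from it.
#' @param outdir output directory (created if missing).
#' @param gain_ratio alpha-gain ratio between consecutive classes.
#' @param p AR background order.
#' @param effect_channels channels carrying the task effect (`NULL` = all).
#' @return An [eeg_manifest] with `n_subjects * n_tasks` rows.
#' @export
generate_dataset <- function(n_subjects = 10L, n_tasks = 4L, classes = 2L,
                             K = 8L, L = 4800L, fs = 160, seed = 1L,
                             outdir, gain_ratio = 1.5, p = 6L,
                             effect_channels = NULL) {
  stopifnot(n_tasks %% classes == 0L)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  profiles <- make_profiles(n_subjects, K = K, p = p, seed = seed)
  rows <- vector("list", n_subjects * n_tasks)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    sseed <- child_seed(seed, s)
    for (m in seq_len(n_tasks)) {
      cls <- ((m - 1L) %% classes) + 1L
      eff <- task_effect(cls, gain = gain_ratio^(cls - 1L),
                         channels = effect_channels)
      rec <- simulate_recording(profiles[[s]], eff, L = L, fs = fs,
                                seed = child_seed(sseed, m), task_id = m)
      fn <- sprintf("subject%02d_task%02d.csv", s, m)
      write_matrix(rec, file.path(outdir, fn))
      i <- i + 1L
      rows[[i]] <- data.frame(path = fn, subject = s, task = m)
    }
  }
  man <- eeg_manifest(do.call(rbind, rows))
  write_manifest(man, file.path(outdir, "manifest.tsv"))
  man$path <- file.path(outdir, man$path)
  man
}

#' Round-robin class of a task
#'
#' The class labelling used by [generate_dataset()]: task m belongs to class
#' `((m-1) mod classes) + 1`.
#'
#' @param task_id integer task id(s).
#' @param classes number of classes.
#' @export
round_robin_class <- function(task_id, classes) {
  ((as.integer(task_id) - 1L) %% as.integer(classes)) + 1L
}
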