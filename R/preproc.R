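#' Classical EEG frequency bands (Hz)
#'
#' Delta 0.5--4, Theta 4--7.5, Alpha 8--13, Beta 14--30, Gamma 30--45.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 7.5), alpha = c(8, 13),
       beta = c(14, 30), gamma = c(30, 45))
}

#' Zero-mean / unit-variance channel normalization
#'
#' Per channel, returns `(x - mu) / sigma` with `mu` the channel mean and
#' `sigma` the channel \emph{population} standard deviation (divisor K = L,
#' not L-1). Reduces intra-subject amplitude variance before the classical
#' feature branch. Idempotent: a standardized channel is returned unchanged.
#'
#' @param rec an [eeg_recording] with >= 2 samples per channel.
#' @return The normalized [eeg_recording].
#' @export
zero_mean_normalize <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- n_samples(rec)
  if (L < 2L) stop("need >= 2 samples per channel to normalize")
  mu <- rowMeans(rec$data)
  sigma <- sqrt(rowMeans(rec$data^2) - mu^2)
  if (any(sigma == 0))
    stop("degenerate-channel error: zero variance on channel(s) ",
         paste(which(sigma == 0), collapse = ", "))
  out <- (rec$data - mu) / sigma
  eeg_recording(out, fs = rec$fs, subject_id = rec$subject_id,
                task_id = rec$task_id, channel_names = rec$channel_names)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), giving zero phase distortion. The default
#' 0.5--45 Hz band covers the classical delta-through-gamma range and
#' removes DC drift and mains-frequency interference.
#'
#' @param rec an [eeg_recording].
#' @param low,high band edges in Hz; `high` must be below the Nyquist
#'   frequency `fs/2`.
#' @param order filter order (of each Butterworth prototype).
#' @return The filtered [eeg_recording].
#' @export
bandpass <- function(rec, low = 0.5, high = 45, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), low > 0, high > low)
  nyq <- rec$fs / 2
  if (high >= nyq)
    stop(sprintf("Nyquist error: high edge %g Hz >= fs/2 = %g Hz", high, nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  if (n_channels(rec) == 1L) out <- matrix(out, nrow = 1L)
  eeg_recording(out, fs = rec$fs, subject_id = rec$subject_id,
                task_id = rec$task_id, channel_names = rec$channel_names)
}

#' Autoregressive coefficients by Yule-Walker
#'
#' Fits the AR(p) model `x(n) = c + sum_i a_i x(n-i) + e(n)` to a single
#' series. Coefficients are estimated by Yule-Walker on the demeaned series
#' (via [stats::ar.yw()]); the intercept is recovered from the sample mean
#' as `c = mean * (1 - sum(a))`. The coefficient vector is the compact
#' spectral signature used as a feature block by the baselines.
#'
#' @param x numeric vector (or 1 x L matrix), length > 10 p.
#' @param p AR order (>= 0).
#' @return An `ar_model` list: `order`, `intercept`, `coef` (length p),
#'   `innovation_var`.
#' @export
ar_coefficients <- function(x, p = 6L) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("numeric error: non-finite values in series")
  p <- as.integer(p)
  if (p < 0L) stop("AR order must be >= 0")
  if (length(x) <= 10L * max(p, 1L))
    stop("series too short: need length > 10*p")
  m <- mean(x)
  if (p == 0L)
    return(structure(list(order = 0L, intercept = m, coef = numeric(0),
                          innovation_var = stats::var(x)),
                     class = "ar_model"))
  fit <- tryCatch(
    stats::ar.yw(x, aic = FALSE, order.max = p, demean = TRUE),
    error = function(e) stop("estimation error: ", conditionMessage(e)))
  a <- as.numeric(fit$ar)
  structure(list(order = p, intercept = m * (1 - sum(a)), coef = a,
                 innovation_var = as.numeric(fit$var.pred)),
            class = "ar_model")
}

#' Welch power spectral density
#'
#' Averages modified periodograms of Hann-windowed, 50%-overlapping
#' segments. Density scaling: the PSD integrates (sum times bin width) to
#' approximately the signal variance. One-sided spectrum on the grid
#' `0, fs/nperseg, ..., fs/2`.
#'
#' @param x numeric vector (or 1 x L matrix) of length >= `nperseg`.
#' @param fs sampling rate in Hz.
#' @param nperseg samples per segment (default 256).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param demean subtract each segment's mean before windowing (default TRUE).
#' @return A `psd_estimate` list: `freq` (Hz), `power` (density, unit^2/Hz),
#'   `resolution` (Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 256L, overlap = 0.5, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x); nperseg <- as.integer(nperseg)
  if (nperseg > n)
    stop(sprintf("window error: nperseg=%d exceeds series length %d",
                 nperseg, n))
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0L, nperseg - 1L) / nperseg)  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    P <- scale * (Re(X)^2 + Im(X)^2)
    # one-sided: double everything except DC (and Nyquist when nperseg even)
    dbl <- rep(2, nfreq); dbl[1L] <- 1
    if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
    acc <- acc + P * dbl
  }
  structure(list(freq = (seq_len(nfreq) - 1L) * fs / nperseg,
                 power = acc / length(starts),
                 resolution = fs / nperseg),
            class = "psd_estimate")
}

#' Integrated band power from a PSD estimate
#'
#' @param psd a `psd_estimate` from [welch_psd()].
#' @param band numeric length-2 vector of band edges in Hz.
#' @return Power integrated (rectangle rule) over bins whose frequency lies
#'   in `[band[1], band[2])`.
#' @export
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1L] & psd$freq < band[2L]
  sum(psd$power[sel]) * psd$resolution
}

#' Classical feature extraction for the baselines
#'
#' For every segment: per channel, `p` Yule-Walker AR coefficients and the
#' five classical band powers (integrated Welch PSD), concatenated channel
#' by channel. With K channels the feature dimension is
#' `K * (p + length(bands))` (44 for K=4, p=6, five bands). Either block
#' can be switched off.
#'
#' @param batch a `segment_batch` (ideally normalized and band-passed).
#' @param fs sampling rate in Hz.
#' @param p AR order per channel (default 6).
#' @param bands named list of band edges; default [eeg_bands()].
#' @param nperseg Welch segment length; capped at the segment length.
#' @param use_ar,use_psd include the AR / band-power blocks.
#' @return A `feature_set`: list with `x` (n_segments x dim matrix) and
#'   `labels` (the batch's label data.frame).
#' @export
extract_features <- function(batch, fs, p = 6L, bands = eeg_bands(),
                             nperseg = 256L, use_ar = TRUE, use_psd = TRUE) {
  stopifnot(inherits(batch, "segment_batch"), use_ar || use_psd)
  nseg <- length(batch$segments)
  feat1 <- function(seg) {
    K <- nrow(seg); L <- ncol(seg)
    nps <- min(nperseg, L)
    unlist(lapply(seq_len(K), function(k) {
      v <- numeric(0)
      if (use_ar) v <- c(v, ar_coefficients(seg[k, ], p = p)$coef)
      if (use_psd) {
        psd <- welch_psd(seg[k, ], fs = fs, nperseg = nps)
        v <- c(v, vapply(bands, function(b) band_power(psd, b), 0))
      }
      v
    }))
  }
  x <- t(vapply(batch$segments, feat1, feat1(batch$segments[[1L]])))
  structure(list(x = x, labels = batch$labels), class = "feature_set")
}
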