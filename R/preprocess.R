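#' Zero-phase IIR band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward (zero phase) along
#' the sample axis. Accepts a numeric vector, a `channels x samples` matrix,
#' a 3-D `(trial, channel, sample)` array, or an [epoched_trials()] object;
#' the output has the same shape/class as the input.
#'
#' @param x input signal(s).
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @param sampling_rate sampling rate in Hz (taken from the object for
#'   `epoched_trials` input).
#' @param order IIR filter order (default 4).
#' @export
bandpass <- function(x, low, high, sampling_rate = NULL, order = 4) {
  if (inherits(x, "epoched_trials")) {
    out <- x
    out$data <- bandpass(x$data, low, high, x$sampling_rate, order)
    return(out)
  }
  if (is.null(sampling_rate)) stop("sampling_rate required")
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)",
                 nyq))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  f1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.null(dim(x))) return(f1(x))
  if (length(dim(x)) == 2) return(t(apply(x, 1, f1)))
  out <- x
  for (m in seq_len(dim(x)[1]))
    for (ch in seq_len(dim(x)[2]))
      out[m, ch, ] <- f1(x[m, ch, ])
  out
}

#' Stimulus-onset latency correction and epoch windowing
#'
#' The visually evoked response lags stimulus onset (about 140 ms in the
#' standard 40-target benchmark protocol); this drops the first
#' `round(delay_s * rate)` samples and keeps the following
#' `round(window_s * rate)` samples, i.e. the 0-based half-open sample window
#' `[round(delay*rate), round(delay*rate) + round(window*rate))`.
#'
#' @param x an [epoched_trials()] object or 3-D array.
#' @param delay_s latency in seconds (>= 0).
#' @param window_s retained window length in seconds.
#' @param sampling_rate required for plain-array input.
#' @export
apply_latency <- function(x, delay_s, window_s, sampling_rate = NULL) {
  if (inherits(x, "epoched_trials")) {
    out <- x
    out$data <- apply_latency(x$data, delay_s, window_s, x$sampling_rate)
    return(out)
  }
  if (is.null(sampling_rate)) stop("sampling_rate required")
  if (delay_s < 0) stop("delay_s must be non-negative")
  start <- round(delay_s * sampling_rate)
  n <- round(window_s * sampling_rate)
  if (n < 1) stop("window too short: zero samples")
  if (start + n > dim(x)[3])
    stop(sprintf("window [%d, %d) extends past epoch end (%d samples)",
                 start, start + n, dim(x)[3]))
  x[, , (start + 1):(start + n), drop = FALSE]
}

#' Epoch a continuous multi-channel recording by event onsets
#'
#' Cuts a `channels x samples` continuous recording into fixed-length
#' epochs starting at the given 1-based onset samples (typically stimulus
#' trigger positions). Latency correction and windowing are applied
#' downstream by [apply_latency()].
#'
#' @param x numeric `channels x samples` matrix.
#' @param onsets integer vector of 1-based onset samples, one per event.
#' @param labels class label per event (1-based).
#' @param epoch_s epoch length in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param blocks optional block index per event.
#' @param channel_names optional channel names.
#' @return an [epoched_trials()] object.
#' @export
epoch_continuous <- function(x, onsets, labels, epoch_s, sampling_rate,
                             blocks = NULL, channel_names = NULL) {
  x <- as.matrix(x)
  n <- round(epoch_s * sampling_rate)
  if (n < 1) stop("epoch too short: zero samples")
  if (length(onsets) != length(labels))
    stop("one label per event onset required")
  bad <- onsets < 1 | onsets + n - 1 > ncol(x)
  if (any(bad))
    stop(sprintf("event(s) %s extend past the recording",
                 paste(which(bad), collapse = ", ")))
  dat <- array(0, c(length(onsets), nrow(x), n))
  for (m in seq_along(onsets))
    dat[m, , ] <- x[, onsets[m]:(onsets[m] + n - 1)]
  epoched_trials(dat, labels, blocks, sampling_rate, channel_names)
}

#' Per-trial, per-channel mean removal
#'
#' Centers every channel of every trial at zero; correlation- and
#' covariance-based recognizers assume centered trials.
#'
#' @param x an [epoched_trials()] object or 3-D array.
#' @export
centralize <- function(x) {
  if (inherits(x, "epoched_trials")) {
    out <- x
    out$data <- centralize(x$data)
    return(out)
  }
  mu <- apply(x, c(1, 2), mean)
  x - array(rep(mu, dim(x)[3]), dim = dim(x))
}
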