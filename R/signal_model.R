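#' Define a set of SSVEP stimulation frequencies
#'
#' An SSVEP experiment presents `Ns` stimuli flickering at distinct
#' frequencies; the brain response at each stimulus contains the fundamental
#' and its harmonics. This object carries everything needed to build the
#' sinusoidal reference templates: the frequencies, the number of harmonics
#' `Nh`, the sampling rate, and the epoch length in samples `Nt`.
#'
#' @param frequencies numeric vector of stimulation frequencies in Hz
#'   (strictly positive, distinct). Class indices used throughout the package
#'   refer to positions in this vector.
#' @param n_harmonics number of harmonics `Nh` per stimulus. Conventional
#'   defaults are 5 for high-density occipital montages and 3 for low-rate
#'   consumer devices; there is no universal value, so it must be given.
#' @param sampling_rate sampling rate in Hz.
#' @param n_samples epoch length `Nt` in samples.
#' @return an object of class `stimulus_set`.
#' @export
stimulus_set <- function(frequencies, n_harmonics, sampling_rate, n_samples) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0)
    stop("stimulus set needs at least one frequency")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("all stimulation frequencies must be strictly positive")
  if (anyDuplicated(frequencies))
    stop("stimulation frequencies must be distinct")
  if (!is_count(n_harmonics)) stop("n_harmonics must be a positive integer")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (!is_count(n_samples)) stop("n_samples must be a positive integer")
  top <- n_harmonics * max(frequencies)
  if (top >= sampling_rate / 2)
    stop(sprintf(
      "harmonic %d of %.4g Hz (= %.4g Hz) is at or above Nyquist (%.4g Hz)",
      n_harmonics, max(frequencies), top, sampling_rate / 2))
  structure(
    list(frequencies = frequencies,
         n_harmonics = as.integer(n_harmonics),
         sampling_rate = as.numeric(sampling_rate),
         n_samples = as.integer(n_samples)),
    class = "stimulus_set")
}

#' Number of stimulus classes in a stimulus set
#' @param x a `stimulus_set`
#' @export
n_classes <- function(x) length(x$frequencies)

#' Container for epoched multi-channel EEG trials
#'
#' The universal data currency of the package: a `(trial, channel, sample)`
#' tensor with per-trial class labels (1-based indices into the stimulus
#' set), optional block indices for block-designed recordings, the sampling
#' rate, and channel names.
#'
#' @param data numeric array `n_trials x n_channels x n_samples`.
#' @param labels integer class label per trial (1-based).
#' @param blocks optional integer block index per trial.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names optional character vector of channel names.
#' @return an object of class `epoched_trials`.
#' @export
epoched_trials <- function(data, labels, blocks = NULL, sampling_rate,
                           channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 3-D array (trial x channel x sample)")
  n_trials <- dim(data)[1]
  labels <- as.integer(labels)
  if (length(labels) != n_trials)
    stop("labels must have one entry per trial")
  if (any(labels < 1)) stop("labels are 1-based class indices")
  if (!is.null(blocks)) {
    blocks <- as.integer(blocks)
    if (length(blocks) != n_trials)
      stop("blocks must have one entry per trial")
    if (anyDuplicated(paste(labels, blocks)))
      warning("duplicate (label, block) pairs: data is not block-designed")
  }
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must match the channel dimension")
  structure(
    list(data = data, labels = labels, blocks = blocks,
         sampling_rate = as.numeric(sampling_rate),
         channel_names = as.character(channel_names)),
    class = "epoched_trials")
}

#' @export
print.epoched_trials <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoched_trials: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  classes: %d, blocks: %s\n", length(unique(x$labels)),
              if (is.null(x$blocks)) "none" else length(unique(x$blocks))))
  invisible(x)
}

#' Number of trials in an epoched container
#' @param trials an [epoched_trials()]
#' @export
n_trials <- function(trials) dim(trials$data)[1]

#' Extract one trial as a channels-by-samples matrix
#' @param trials an [epoched_trials()]
#' @param m trial index
#' @export
trial_matrix <- function(trials, m) {
  X <- trials$data[m, , , drop = FALSE]
  dim(X) <- dim(trials$data)[2:3]
  X
}

#' Subset trials, channels or the sample window
#'
#' `subset_trials` keeps the trials selected by `idx` (logical or integer);
#' `select_channels` restricts to named or indexed channels;
#' `crop_samples` keeps the first `n_keep` samples of every trial.
#'
#' @param trials an [epoched_trials()]
#' @param idx trial selection (logical or integer)
#' @export
subset_trials <- function(trials, idx) {
  epoched_trials(trials$data[idx, , , drop = FALSE], trials$labels[idx],
                 if (is.null(trials$blocks)) NULL else trials$blocks[idx],
                 trials$sampling_rate, trials$channel_names)
}

#' @rdname subset_trials
#' @param channels channel names or indices
#' @export
select_channels <- function(trials, channels) {
  if (is.character(channels)) {
    miss <- setdiff(channels, trials$channel_names)
    if (length(miss))
      stop("unknown channel name(s): ", paste(miss, collapse = ", "))
    channels <- match(channels, trials$channel_names)
  }
  epoched_trials(trials$data[, channels, , drop = FALSE], trials$labels,
                 trials$blocks, trials$sampling_rate,
                 trials$channel_names[channels])
}

#' @rdname subset_trials
#' @param n_keep number of leading samples to keep
#' @export
crop_samples <- function(trials, n_keep) {
  if (n_keep > dim(trials$data)[3])
    stop("window longer than the available epoch")
  epoched_trials(trials$data[, , seq_len(n_keep), drop = FALSE],
                 trials$labels, trials$blocks, trials$sampling_rate,
                 trials$channel_names)
}

#' Sinusoidal reference template for one stimulus
#'
#' Builds the `Nt x 2Nh` matrix `Y(f)` whose columns are
#' `sin(2*pi*h*f*t), cos(2*pi*h*f*t)` for harmonics `h = 1..Nh`, with
#' `t = n / sampling_rate`, `n = 0, ..., Nt-1` (zero phase; time origin at
#' the first retained sample of the epoch).
#'
#' @param freq stimulation frequency in Hz.
#' @param stim a [stimulus_set()] supplying `Nh`, the sampling rate and `Nt`.
#' @return numeric matrix `Nt x 2Nh`, columns named `sinh/cosh`.
#' @export
build_reference <- function(freq, stim) {
  stopifnot(inherits(stim, "stimulus_set"))
  if (!is.numeric(freq) || length(freq) != 1 || freq <= 0)
    stop("freq must be a single positive frequency")
  nh <- stim$n_harmonics
  for (h in seq_len(nh))
    if (h * freq >= stim$sampling_rate / 2)
      stop(sprintf("harmonic %d of %.4g Hz is at or above Nyquist", h, freq))
  t <- (seq_len(stim$n_samples) - 1) / stim$sampling_rate
  Y <- matrix(0, stim$n_samples, 2L * nh)
  for (h in seq_len(nh)) {
    Y[, 2L * h - 1L] <- sin(2 * pi * h * freq * t)
    Y[, 2L * h]      <- cos(2 * pi * h * freq * t)
  }
  Y
}

#' Harmonic dictionary over all stimuli
#'
#' Concatenates the per-stimulus reference templates into the global
#' dictionary `Phi = [Y(f1) Y(f2) ... Y(fNs)]` of size `Nt x 2*Ns*Nh`. Every
#' single-channel SSVEP time course is modeled as a sparse linear
#' combination of these columns.
#'
#' @param stim a [stimulus_set()].
#' @return object of class `harmonic_dictionary` with elements
#'   `per_stimulus` (list of `Y(f_s)` matrices), `full` (the concatenation),
#'   and `stimulus_set`.
#' @export
build_dictionary <- function(stim) {
  stopifnot(inherits(stim, "stimulus_set"))
  per <- lapply(stim$frequencies, build_reference, stim = stim)
  structure(list(per_stimulus = per, full = do.call(cbind, per),
                 stimulus_set = stim),
            class = "harmonic_dictionary")
}

#' @export
print.harmonic_dictionary <- function(x, ...) {
  cat(sprintf("harmonic_dictionary: %d stimuli, Nh=%d, %d x %d\n",
              n_classes(x$stimulus_set), x$stimulus_set$n_harmonics,
              nrow(x$full), ncol(x$full)))
  invisible(x)
}
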