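# Preprocessing: container types, zero-phase Kaiser-window FIR filtering,
# downsampling, average referencing and fixed-length epoching.

#' Construct an EEG recording
#'
#' @param data Numeric channels x samples matrix (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param montage Ordered character vector of channel labels.
#' @param reference Reference tag, `"average"` or `"other"`.
#' @return An `eeg_recording` object.
#' @export
recording <- function(data, fs, montage, reference = "other") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (length(montage) != nrow(data))
    stop("montage length must equal the number of channels")
  if (!is.finite(fs) || fs <= 0) stop("fs must be positive")
  rownames(data) <- montage
  structure(list(data = data, fs = fs, montage = montage,
                 reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d ch x %d samples @ %g Hz (%s reference)\n",
              nrow(x$data), ncol(x$data), x$fs, x$reference))
  invisible(x)
}

# Kaiser window design from a maximum passband ripple: attenuation
# A = -20 log10(ripple), beta from the standard Kaiser formula, order from
# N = (A - 8) / (2.285 * dw) with dw the transition width in rad/sample.
.kaiser_design <- function(ripple, transition_hz, fs) {
  a <- -20 * log10(ripple)
  beta <- if (a > 50) {
    0.1102 * (a - 8.7)
  } else if (a >= 21) {
    0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
  } else 0
  dw <- 2 * pi * transition_hz / fs
  n <- ceiling((a - 8) / (2.285 * dw))
  n <- n + n %% 2L  # even order -> integer group delay
  list(order = n, beta = beta)
}

#' Zero-phase FIR filter (Kaiser window)
#'
#' Windowed-sinc FIR filter with a Kaiser window whose beta is derived from
#' the maximum passband ripple; the filter order follows from the Kaiser
#' design formula with a transition width of 25% of the lowest edge (unless
#' overridden).  The filter is applied forward and the group delay is
#' compensated, so microstate timing is not shifted.
#'
#' @param rec An `eeg_recording`.
#' @param kind `"lowpass"`, `"bandpass"` or `"bandstop"`.
#' @param edges Cutoff frequency (lowpass) or c(low, high) in Hz.
#' @param max_ripple Maximum passband ripple (fraction), default 0.001.
#' @param transition_hz Optional transition-band width override in Hz.
#' @return The filtered `eeg_recording`; the realized filter order is
#'   stored in attribute `"filter_order"`.
#' @export
fir_filter <- function(rec, kind = c("lowpass", "bandpass", "bandstop"),
                       edges, max_ripple = 0.001, transition_hz = NULL) {
  kind <- match.arg(kind)
  nyq <- rec$fs / 2
  if (any(edges <= 0) || any(edges >= nyq))
    stop("filter edges must lie strictly between 0 and the Nyquist frequency")
  if (kind != "lowpass" && length(edges) != 2L)
    stop(kind, " requires two edge frequencies")
  if (length(edges) == 2L && edges[1] >= edges[2])
    stop("edges must be increasing")
  if (is.null(transition_hz)) transition_hz <- 0.25 * min(edges)
  des <- .kaiser_design(max_ripple, transition_hz, rec$fs)
  n <- des$order
  if (ncol(rec$data) <= n)
    stop(sprintf("signal (%d samples) is shorter than the filter order (%d)",
                 ncol(rec$data), n))
  type <- switch(kind, lowpass = "low", bandpass = "pass", bandstop = "stop")
  b <- signal::fir1(n, edges / nyq, type = type,
                    window = signal::kaiser(n + 1L, des$beta))
  half <- n %/% 2L
  out <- t(apply(rec$data, 1L, function(x) {
    y <- signal::fftfilt(b, c(x, numeric(half)))
    y[(half + 1L):(half + length(x))]
  }))
  res <- recording(out, rec$fs, rec$montage, rec$reference)
  attr(res, "filter_order") <- n
  res
}

#' Downsample a recording
#'
#' Integer decimation uses an internal anti-alias lowpass (Kaiser FIR,
#' cutoff at 0.45 of the target rate) followed by sample picking;
#' non-integer ratios use polyphase resampling.  Duration is preserved to
#' within one sample.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target sampling rate in Hz (must not exceed `rec$fs`).
#' @return The resampled `eeg_recording`.
#' @export
downsample <- function(rec, target_fs) {
  if (target_fs > rec$fs) stop("target_fs must not exceed the sampling rate")
  if (target_fs == rec$fs) return(rec)
  if (rec$fs %% target_fs == 0) {
    q <- rec$fs / target_fs
    aa <- fir_filter(rec, "lowpass", edges = 0.45 * target_fs,
                     transition_hz = 0.1 * target_fs)
    idx <- seq(1L, ncol(rec$data), by = q)
    out <- aa$data[, idx, drop = FALSE]
  } else {
    ratio <- target_fs / rec$fs
    fr <- .rational_approx(ratio)
    out <- t(apply(rec$data, 1L, function(x)
      signal::resample(x, p = fr[1], q = fr[2])))
  }
  recording(out, target_fs, rec$montage, rec$reference)
}

.rational_approx <- function(x, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err) { err <- e; best <- c(as.integer(p), q) }
    if (e == 0) break
  }
  best
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels from every sample, so each
#' column (time point) of the data sums to zero.  Idempotent.
#'
#' @param rec An `eeg_recording` with at least two channels.
#' @return The average-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2L) stop("average reference requires >= 2 channels")
  data <- sweep(rec$data, 2L, colMeans(rec$data))
  recording(data, rec$fs, rec$montage, reference = "average")
}

#' Cut a recording into fixed-length epochs
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_length_s` seconds (half-open sample windows); a trailing partial
#' epoch is discarded.  Epochs are treated as temporally discontinuous by
#' all downstream stages.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 1).
#' @return An `eeg_epochs` object: list of channels x samples_per_epoch
#'   matrices plus `fs`, `montage`, `epoch_length_s`, `reference`.
#' @export
epoch_recording <- function(rec, epoch_length_s = 1) {
  spe <- as.integer(round(rec$fs * epoch_length_s))
  if (spe < 1L) stop("epoch length must cover at least one sample")
  n_ep <- ncol(rec$data) %/% spe
  if (n_ep < 1L) stop("recording is shorter than one epoch")
  epochs <- lapply(seq_len(n_ep), function(k) {
    rec$data[, ((k - 1L) * spe + 1L):(k * spe), drop = FALSE]
  })
  structure(list(epochs = epochs, fs = rec$fs, montage = rec$montage,
                 epoch_length_s = epoch_length_s, reference = rec$reference),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("Epoched EEG: %d epochs of %g s (%d ch @ %g Hz)\n",
              length(x$epochs), x$epoch_length_s, length(x$montage), x$fs))
  invisible(x)
}

#' Concatenate epochs back into a continuous recording
#'
#' @param ep An `eeg_epochs` object.
#' @return An `eeg_recording` equal to the epoch-truncated original.
#' @export
concatenate_epochs <- function(ep) {
  recording(do.call(cbind, ep$epochs), ep$fs, ep$montage, ep$reference)
}

#' Canonical frequency band definitions
#'
#' The analysis bands: broadband (lowpass 40 Hz), delta (lowpass below
#' 4 Hz), theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz).  Delta is
#' realized as a pure lowpass: the procedure low-pass filters below 4 Hz
#' rather than band-passing 1-4 Hz.
#'
#' @return Named list of band specs (`name`, `low_hz`, `high_hz`).
#' @export
band_specs <- function() {
  list(
    broadband = list(name = "broadband", low_hz = NA_real_, high_hz = 40),
    delta = list(name = "delta", low_hz = NA_real_, high_hz = 4),
    theta = list(name = "theta", low_hz = 4, high_hz = 8),
    alpha = list(name = "alpha", low_hz = 8, high_hz = 13),
    beta = list(name = "beta", low_hz = 13, high_hz = 30))
}

#' Filter a recording into one analysis band
#'
#' @param rec An `eeg_recording`.
#' @param band A band name from [band_specs()] or a band spec list.
#' @return The band-filtered `eeg_recording`.
#' @export
filter_band <- function(rec, band) {
  if (is.character(band)) {
    specs <- band_specs()
    if (!band %in% names(specs)) stop("unknown band: ", band)
    band <- specs[[band]]
  }
  if (is.na(band$low_hz)) {
    fir_filter(rec, "lowpass", edges = band$high_hz)
  } else {
    fir_filter(rec, "bandpass", edges = c(band$low_hz, band$high_hz))
  }
}
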