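# EEG feature extraction: principal scalp series, Morlet time-frequency
# power, global field power, steady-state evoked response spectra

#' Project an EEG recording onto its first spatial principal component
#'
#' Electrode rows are mean-centred over time and decomposed by SVD
#' (computed through the eigendecomposition of the electrode covariance);
#' the representative scalp series is the projection onto the leading left
#' singular vector.  Out of all linear projections this captures the most
#' variance, and for visually driven data the loading concentrates on
#' posterior electrodes.  The eigenvector sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @return An object of class \code{scalp_series}: list with \code{series},
#'   unit-norm \code{eigenvector} (named by channel), scalar
#'   \code{variance_explained} and \code{sampling_rate}; protocol
#'   annotations are carried over.
#' @examples
#' Y <- outer(c(1, 2, 3), sin(2 * pi * 5 * seq(0, 1, by = 0.01)))
#' s <- principal_projection(eeg_recording(Y, 100))
#' s$variance_explained   # 1: rank-one data
#' @export
principal_projection <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  Yc <- rec$data - rowMeans(rec$data)
  if (all(Yc == 0))
    stop_invalid("degenerate input: EEG data has rank 0 after centering")
  ev <- eigen(tcrossprod(Yc), symmetric = TRUE)
  u1 <- ev$vectors[, 1L]
  if (u1[which.max(abs(u1))] < 0) u1 <- -u1
  vals <- pmax(ev$values, 0)
  names(u1) <- rec$channel_labels
  structure(list(
    series = drop(crossprod(u1, Yc)),
    eigenvector = u1,
    variance_explained = vals[1L] / sum(vals),
    sampling_rate = rec$sampling_rate,
    annotations = rec$annotations
  ), class = "scalp_series")
}

#' @export
print.scalp_series <- function(x, ...) {
  cat(sprintf("Scalp series: %d samples at %g Hz, first component explains %.1f%% variance\n",
              length(x$series), x$sampling_rate, 100 * x$variance_explained))
  invisible(x)
}

#' Morlet wavelet time-frequency power
#'
#' Convolves a signal with complex Morlet wavelets
#' \eqn{G(f,t) = A \exp(-t^2/2\sigma_t^2) \exp(2 i \pi f t)} with
#' \eqn{A = (\sigma_t \sqrt{\pi})^{-1/2}}, \eqn{\sigma_t = 1/(2\pi\sigma_f)}
#' and \eqn{\sigma_f = f / R}, and returns the squared modulus of the
#' convolution at every frequency and time point.  The normalisation gives
#' each wavelet unit energy, so the power of a pure sinusoid of fixed
#' amplitude scales as \eqn{1/f} across analysis frequencies (it is the
#' frequency profile at a fixed time point, after per-time normalisation,
#' that the downstream transfer functions consume).
#'
#' Convolution uses zero padding; samples within \eqn{3\sigma_t(f)} of the
#' record boundaries are edge-affected and their per-frequency half-width is
#' returned in \code{edge_half_width} so summaries can exclude them.
#'
#' @param x numeric signal, or a \code{scalp_series}.
#' @param sampling_rate sampling rate in Hz (taken from the object when
#'   \code{x} is a \code{scalp_series}).
#' @param freqs analysis frequency grid in Hz, default 1-40 Hz in 1 Hz steps;
#'   must lie strictly inside (0, Nyquist).
#' @param R the wavelet factor (number of cycles parameter), default 7.
#' @return Object of class \code{tf_power}: list with \code{power}
#'   (frequencies x time), \code{freqs}, \code{times}, \code{R},
#'   \code{sampling_rate} and integer \code{edge_half_width} per frequency
#'   (in samples).
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 250))
#' P <- morlet_power(x, 250, freqs = 5:15)
#' P$freqs[which.max(rowMeans(P$power))]   # 10
#' @export
morlet_power <- function(x, sampling_rate = NULL, freqs = 1:40, R = 7) {
  if (inherits(x, "scalp_series")) {
    sampling_rate <- x$sampling_rate
    x <- x$series
  }
  check_positive_scalar(sampling_rate, "sampling_rate")
  check_positive_scalar(R, "R")
  if (is.unsorted(freqs, strictly = TRUE))
    stop_invalid("invalid parameter: `freqs` must be strictly increasing")
  if (any(freqs <= 0) || any(freqs >= sampling_rate / 2))
    stop_invalid("invalid parameter: `freqs` must lie in (0, Nyquist = %g)",
                 sampling_rate / 2)
  n <- length(x)
  dt <- 1 / sampling_rate
  sigma_t <- R / (2 * pi * freqs)
  half <- pmin(ceiling(4 * sigma_t * sampling_rate), n)
  nfft <- nextn(n + 2L * max(half) + 1L)
  fx <- fft(c(x, numeric(nfft - n)))
  P <- matrix(0, length(freqs), n)
  for (j in seq_along(freqs)) {
    h <- half[j]
    tk <- (-h:h) * dt
    A <- (sigma_t[j] * sqrt(pi))^(-1 / 2)
    g <- A * exp(-tk^2 / (2 * sigma_t[j]^2)) * exp(2i * pi * freqs[j] * tk)
    fg <- fft(c(g, numeric(nfft - length(g))))
    conv <- fft(fx * fg, inverse = TRUE) / nfft
    P[j, ] <- Mod(conv[(h + 1L):(h + n)] * dt)^2
  }
  structure(list(
    power = P, freqs = freqs,
    times = (seq_len(n) - 1) * dt,
    R = R, sampling_rate = sampling_rate,
    edge_half_width = as.integer(pmin(ceiling(3 * sigma_t * sampling_rate), n))
  ), class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  cat(sprintf("Time-frequency power: %d frequencies (%g-%g Hz) x %d samples, wavelet factor R = %g\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$power), x$R))
  invisible(x)
}

# time-average of power per frequency over the interior (edge-excluded)
# region; falls back to the full record when a frequency's edges overlap
interior_mean_power <- function(P) {
  n <- ncol(P$power)
  vapply(seq_along(P$freqs), function(j) {
    h <- P$edge_half_width[j]
    idx <- if (2L * h >= n) seq_len(n) else (h + 1L):(n - h)
    mean(P$power[j, idx])
  }, numeric(1))
}

#' Global field power of a multichannel EEG recording
#'
#' Per-sample root-mean-square deviation of the electrode potentials from
#' their instantaneous cross-electrode mean.  Because the mean is removed at
#' every time point the measure is reference-free: adding any common offset
#' per sample leaves it unchanged.
#'
#' @param rec an \code{\link{eeg_recording}} with at least 2 electrodes.
#' @return Numeric vector, one value per sample (micro-volts).
#' @examples
#' Y <- rbind(c(1, 2), c(-1, 2))
#' global_field_power(eeg_recording(Y, 100))   # 1, 0
#' @export
global_field_power <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  Y <- rec$data
  if (nrow(Y) < 2L)
    stop_invalid("degenerate input: global field power needs >= 2 electrodes")
  dev <- sweep(Y, 2L, colMeans(Y))
  sqrt(colMeans(dev^2))
}

#' Steady-state visual evoked response spectra
#'
#' Epochs one channel of the recording in short windows time-locked to the
#' checkerboard reversals of each task block (reversals occur at twice the
#' flicker frequency, so all windows of one condition are phase-aligned),
#' averages the epochs per flicker frequency, and computes the Morlet power
#' spectrum of each averaged epoch.  For reversal stimuli the response is
#' entrained at the second harmonic of the flicker frequency, so the
#' spectral peak sits at 2f whenever 2f is inside the analysis range.
#'
#' @param rec an \code{\link{eeg_recording}} whose annotations contain the
#'   task blocks (as produced by \code{\link{simulate_eeg}}).
#' @param channel channel label to analyse (default "O2").
#' @param window epoch length in seconds (default 0.5).
#' @param freqs analysis frequency grid for the spectra (default 1-40 Hz).
#' @param R wavelet factor (default 7).
#' @return Object of class \code{ssver}: a list with one element per flicker
#'   frequency, each holding \code{frequency}, \code{n_trials}, the averaged
#'   \code{epoch}, its \code{tf_power} spectrum, the time-averaged
#'   \code{spectrum} per frequency and the \code{peak_frequency} (grid
#'   argmax of the averaged spectrum).
#' @export
compute_ssver <- function(rec, channel = "O2", window = 0.5,
                          freqs = 1:40, R = 7) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$annotations))
    stop_invalid("invalid parameter: recording has no block annotations")
  if (!channel %in% rec$channel_labels)
    stop_invalid("invalid parameter: channel `%s` not present", channel)
  task <- rec$annotations[rec$annotations$condition == "task", ]
  if (any(window > task$duration))
    stop_invalid("invalid parameter: window (%g s) exceeds the stimulation block duration",
                 window)
  x <- rec$data[channel, ]
  rate <- rec$sampling_rate
  wlen <- round(window * rate)
  out <- list()
  for (f in sort(unique(task$frequency))) {
    bl <- task[task$frequency == f, ]
    acc <- numeric(wlen)
    n_tr <- 0L
    for (i in seq_len(nrow(bl))) {
      onsets <- seq(bl$onset[i], bl$onset[i] + bl$duration[i] - window,
                    by = 1 / (2 * f))
      for (o in onsets) {
        i0 <- round(o * rate) + 1L
        if (i0 + wlen - 1L > length(x)) next
        acc <- acc + x[i0:(i0 + wlen - 1L)]
        n_tr <- n_tr + 1L
      }
    }
    epoch <- acc / n_tr
    tfp <- morlet_power(epoch, rate, freqs = freqs, R = R)
    spec <- rowMeans(tfp$power)
    out[[as.character(f)]] <- list(
      frequency = f, n_trials = n_tr, epoch = epoch, tf = tfp,
      spectrum = spec, peak_frequency = freqs[which.max(spec)]
    )
  }
  structure(out, class = "ssver")
}

#' @export
print.ssver <- function(x, ...) {
  cat("Steady-state visual evoked responses:\n")
  for (e in x)
    cat(sprintf("  flicker %5.2f Hz: %4d trials, spectral peak at %g Hz\n",
                e$frequency, e$n_trials, e$peak_frequency))
  invisible(x)
}
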