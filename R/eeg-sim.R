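# synthetic EEG: steady-state entrainment at the reversal second harmonic,
# task-modulated alpha, and 1/f broadband noise, all reproducible by seed

# 29-channel 10/20 montage used by default (EOG/ECG channels excluded)
montage_29 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CP2", "CP6",
                "P7", "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2")
posterior_channels <- c("P7", "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2")

# inverted-U steady-state response amplitude curve: relative amplitude of the
# second-harmonic response as a function of flicker frequency; peaks at
# 7.5 Hz and vanishes above 15 Hz
default_ssver_curve <- data.frame(
  frequency = c(2, 3.75, 5, 6, 7.5, 10, 15),
  amplitude = c(0.5, 0.65, 0.8, 0.9, 1.0, 0.75, 0.35)
)

#' Parameters for the synthetic EEG generator
#'
#' @param n_electrodes number of electrodes (default 29; if not 29, channels
#'   are labelled \code{E1..En} and the last third are treated as posterior).
#' @param ssver_amplitude peak amplitude (micro-volts) of the steady-state
#'   response at the optimal flicker frequency; the frequency dependence is
#'   given by \code{ssver_curve}.
#' @param ssver_curve data frame with columns \code{frequency}, \code{amplitude}
#'   giving the relative inverted-U amplitude curve; linearly interpolated,
#'   zero outside its support.
#' @param alpha_power_rest,alpha_power_task alpha-band (10 Hz) power in
#'   micro-volts squared during rest and task blocks; alpha desynchronises
#'   during stimulation so the task value is normally lower.
#' @param alpha_freq alpha frequency in Hz (default 10).
#' @param one_over_f_exponent exponent of the 1/f^a background noise spectrum.
#' @param noise_sd per-channel standard deviation (micro-volts) of the
#'   broadband 1/f noise.
#' @param topography unit-norm spatial loading of the signal across
#'   electrodes, or NULL for the default posterior-weighted loading.
#' @param exclude_channels optional character vector of channels to drop
#'   (e.g. \code{c("Fp1", "Fp2")} for eye-blink-prone frontal electrodes).
#' @param seed master integer seed; the generator draws from the
#'   \code{"eeg-noise"} substream.
#' @return A list of class \code{eeg_sim_params}.
#' @export
eeg_sim_params <- function(n_electrodes = 29L,
                           ssver_amplitude = 5,
                           ssver_curve = default_ssver_curve,
                           alpha_power_rest = 25,
                           alpha_power_task = 10,
                           alpha_freq = 10,
                           one_over_f_exponent = 1,
                           noise_sd = 5,
                           topography = NULL,
                           exclude_channels = NULL,
                           seed = 1L) {
  n_electrodes <- check_count(n_electrodes, "n_electrodes", min = 2L)
  for (nm in c("ssver_amplitude", "alpha_power_rest", "alpha_power_task",
               "noise_sd"))
    if (get(nm) < 0) stop_invalid("invalid parameter: `%s` must be >= 0", nm)
  labels <- if (n_electrodes == 29L) montage_29 else
    paste0("E", seq_len(n_electrodes))
  if (is.null(topography)) {
    post <- if (n_electrodes == 29L) labels %in% posterior_channels else
      seq_len(n_electrodes) > ceiling(2 * n_electrodes / 3)
    topography <- ifelse(post, 1, 0.15)
  }
  if (length(topography) != n_electrodes)
    stop_invalid("invalid parameter: `topography` length must equal n_electrodes")
  topography <- topography / sqrt(sum(topography^2))
  structure(list(
    n_electrodes = n_electrodes, channel_labels = labels,
    ssver_amplitude = ssver_amplitude, ssver_curve = ssver_curve,
    alpha_power_rest = alpha_power_rest, alpha_power_task = alpha_power_task,
    alpha_freq = alpha_freq, one_over_f_exponent = one_over_f_exponent,
    noise_sd = noise_sd, topography = topography,
    exclude_channels = exclude_channels, seed = as.integer(seed)
  ), class = "eeg_sim_params")
}

# relative second-harmonic amplitude for a flicker frequency
ssver_rel_amplitude <- function(curve, f) {
  if (f < min(curve$frequency) || f > max(curve$frequency)) return(0)
  approx(curve$frequency, curve$amplitude, xout = f, rule = 1)$y
}

# 1/f^a noise of length n at the given rate, unit variance before scaling
one_over_f_noise <- function(n, exponent, rate) {
  # shape a white spectrum by f^(-a/2); flatten below 0.5 Hz so the series
  # stays stationary (the pipeline high-pass removes that range anyway)
  nf <- floor(n / 2)
  f <- seq_len(nf) * rate / n
  amp <- pmax(f, 0.5)^(-exponent / 2)
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  idx <- n - seq_len(nf - 1L) + 1L          # negative frequencies
  full[idx] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

#' Construct an EEG recording object
#'
#' @param data electrodes x samples numeric matrix (micro-volts).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one per row of \code{data}.
#' @param annotations optional data frame of block annotations
#'   (onset, duration, condition, frequency in seconds/Hz).
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          annotations = NULL) {
  if (!is.matrix(data) || nrow(data) < 2L)
    stop_invalid("degenerate input: EEG data must be a matrix with >= 2 electrode rows")
  if (any(!is.finite(data)))
    stop_invalid("invalid parameter: EEG data contains non-finite samples")
  check_positive_scalar(sampling_rate, "sampling_rate")
  if (is.null(channel_labels)) channel_labels <- paste0("E", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop_invalid("invalid parameter: one channel label per electrode required")
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' Simulate multichannel EEG for a flicker protocol
#'
#' During each task block at flicker frequency f the signal contains a
#' sinusoid at 2f (the pattern-reversal steady-state response) whose
#' amplitude follows the inverted-U curve in \code{params}; a 10 Hz alpha
#' component switches between rest and task power levels; both are projected
#' through the posterior-weighted sensor topography.  Independent 1/f-shaped
#' broadband noise is added per channel.  Output is reproducible under a
#' fixed seed.
#'
#' @param protocol a \code{\link{stim_protocol}}.
#' @param params an \code{\link{eeg_sim_params}} list.
#' @return An \code{\link{eeg_recording}} with the protocol blocks attached
#'   as annotations.
#' @examples
#' p <- generate_protocol(2, seed = 1)
#' rec <- simulate_eeg(p, eeg_sim_params(seed = 1))
#' dim(rec$data)
#' @export
simulate_eeg <- function(protocol, params = eeg_sim_params()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  rate <- protocol$eeg_rate
  fmax <- max(protocol$blocks$frequency, na.rm = TRUE)
  if (rate < 2 * (2 * fmax))
    stop_invalid("aliasing: eeg_rate %g Hz cannot represent the %g Hz response (need >= %g Hz)",
                 rate, 2 * fmax, 4 * fmax)
  n <- round(protocol$duration * rate)
  tt <- (seq_len(n) - 1) / rate
  set.seed(seed_stream(params$seed, "eeg-noise"))
  alpha_phase <- runif(1, 0, 2 * pi)

  signal <- numeric(n)
  alpha_amp <- rep(sqrt(2 * params$alpha_power_rest), n)
  task <- protocol$blocks[protocol$blocks$condition == "task", ]
  for (i in seq_len(nrow(task))) {
    f <- task$frequency[i]
    idx <- which(tt >= task$onset[i] & tt < task$onset[i] + task$duration[i])
    a <- params$ssver_amplitude * ssver_rel_amplitude(params$ssver_curve, f)
    if (a > 0)
      signal[idx] <- signal[idx] +
        a * sin(2 * pi * (2 * f) * (tt[idx] - task$onset[i]))
    alpha_amp[idx] <- sqrt(2 * params$alpha_power_task)
  }
  signal <- signal + alpha_amp * sin(2 * pi * params$alpha_freq * tt + alpha_phase)

  Y <- params$topography %o% signal
  if (params$noise_sd > 0)
    for (e in seq_len(params$n_electrodes))
      Y[e, ] <- Y[e, ] + params$noise_sd *
        one_over_f_noise(n, params$one_over_f_exponent, rate)

  labels <- params$channel_labels
  if (!is.null(params$exclude_channels)) {
    keep <- !(labels %in% params$exclude_channels)
    Y <- Y[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  eeg_recording(Y, rate, labels, annotations = protocol$blocks)
}
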