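# transfer functions: the candidate mappings from EEG spectral features to
# the BOLD predictor, evaluated per time point on a tf_power matrix

#' Construct a regressor set
#'
#' A regressor set holds one or more named transfer-function time series at
#' the EEG feature rate, before HRF expansion.  Scalar models (TP, RMSF,
#' uRMSF, MSF, MF, GFP) have one column; the frequency-response models FR3,
#' FR5 and FR8 have one column per band.
#'
#' @param columns numeric matrix (time x columns) or vector; column names
#'   are kept.
#' @param model_label model identifier, e.g. "TP", "FR3", "RMSF".
#' @param sampling_rate sampling rate of the series in Hz.
#' @param times optional time stamps in seconds.
#' @param bands optional list of band specifications (for FR models).
#' @return Object of class \code{regressor_set}.
#' @export
regressor_set <- function(columns, model_label, sampling_rate,
                          times = NULL, bands = NULL) {
  if (!is.matrix(columns)) {
    columns <- matrix(columns, ncol = 1L,
                      dimnames = list(NULL, model_label))
  }
  check_positive_scalar(sampling_rate, "sampling_rate")
  if (is.null(times)) times <- (seq_len(nrow(columns)) - 1) / sampling_rate
  structure(list(columns = columns, model_label = model_label,
                 sampling_rate = sampling_rate, times = times, bands = bands),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("Regressor set `%s`: %d column(s) x %d samples at %g Hz\n",
              x$model_label, ncol(x$columns), nrow(x$columns),
              x$sampling_rate))
  invisible(x)
}

#' Normalise a time-frequency power matrix per time point
#'
#' Divides each time column of the power matrix by its sum over frequencies,
#' so that at every time point the spectrum is a probability distribution
#' over frequencies.  Zero-total columns (impossible on realistic data with
#' broadband noise) are mapped to the uniform spectrum 1/n_f with a warning.
#'
#' @param P a \code{tf_power} object (see \code{\link{morlet_power}}).
#' @return Object of class \code{norm_spectrum} with fields \code{ptilde},
#'   \code{freqs}, \code{times}.
#' @export
normalize_spectrum <- function(P) {
  stopifnot(inherits(P, "tf_power"))
  tot <- colSums(P$power)
  zero <- tot <= 0
  if (any(zero)) {
    warning(sprintf("%d time point(s) with zero total power set to the uniform spectrum",
                    sum(zero)), call. = FALSE)
    tot[zero] <- 1
  }
  pt <- sweep(P$power, 2L, tot, "/")
  if (any(zero)) pt[, zero] <- 1 / length(P$freqs)
  structure(list(ptilde = pt, freqs = P$freqs, times = P$times,
                 sampling_rate = P$sampling_rate),
            class = "norm_spectrum")
}

# accept either raw or normalised spectra where both make sense
spectrum_matrix <- function(P) {
  if (inherits(P, "tf_power")) P$power
  else if (inherits(P, "norm_spectrum")) P$ptilde
  else stop_invalid("invalid parameter: expected a tf_power or norm_spectrum object")
}

#' Total EEG power transfer function
#'
#' Sums the time-frequency power over all analysis frequencies (1-40 Hz by
#' default), yielding the frequency-independent "Total Power" predictor:
#' a pure power transducer model of neurovascular coupling.
#'
#' @param P a \code{tf_power} object.
#' @return A single-column \code{\link{regressor_set}} labelled "TP".
#' @export
total_power <- function(P) {
  stopifnot(inherits(P, "tf_power"))
  regressor_set(colSums(P$power), "TP", P$sampling_rate, P$times)
}

#' Frequency band presets for the frequency-response models
#'
#' \itemize{
#'   \item \code{FR3}: low [1,7], alpha [8,15], high [15,40] Hz;
#'   \item \code{FR5}: delta [1,4], theta [5,8], alpha [9,13], beta [14,30],
#'     low gamma [31,40] Hz (classical band edges, shared endpoints assigned
#'     to the lower band so the bands partition the integer grid);
#'   \item \code{FR8}: eight 5 Hz bands spanning 1-40 Hz;
#'   \item \code{FR1a}: the single alpha band [8,15];
#'   \item \code{FR1bg}: the single beta/gamma band [15,40].
#' }
#' Bounds are inclusive on the integer frequency grid.
#'
#' @param name one of "FR3", "FR5", "FR8", "FR1a", "FR1bg".
#' @return A named list of \code{c(f_min, f_max)} pairs.
#' @export
band_presets <- function(name) {
  switch(name,
    FR3  = list(low = c(1, 7), alpha = c(8, 15), high = c(15, 40)),
    FR5  = list(delta = c(1, 4), theta = c(5, 8), alpha = c(9, 13),
                beta = c(14, 30), gamma = c(31, 40)),
    FR8  = {
      b <- lapply(0:7, function(i) c(1 + 5 * i, 5 + 5 * i))
      names(b) <- vapply(b, function(x) sprintf("b%d_%d", x[1], x[2]), "")
      b
    },
    FR1a  = list(alpha = c(8, 15)),
    FR1bg = list(betagamma = c(15, 40)),
    stop_invalid("invalid parameter: unknown band preset `%s`", name)
  )
}

#' Band-limited power transfer functions (frequency-response model)
#'
#' Sums power over each requested frequency interval, producing one
#' regressor column per band: the multiple-regression "Frequency Response"
#' model in its 3-, 5- or 8-band variants (or any custom banding).  Can be
#' applied to the normalised spectrum to build the normalised-band variant.
#'
#' @param P a \code{tf_power} or \code{norm_spectrum} object.
#' @param bands a preset name (see \code{\link{band_presets}}) or a named
#'   list of inclusive \code{c(f_min, f_max)} bounds.
#' @param model_label label for the set; defaults to the preset name or
#'   "FR<k>".
#' @return A \code{\link{regressor_set}} with one column per band.
#' @export
band_power <- function(P, bands = "FR3", model_label = NULL) {
  pm <- spectrum_matrix(P)
  if (is.character(bands)) {
    if (is.null(model_label)) model_label <- bands
    bands <- band_presets(bands)
  }
  if (is.null(model_label)) model_label <- sprintf("FR%d", length(bands))
  cols <- vapply(bands, function(b) {
    if (b[1] > b[2] || b[1] < min(P$freqs) || b[2] > max(P$freqs))
      stop_invalid("invalid parameter: band [%g, %g] outside the frequency grid [%g, %g]",
                   b[1], b[2], min(P$freqs), max(P$freqs))
    sel <- P$freqs >= b[1] & P$freqs <= b[2]
    colSums(pm[sel, , drop = FALSE])
  }, numeric(ncol(pm)))
  if (is.null(names(bands)))
    names(bands) <- vapply(bands, function(b) sprintf("b%g_%g", b[1], b[2]), "")
  colnames(cols) <- names(bands)
  regressor_set(cols, model_label, P$sampling_rate, P$times, bands = bands)
}

#' Root-mean-square frequency (the "Heuristic" transfer function)
#'
#' The RMS average frequency of the normalised EEG spectrum,
#' \eqn{q(t) = \sqrt{\sum_f f^2 \tilde P(f,t)}}.  A shift of relative
#' spectral mass toward higher frequencies raises the predictor regardless
#' of overall amplitude; this is the frequency-dependent coupling law the
#' package is built to test.
#'
#' @param ptilde a \code{norm_spectrum} (see \code{\link{normalize_spectrum}}).
#' @return A single-column \code{\link{regressor_set}} labelled "RMSF".
#' @export
rmsf <- function(ptilde) {
  stopifnot(inherits(ptilde, "norm_spectrum"))
  q <- sqrt(drop(crossprod(ptilde$ptilde, ptilde$freqs^2)))
  regressor_set(q, "RMSF", ptilde$sampling_rate, ptilde$times)
}

#' Un-normalised Heuristic transfer function
#'
#' Same second-moment form as \code{\link{rmsf}} but evaluated on the raw
#' (un-normalised) power matrix: \eqn{q(t) = \sqrt{\sum_f f^2 P(f,t)}}.
#' Unlike the normalised version this predictor scales with overall EEG
#' amplitude (by \eqn{\sqrt{c}} when power is scaled by \eqn{c}).
#'
#' @param P a \code{tf_power} object.
#' @return A single-column \code{\link{regressor_set}} labelled "uRMSF".
#' @export
u_rmsf <- function(P) {
  stopifnot(inherits(P, "tf_power"))
  q <- sqrt(drop(crossprod(P$power, P$freqs^2)))
  regressor_set(q, "uRMSF", P$sampling_rate, P$times)
}

#' Linear Heuristic (mean-square frequency) transfer function
#'
#' \eqn{q(t) = \sum_f f^2 \tilde P(f,t)}: the square of \code{\link{rmsf}},
#' i.e. the Heuristic without the square-root non-linearity.  Because it is
#' a fixed linear combination (weights \eqn{f^2}) of the normalised 1 Hz
#' band powers, a design containing all normalised bands spans it.
#'
#' @param ptilde a \code{norm_spectrum}.
#' @return A single-column \code{\link{regressor_set}} labelled "MSF".
#' @export
msf <- function(ptilde) {
  stopifnot(inherits(ptilde, "norm_spectrum"))
  q <- drop(crossprod(ptilde$ptilde, ptilde$freqs^2))
  regressor_set(q, "MSF", ptilde$sampling_rate, ptilde$times)
}

#' Mean frequency transfer function
#'
#' The first moment of the normalised spectrum,
#' \eqn{q(t) = \sum_f f \tilde P(f,t)}.  By Jensen's inequality it never
#' exceeds \code{\link{rmsf}}, with equality only for a point-mass spectrum.
#'
#' @param ptilde a \code{norm_spectrum}.
#' @return A single-column \code{\link{regressor_set}} labelled "MF".
#' @export
mean_frequency <- function(ptilde) {
  stopifnot(inherits(ptilde, "norm_spectrum"))
  q <- drop(crossprod(ptilde$ptilde, ptilde$freqs))
  regressor_set(q, "MF", ptilde$sampling_rate, ptilde$times)
}

#' Global field power regressor
#'
#' Wraps \code{\link{global_field_power}} as a transfer-function regressor:
#' the frequency-independent, amplitude-only predictor.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @return A single-column \code{\link{regressor_set}} labelled "GFP".
#' @export
gfp_regressor <- function(rec) {
  regressor_set(global_field_power(rec), "GFP", rec$sampling_rate)
}

#' Build the standard set of transfer-function regressors
#'
#' Convenience wrapper computing any subset of the candidate models from a
#' time-frequency power matrix (and, for GFP, the original recording).
#'
#' @param P a \code{tf_power} object.
#' @param models character vector from \{"TP", "FR3", "FR5", "FR8", "FR1a",
#'   "FR1bg", "RMSF", "uRMSF", "MSF", "MF", "GFP", "FR5n", "FR8n"\}; the
#'   "n" suffix denotes bands of the normalised spectrum.
#' @param rec the \code{eeg_recording}, required only for "GFP".
#' @return Named list of \code{\link{regressor_set}} objects.
#' @export
transfer_functions <- function(P, models = c("TP", "FR3", "RMSF"),
                               rec = NULL) {
  stopifnot(inherits(P, "tf_power"))
  need_norm <- any(models %in% c("RMSF", "MSF", "MF", "FR5n", "FR8n"))
  pt <- if (need_norm) normalize_spectrum(P) else NULL
  out <- lapply(models, function(m) {
    switch(m,
      TP    = total_power(P),
      FR3   = band_power(P, "FR3"),
      FR5   = band_power(P, "FR5"),
      FR8   = band_power(P, "FR8"),
      FR1a  = band_power(P, "FR1a"),
      FR1bg = band_power(P, "FR1bg"),
      RMSF  = rmsf(pt),
      uRMSF = u_rmsf(P),
      MSF   = msf(pt),
      MF    = mean_frequency(pt),
      FR5n  = band_power(pt, band_presets("FR5"), model_label = "FR5n"),
      FR8n  = band_power(pt, band_presets("FR8"), model_label = "FR8n"),
      GFP   = {
        if (is.null(rec))
          stop_invalid("invalid parameter: GFP needs the original recording (`rec`)")
        gfp_regressor(rec)
      },
      stop_invalid("invalid parameter: unknown model label `%s`", m)
    )
  })
  names(out) <- models
  out
}
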