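# synthetic BOLD: a chosen transfer function acts as the ground-truth
# coupling law; active voxels carry its HRF-convolved time course on top of
# AR(1) noise and slow polynomial drift

#' Parameters for the synthetic BOLD generator
#'
#' @param ground_truth_model label of the coupling law used to generate the
#'   signal, one of \code{"TP"}, \code{"FR3"}, \code{"FR5"}, \code{"FR8"},
#'   \code{"RMSF"}, \code{"uRMSF"}, \code{"MSF"}, \code{"MF"}, \code{"GFP"}.
#' @param coupling_gain signal amplitude in units of the noise standard
#'   deviation (the convolved ground-truth regressor is standardised to
#'   unit variance before scaling).
#' @param n_voxels total number of voxels.
#' @param active_voxels integer indices of voxels that carry the signal
#'   (must lie in \code{1..n_voxels}).
#' @param ar1_coefficient lag-1 autocorrelation of the noise, in [0, 1).
#' @param noise_sd marginal standard deviation of the AR(1) noise.
#' @param drift_amplitude scale of the per-voxel second-order polynomial
#'   drift (standard deviation of each polynomial coefficient over the
#'   orthonormal polynomial basis).
#' @param column_weights weights combining the (standardised) columns of a
#'   multi-column ground-truth regressor set into one signal; NULL picks 1
#'   for single columns, \code{c(-0.5, -1, 1.5)} for three-band models
#'   (the canonical low/alpha/high sign pattern: low-frequency and alpha
#'   power fall during visual activation while beta/gamma power rises) and
#'   a negative-to-positive ramp otherwise.
#' @param seed master integer seed; draws come from the \code{"bold-noise"}
#'   and \code{"motion"} substreams.
#' @return A list of class \code{bold_sim_params}.
#' @export
bold_sim_params <- function(ground_truth_model = "RMSF",
                            coupling_gain = 2,
                            n_voxels = 200L,
                            active_voxels = 1:40,
                            ar1_coefficient = 0.3,
                            noise_sd = 1,
                            drift_amplitude = 1,
                            column_weights = NULL,
                            seed = 1L) {
  known <- c("TP", "FR3", "FR5", "FR8", "RMSF", "uRMSF", "MSF", "MF", "GFP")
  if (!ground_truth_model %in% known)
    stop_invalid("invalid parameter: unknown ground_truth_model `%s`",
                 ground_truth_model)
  n_voxels <- check_count(n_voxels, "n_voxels")
  if (length(active_voxels) &&
      (any(active_voxels < 1) || any(active_voxels > n_voxels) ||
       any(active_voxels != round(active_voxels))))
    stop_invalid("invalid parameter: active_voxels must be indices in 1..n_voxels")
  if (!is.finite(ar1_coefficient) || abs(ar1_coefficient) >= 1)
    stop_invalid("invalid parameter: |ar1_coefficient| must be < 1")
  if (coupling_gain < 0 || noise_sd < 0 || drift_amplitude < 0)
    stop_invalid("invalid parameter: gain, noise_sd and drift_amplitude must be >= 0")
  structure(list(
    ground_truth_model = ground_truth_model, coupling_gain = coupling_gain,
    n_voxels = n_voxels, active_voxels = as.integer(active_voxels),
    ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, column_weights = column_weights,
    seed = as.integer(seed)
  ), class = "bold_sim_params")
}

#' Construct a BOLD dataset object
#'
#' @param Y scans x voxels numeric matrix.
#' @param TR repetition time in seconds.
#' @param sessions integer session id per scan (contiguous); default one
#'   session.
#' @param motion list with one scans-per-session x 6 matrix per session, or
#'   a single matrix for one session.
#' @param mask optional voxel index subset.
#' @return Object of class \code{bold_dataset}.
#' @export
bold_dataset <- function(Y, TR, sessions = NULL, motion = NULL, mask = NULL) {
  if (!is.matrix(Y)) stop_invalid("invalid parameter: Y must be a scans x voxels matrix")
  check_positive_scalar(TR, "TR")
  if (is.null(sessions)) sessions <- rep(1L, nrow(Y))
  if (length(sessions) != nrow(Y))
    stop_invalid("length mismatch: one session id per scan required")
  r <- rle(sessions)
  if (any(duplicated(r$values)))
    stop_invalid("invalid parameter: session ids must be contiguous")
  if (is.matrix(motion)) motion <- list(motion)
  if (!is.null(motion)) {
    if (length(motion) != length(r$values))
      stop_invalid("length mismatch: one motion matrix per session required")
    for (i in seq_along(motion))
      if (nrow(motion[[i]]) != r$lengths[i] || ncol(motion[[i]]) != 6L)
        stop_invalid("length mismatch: motion matrices must be scans x 6 per session")
  }
  structure(list(Y = Y, TR = TR, sessions = as.integer(sessions),
                 motion = motion, mask = mask),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("BOLD dataset: %d scans x %d voxels, TR = %g s, %d session(s)\n",
              nrow(x$Y), ncol(x$Y), x$TR, length(unique(x$sessions))))
  invisible(x)
}

# AR(1) series with unit marginal variance
ar1_noise <- function(n, rho) {
  if (rho == 0) return(rnorm(n))
  drop(stats::filter(rnorm(n, sd = sqrt(1 - rho^2)), rho,
                     method = "recursive",
                     init = rnorm(1)))
}

# smooth random-walk motion covariates: 6 series (3 translations mm,
# 3 rotations rad), small amplitude
simulate_motion <- function(n_scans) {
  m <- vapply(1:6, function(i) cumsum(rnorm(n_scans, sd = 0.02)), numeric(n_scans))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Simulate BOLD data from a ground-truth transfer function
#'
#' Active voxels receive \code{coupling_gain} times the ground-truth
#' regressor convolved with the canonical HRF (canonical only -- the
#' derivative kernels are an analysis device, not part of the forward
#' model), downsampled to the mid-TR acquisition times and standardised to
#' unit variance; every voxel additionally receives AR(1) noise and a
#' second-order polynomial drift.  Multi-column ground truths (band models)
#' are first combined with \code{column_weights}.
#'
#' @param q_true a \code{\link{regressor_set}} for the ground-truth model,
#'   at the EEG feature rate (its \code{model_label} must match
#'   \code{params$ground_truth_model}).
#' @param protocol the \code{\link{stim_protocol}} the features came from.
#' @param params a \code{\link{bold_sim_params}} list.
#' @param basis an \code{\link{hrf_basis}} at the feature sampling interval,
#'   or NULL to build one.
#' @return A list with elements \code{bold} (a \code{\link{bold_dataset}}
#'   including simulated motion covariates) and \code{ground_truth} (class
#'   \code{synthetic_ground_truth}: model label, the scan-rate standardised
#'   regressor, active voxel set, and all parameters/seeds).
#' @export
simulate_bold <- function(q_true, protocol, params = bold_sim_params(),
                          basis = NULL) {
  stopifnot(inherits(q_true, "regressor_set"),
            inherits(protocol, "stim_protocol"),
            inherits(params, "bold_sim_params"))
  if (q_true$model_label != params$ground_truth_model)
    stop_invalid("invalid parameter: regressor label `%s` does not match ground_truth_model `%s`",
                 q_true$model_label, params$ground_truth_model)
  n_scans <- protocol$n_scans
  TR <- protocol$TR
  if (is.null(basis)) basis <- canonical_hrf_basis(1 / q_true$sampling_rate)
  conv <- convolve_and_downsample(q_true, basis, TR, n_scans, center = TRUE)
  canon <- conv[, grepl("\\.canonical$", colnames(conv)), drop = FALSE]
  k <- ncol(canon)
  w <- params$column_weights
  if (is.null(w)) {
    # default band weights follow the canonical sign pattern of band-BOLD
    # couplings in visual block paradigms: low-frequency and alpha power
    # fall during activation, beta/gamma power rises
    w <- if (k == 1L) 1 else if (k == 3L) c(-0.5, -1, 1.5) else
      seq(-1, 1.5, length.out = k)
  }
  if (length(w) != k)
    stop_invalid("length mismatch: %d column weights needed, %d given", k, length(w))
  # weights are per-band effect sizes: standardise each convolved column
  # first so raw power-scale differences between bands do not distort the
  # intended coupling pattern
  canon <- apply(canon, 2L, function(x) {
    s <- stats::sd(x)
    if (s > 0) x / s else x
  })
  g <- drop(canon %*% w)
  s <- stats::sd(g)
  if (s > 0) g <- (g - mean(g)) / s

  set.seed(seed_stream(params$seed, "bold-noise"))
  Y <- matrix(0, n_scans, params$n_voxels)
  poly_basis <- cbind(1, stats::poly(seq_len(n_scans), 2))
  for (v in seq_len(params$n_voxels)) {
    eps <- params$noise_sd * ar1_noise(n_scans, params$ar1_coefficient)
    drift <- if (params$drift_amplitude > 0)
      drop(poly_basis %*% rnorm(3, sd = params$drift_amplitude)) else 0
    Y[, v] <- eps + drift
  }
  if (length(params$active_voxels) && params$coupling_gain > 0)
    Y[, params$active_voxels] <- Y[, params$active_voxels] +
      params$coupling_gain * g

  set.seed(seed_stream(params$seed, "motion"))
  motion <- simulate_motion(n_scans)

  truth <- structure(list(
    model_label = params$ground_truth_model,
    regressor = g,
    active_voxels = params$active_voxels,
    column_weights = w,
    params = params,
    protocol_seed = protocol$seed
  ), class = "synthetic_ground_truth")

  list(bold = bold_dataset(Y, TR, motion = motion), ground_truth = truth)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %s coupling, gain %g, %d active of %d voxels\n",
              x$model_label, x$params$coupling_gain,
              length(x$active_voxels), x$params$n_voxels))
  invisible(x)
}
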