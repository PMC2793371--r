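# hemodynamic response basis, convolution/downsampling, and the
# discrete-cosine high-pass filter

# double-gamma HRF density evaluated at times t (seconds)
double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                         peak_disp = 1, undershoot_disp = 1, ratio = 6,
                         onset = 0) {
  tt <- t - onset
  h <- dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(tt, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  h[tt < 0] <- 0
  h
}

#' Canonical HRF informed basis set
#'
#' Builds the three-function informed basis: the canonical double-gamma
#' hemodynamic response (response peak at ~5 s, undershoot peaking near
#' 16 s with ratio 1/6, 32 s support), its temporal derivative (finite
#' difference under a 1 s onset shift, accommodating responses that peak
#' about a second earlier or later) and its dispersion derivative (finite
#' difference under a small perturbation of the peak dispersion,
#' accommodating wider or narrower responses).  Both derivatives are
#' orthogonalised against the canonical kernel so the canonical coefficient
#' keeps its interpretation; F-tests over the triplet are unaffected by
#' this choice.
#'
#' @param dt kernel sampling interval in seconds (> 0).
#' @param length_s kernel support in seconds (default 32).
#' @return Object of class \code{hrf_basis}: list with \code{kernels}
#'   (length x 3 matrix: canonical, temporal derivative, dispersion
#'   derivative), \code{dt}, \code{times} and the parameterisation record.
#' @examples
#' b <- canonical_hrf_basis(0.1)
#' b$times[which.max(b$kernels[, 1])]   # canonical peaks near 5 s
#' @export
canonical_hrf_basis <- function(dt, length_s = 32) {
  check_positive_scalar(dt, "dt")
  pars <- list(peak_delay = 6, undershoot_delay = 16, peak_disp = 1,
               undershoot_disp = 1, ratio = 6, onset = 0,
               length_s = length_s, dt = dt)
  tt <- seq(0, length_s - dt, by = dt)
  canon <- double_gamma(tt)
  # temporal derivative: 1 s onset shift, divided by the shift
  td <- (canon - double_gamma(tt, onset = 1)) / 1
  # dispersion derivative: perturb the peak dispersion by 1%
  dd <- (canon - double_gamma(tt, peak_disp = 1.01)) / 0.01
  orth <- function(v, ref) v - ref * sum(v * ref) / sum(ref * ref)
  td <- orth(td, canon)
  dd <- orth(dd, canon)
  kernels <- cbind(canonical = canon, temporal = td, dispersion = dd)
  structure(list(kernels = kernels, dt = dt, times = tt, params = pars),
            class = "hrf_basis")
}

#' @export
print.hrf_basis <- function(x, ...) {
  cat(sprintf("HRF informed basis: 3 kernels, %g s support at dt = %g s (peak %.2f s)\n",
              x$params$length_s, x$dt, x$times[which.max(x$kernels[, 1])]))
  invisible(x)
}

# mid-TR acquisition times for n scans (slice-time reference: middle slice)
scan_times <- function(n_scans, TR) (seq_len(n_scans) - 0.5) * TR

#' Convolve regressors with the HRF basis and downsample to scan rate
#'
#' Each regressor column is causally convolved with each of the three basis
#' kernels, sampled at the mid-TR acquisition times
#' \eqn{t_k = (k - 1/2) TR}, and mean-centred.  Three design columns are
#' produced per input column, labelled
#' \code{<model>.<column>.<canonical|temporal|dispersion>}.
#'
#' @param q a \code{\link{regressor_set}} sampled at the feature rate (which
#'   must be at least the scan rate 1/TR).
#' @param basis an \code{\link{hrf_basis}} whose \code{dt} matches the
#'   feature sampling interval of \code{q}.
#' @param TR repetition time in seconds.
#' @param n_scans number of scans to sample.
#' @param center mean-centre the sampled columns (default TRUE).
#' @return Numeric matrix, \code{n_scans} x \code{3 * ncol(q$columns)}.
#' @export
convolve_and_downsample <- function(q, basis, TR, n_scans, center = TRUE) {
  stopifnot(inherits(q, "regressor_set"), inherits(basis, "hrf_basis"))
  check_positive_scalar(TR, "TR")
  n_scans <- check_count(n_scans, "n_scans")
  rate <- q$sampling_rate
  if (rate < 1 / TR)
    stop_invalid("invalid parameter: feature rate %g Hz below the scan rate 1/TR", rate)
  if (abs(basis$dt - 1 / rate) > 1e-9)
    stop_invalid("invalid parameter: basis dt (%g) does not match the feature sampling interval (%g)",
                 basis$dt, 1 / rate)
  n_t <- nrow(q$columns)
  if (n_t < round(n_scans * TR * rate) - 1L)
    stop_invalid("length mismatch: regressors (%.1f s) shorter than the protocol (%.1f s)",
                 n_t / rate, n_scans * TR)
  samp_idx <- pmin(round(scan_times(n_scans, TR) * rate) + 1L, n_t)
  nfft <- nextn(n_t + nrow(basis$kernels))
  out <- matrix(0, n_scans, 3L * ncol(q$columns))
  labels <- character(ncol(out))
  kern_f <- apply(basis$kernels, 2L, function(k) fft(c(k, numeric(nfft - length(k)))))
  for (j in seq_len(ncol(q$columns))) {
    xf <- fft(c(q$columns[, j], numeric(nfft - n_t)))
    for (b in 1:3) {
      conv <- Re(fft(xf * kern_f[, b], inverse = TRUE)) / nfft * basis$dt
      col <- conv[samp_idx]
      if (center) col <- col - mean(col)
      out[, 3L * (j - 1L) + b] <- col
      labels[3L * (j - 1L) + b] <- paste(q$model_label,
                                         colnames(q$columns)[j],
                                         colnames(basis$kernels)[b],
                                         sep = ".")
    }
  }
  colnames(out) <- labels
  out
}

#' Discrete cosine basis spanning slow components
#'
#' Orthonormal DCT-II columns with periods longer than \code{cutoff}
#' seconds, for a session of \code{n} scans.  These are the components the
#' high-pass filter removes (drift, slow physiological trends); they are
#' orthogonal to the constant, so session means survive filtering.
#'
#' @param n number of scans.
#' @param TR repetition time (seconds).
#' @param cutoff high-pass cutoff period in seconds (default 128).
#' @return An \code{n} x \code{K} matrix (possibly 0 columns).
#' @export
dct_highpass_basis <- function(n, TR, cutoff = 128) {
  n <- check_count(n, "n")
  K <- max(0L, ceiling(2 * n * TR / cutoff) - 1L)
  if (K == 0L) return(matrix(0, n, 0L))
  t0 <- seq_len(n) - 1L
  D <- vapply(seq_len(K),
              function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)) * sqrt(2 / n),
              numeric(n))
  D
}

#' High-pass filter a matrix of scan-rate series
#'
#' Residual-forming projection off the discrete cosine components with
#' periods longer than the cutoff, applied per session.  The constant has
#' infinite period, so the filter span includes the session mean: a
#' constant series maps to zero.  The same projection is applied to the
#' BOLD data and to the design columns of interest inside
#' \code{\link{fit_glm}}, which keeps the nested-model F-tests exact.
#'
#' @param x numeric vector or matrix (scans x series).
#' @param TR repetition time (seconds).
#' @param cutoff cutoff period in seconds (default 128).
#' @param sessions optional integer vector of session ids per row; the
#'   filter is applied within each session separately.
#' @param demean if TRUE (default) the session mean (the infinite-period
#'   component) is removed along with the slow cosines.
#' @return Filtered matrix of the same shape.
#' @examples
#' tt <- ((1:256) - 0.5) * 2
#' max(abs(highpass(cos(2 * pi * tt / 256), TR = 2)))   # ~0: inside span
#' @export
highpass <- function(x, TR, cutoff = 128, sessions = NULL, demean = TRUE) {
  x <- as.matrix(x)
  if (is.null(sessions)) sessions <- rep(1L, nrow(x))
  out <- x
  for (s in unique(sessions)) {
    idx <- which(sessions == s)
    D <- dct_highpass_basis(length(idx), TR, cutoff)
    xs <- x[idx, , drop = FALSE]
    if (demean) xs <- sweep(xs, 2L, colMeans(xs))
    if (ncol(D) > 0L) xs <- xs - D %*% crossprod(D, xs)
    out[idx, ] <- xs
  }
  out
}
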