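# mass-univariate GLM estimation and nested-model F-contrasts

#' Fit a mass-univariate GLM
#'
#' Applies the high-pass filter recorded in the design (residual-forming
#' projection off the per-session slow cosine set, session mean included)
#' to the data and to all non-constant design columns, then estimates
#' ordinary least squares per voxel.  Rank deficiency is handled through a
#' pivoted QR decomposition with rank-adjusted degrees of freedom.  The
#' residual degrees of freedom account for the dimensions removed by the
#' filter: \code{df = n - K - rank(X)}, with K the number of dropped cosine
#' components across sessions.
#'
#' @param bold a \code{\link{bold_dataset}}.
#' @param design a \code{\link{design_matrix}} built for the same data.
#' @param prewhiten if TRUE, estimate a single pooled lag-1 autocorrelation
#'   from the OLS residuals and refit after AR(1) prewhitening (off by
#'   default: the F-tests are comparative and mild autocorrelation affects
#'   all models alike).
#' @return Object of class \code{glm_fit}: list with \code{beta}
#'   (parameters x voxels; aliased columns zero), \code{residual_ss},
#'   \code{df_residual}, \code{rank}, the filtered data and design, and the
#'   design reference.
#' @export
fit_glm <- function(bold, design, prewhiten = FALSE) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(design, "design_matrix"))
  if (nrow(bold$Y) != nrow(design$X))
    stop_invalid("length mismatch: %d scans of data vs %d design rows",
                 nrow(bold$Y), nrow(design$X))
  sess <- design$sessions
  K <- 0L
  for (s in unique(sess))
    K <- K + ncol(dct_highpass_basis(sum(sess == s), design$TR,
                                     design$hp_cutoff))
  is_const <- apply(design$X, 2L, function(col) {
    for (s in unique(sess)) {
      v <- col[sess == s]
      if (any(v != v[1L])) return(FALSE)
    }
    TRUE
  })
  Xf <- design$X
  Xf[, !is_const] <- highpass(design$X[, !is_const, drop = FALSE],
                              design$TR, design$hp_cutoff, sess)
  Yf <- highpass(bold$Y, design$TR, design$hp_cutoff, sess)

  if (prewhiten) {
    qr0 <- qr(Xf)
    res0 <- qr.resid(qr0, Yf)
    num <- sum(colSums(res0[-1L, , drop = FALSE] * res0[-nrow(res0), , drop = FALSE]))
    den <- sum(res0^2)
    rho <- if (den > 0) num / den else 0
    W <- function(M) {
      out <- M
      for (s in unique(sess)) {
        i <- which(sess == s)
        out[i[-1L], ] <- (M[i[-1L], , drop = FALSE] -
                            rho * M[i[-length(i)], , drop = FALSE]) /
          sqrt(1 - rho^2)
      }
      out
    }
    Xf <- W(Xf)
    Yf <- W(Yf)
  } else {
    rho <- NA_real_
  }

  qrx <- qr(Xf)
  rank <- qrx$rank
  beta <- qr.coef(qrx, Yf)
  aliased <- is.na(beta[, 1L])
  beta[is.na(beta)] <- 0
  res <- qr.resid(qrx, Yf)
  rss <- colSums(res^2)
  # K filter dimensions per design + the session means are both counted:
  # mean columns are orthogonal to the filtered data, so rank(X) includes
  # them while they explain nothing -- the accounting stays exact
  df_res <- nrow(Yf) - K - rank
  if (df_res <= 0)
    stop_invalid("invalid parameter: no residual degrees of freedom (n = %d, K = %d, rank = %d)",
                 nrow(Yf), K, rank)
  structure(list(beta = beta, residual_ss = rss, df_residual = df_res,
                 rank = rank, aliased = aliased, n_filter = K,
                 X_filtered = Xf, Y_filtered = Yf, design = design,
                 ar1_rho = rho),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM fit: %d voxels, rank %d/%d, residual df %d%s\n",
              ncol(x$beta), x$rank, ncol(x$X_filtered), x$df_residual,
              if (!is.na(x$ar1_rho)) sprintf(", AR(1) rho = %.3f", x$ar1_rho)
              else ""))
  invisible(x)
}

#' Extra-sum-of-squares F-contrast over a set of design columns
#'
#' Tests the additional variance explained by the given columns: the full
#' model is compared with the reduced model from which they are removed
#' (equivalent to an explicit reduced-model refit).  The numerator degrees
#' of freedom are the rank difference between the two models, so
#' collinearity within or across sets is accounted for automatically.
#'
#' @param fit a \code{\link{glm_fit}}.
#' @param columns integer column indices to test, or a model label from the
#'   design partition.  Confound columns cannot be tested.
#' @return Object of class \code{f_comparison}: list with per-voxel
#'   \code{F}, \code{df} (numerator, denominator), \code{p_uncorrected},
#'   Bonferroni-corrected \code{p_bonferroni}, and the tested column set.
#' @export
f_contrast <- function(fit, columns) {
  stopifnot(inherits(fit, "glm_fit"))
  design <- fit$design
  if (is.character(columns)) {
    if (!columns %in% names(design$partition))
      stop_invalid("invalid parameter: no partition entry `%s`", columns)
    columns <- design$partition[[columns]]
  }
  columns <- as.integer(columns)
  if (!length(columns) || any(columns < 1L) || any(columns > ncol(design$X)))
    stop_invalid("invalid parameter: column indices out of range")
  if (any(columns %in% design$partition$confounds))
    stop_invalid("invalid parameter: tested set overlaps the confounds")
  qr_r <- qr(fit$X_filtered[, -columns, drop = FALSE])
  rss_r <- colSums(qr.resid(qr_r, fit$Y_filtered)^2)
  df1 <- fit$rank - qr_r$rank
  if (df1 < 1L)
    stop_invalid("invalid parameter: tested columns add no rank to the design")
  df2 <- fit$df_residual
  F <- pmax(0, (rss_r - fit$residual_ss) / df1) / (fit$residual_ss / df2)
  p <- pf(F, df1, df2, lower.tail = FALSE)
  n_vox <- length(F)
  structure(list(F = F, df = c(df1, df2), p_uncorrected = p,
                 p_bonferroni = pmin(1, n_vox * p), columns = columns),
            class = "f_comparison")
}

#' @export
print.f_comparison <- function(x, ...) {
  cat(sprintf("F-contrast over %d column(s): F(%d, %d), max F = %.2f, %d voxel(s) with Bonferroni p < 0.05\n",
              length(x$columns), x$df[1], x$df[2], max(x$F),
              sum(x$p_bonferroni < 0.05)))
  invisible(x)
}
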