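# figure-style summaries (base graphics): regressor traces, steady-state
# response spectra, component topography

#' Plot transfer-function regressors against the block paradigm
#'
#' @param x a named list of \code{\link{regressor_set}} objects or a single
#'   set.
#' @param protocol optional \code{\link{stim_protocol}}; task blocks are
#'   shaded.
#' @param xlim optional time range in seconds.
#' @param ... passed to \code{matplot}.
#' @export
plot_regressors <- function(x, protocol = NULL, xlim = NULL, ...) {
  if (inherits(x, "regressor_set")) x <- list(x)
  n <- length(x)
  old <- graphics::par(mfrow = c(n, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (r in x) {
    z <- scale(r$columns)
    graphics::matplot(r$times, z, type = "l", lty = 1,
                      xlab = "time (s)", ylab = r$model_label,
                      xlim = xlim, ...)
    if (!is.null(protocol)) {
      b <- protocol$blocks[protocol$blocks$condition == "task", ]
      graphics::rect(b$onset, graphics::par("usr")[3],
                     b$onset + b$duration, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.25), border = NA)
    }
  }
  invisible(x)
}

#' Plot steady-state evoked response spectra per flicker frequency
#'
#' One panel per condition, with the expected second-harmonic response
#' frequency marked.
#'
#' @param x an \code{ssver} object from \code{\link{compute_ssver}}.
#' @param ... passed to \code{plot}.
#' @export
plot_ssver <- function(x, ...) {
  stopifnot(inherits(x, "ssver"))
  n <- length(x)
  old <- graphics::par(mfrow = c(ceiling(n / 2), 2), mar = c(3, 3.5, 1.5, 1))
  on.exit(graphics::par(old))
  for (e in x) {
    graphics::plot(e$tf$freqs, e$spectrum, type = "h", lwd = 2,
                   xlab = "frequency (Hz)", ylab = "power",
                   main = sprintf("flicker %g Hz", e$frequency), ...)
    graphics::abline(v = 2 * e$frequency, col = "red", lty = 2)
  }
  invisible(x)
}

#' Bar chart of the first spatial component's electrode loadings
#'
#' @param x a \code{scalp_series} from \code{\link{principal_projection}}.
#' @param ... passed to \code{barplot}.
#' @export
plot_topography <- function(x, ...) {
  stopifnot(inherits(x, "scalp_series"))
  graphics::barplot(x$eigenvector, las = 2, cex.names = 0.7,
                    ylab = "loading",
                    main = sprintf("first spatial component (%.0f%% variance)",
                                   100 * x$variance_explained), ...)
  invisible(x)
}
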