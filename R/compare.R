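# model comparison reports: separate vs shared designs, thresholded voxel
# counts and maxima within/outside the activation mask; plus the
# stimulus-driven activation mask and a seeded model-recovery study

#' Compare transfer-function models voxel-wise
#'
#' In \code{"separate"} mode each model gets its own design matrix and the
#' F-test measures its marginal correlation with BOLD; in \code{"shared"}
#' mode all models enter one design and each model's F-test measures the
#' variance it uniquely explains (variance no other model in the design can
#' account for).  For every model the report gives the number of
#' suprathreshold voxels and the maximum F within and outside the mask, at
#' a Bonferroni family-wise threshold and an uncorrected threshold.
#'
#' @param bold a \code{\link{bold_dataset}}.
#' @param models named list of \code{\link{regressor_set}} objects (or
#'   per-session list of such lists), as for \code{\link{assemble_design}}.
#' @param mode \code{"shared"} (default) or \code{"separate"}.
#' @param mask optional integer vector of voxel indices ("within" region);
#'   its complement is the "outside" region.  NULL reports a single "all"
#'   region.
#' @param basis optional \code{\link{hrf_basis}}.
#' @param alpha_fwe family-wise (Bonferroni) threshold, default 0.05.
#' @param alpha_unc uncorrected threshold, default 0.001.
#' @param hp_cutoff high-pass cutoff in seconds, default 128.
#' @param prewhiten passed to \code{\link{fit_glm}}.
#' @return Object of class \code{comparison_report}: a data frame with one
#'   row per model x region x threshold (columns \code{model},
#'   \code{region}, \code{threshold}, \code{n_vox}, \code{F_max},
#'   \code{peak_voxel}), with the per-model \code{f_comparison} objects,
#'   mode and degrees of freedom attached as attributes.  \code{F_max} and
#'   \code{peak_voxel} are NA when no voxel passes the threshold; ties for
#'   the maximum resolve to the lowest voxel index.
#' @export
compare_models <- function(bold, models, mode = c("shared", "separate"),
                           mask = NULL, basis = NULL,
                           alpha_fwe = 0.05, alpha_unc = 0.001,
                           hp_cutoff = 128, prewhiten = FALSE) {
  mode <- match.arg(mode)
  per_session <- length(models) > 0L && !inherits(models[[1L]], "regressor_set")
  labels <- if (per_session) names(models[[1L]]) else names(models)
  if (is.null(labels) || length(labels) == 0L)
    stop_invalid("invalid parameter: empty model list")

  tests <- list()
  if (mode == "shared") {
    design <- assemble_design(models, bold, basis, hp_cutoff)
    fit <- fit_glm(bold, design, prewhiten)
    for (m in labels) tests[[m]] <- f_contrast(fit, m)
  } else {
    for (m in labels) {
      one <- if (per_session) lapply(models, function(s) s[m]) else models[m]
      design <- assemble_design(one, bold, basis, hp_cutoff)
      fit <- fit_glm(bold, design, prewhiten)
      tests[[m]] <- f_contrast(fit, m)
    }
  }

  n_vox <- ncol(bold$Y)
  regions <- if (is.null(mask)) list(all = seq_len(n_vox)) else
    list(within = as.integer(mask),
         outside = setdiff(seq_len(n_vox), as.integer(mask)))
  rows <- list()
  for (m in labels) {
    ts <- tests[[m]]
    for (rg in names(regions)) {
      idx <- regions[[rg]]
      for (thr in c("fwe", "uncorrected")) {
        p <- if (thr == "fwe") ts$p_bonferroni[idx] else ts$p_uncorrected[idx]
        alpha <- if (thr == "fwe") alpha_fwe else alpha_unc
        sig <- which(p < alpha)
        if (length(sig)) {
          Fs <- ts$F[idx][sig]
          j <- which.max(Fs)   # first maximum = lowest voxel index on ties
          fmax <- Fs[j]
          peak <- idx[sig[j]]
        } else {
          fmax <- NA_real_
          peak <- NA_integer_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, region = rg, threshold = thr,
          n_vox = length(sig), F_max = fmax, peak_voxel = peak,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  structure(report, class = c("comparison_report", "data.frame"),
            mode = mode, tests = tests,
            alpha = c(fwe = alpha_fwe, uncorrected = alpha_unc))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Model comparison (%s design%s):\n", attr(x, "mode"),
              if (attr(x, "mode") == "shared") ": unique variance per model"
              else "s: marginal variance per model"))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Stimulus-driven BOLD activation mask
#'
#' Fits a GLM with the stimulus-onset boxcar (task blocks) expanded through
#' the HRF basis -- the only analysis in which onset regressors are used --
#' and returns the voxels whose F-test survives the Bonferroni threshold.
#' The resulting mask restricts transfer-function comparisons to
#' stimulus-responsive voxels.
#'
#' @param bold a \code{\link{bold_dataset}} (single session, or sessions
#'   sharing the protocol).
#' @param protocol the \code{\link{stim_protocol}}.
#' @param basis optional \code{\link{hrf_basis}} at dt = 0.1 s.
#' @param alpha Bonferroni family-wise level, default 0.05.
#' @param hp_cutoff high-pass cutoff in seconds, default 128.
#' @return Integer vector of voxel indices, with the underlying
#'   \code{f_comparison} attached as attribute \code{"test"}.
#' @export
activation_mask <- function(bold, protocol, basis = NULL, alpha = 0.05,
                            hp_cutoff = 128) {
  stopifnot(inherits(bold, "bold_dataset"), inherits(protocol, "stim_protocol"))
  if (alpha < 0 || alpha > 1)
    stop_invalid("invalid parameter: alpha must be in [0, 1]")
  dt <- 0.1
  if (is.null(basis)) basis <- canonical_hrf_basis(dt)
  tt <- seq(0, protocol$duration - basis$dt, by = basis$dt)
  box <- regressor_set(protocol_boxcar(protocol, tt), "stimulus", 1 / basis$dt)
  design <- assemble_design(list(stimulus = box), bold, basis, hp_cutoff)
  fit <- fit_glm(bold, design)
  ts <- f_contrast(fit, "stimulus")
  mask <- which(ts$p_bonferroni < alpha)
  attr(mask, "test") <- ts
  mask
}

#' Seeded model-recovery study
#'
#' For each candidate ground-truth coupling law, simulates coupled EEG-BOLD
#' datasets across replicates, derives the activation mask from the
#' stimulus regressors, runs the shared-design comparison over
#' \code{compare} (all candidate models in one design), and records which
#' model attains the highest within-mask maximum F.  The EEG (and hence the
#' transfer-function regressors) is shared across ground truths within a
#' replicate, so the comparison is paired.
#'
#' @param truths character vector of generator labels (default
#'   \code{c("TP", "FR3", "RMSF")}).
#' @param compare character vector of models entering the shared design
#'   (default the same three).
#' @param n_replicates number of seeded replicates, default 10.
#' @param n_task_blocks task blocks per replicate (default 30, i.e. 300
#'   scans).
#' @param seed master seed; replicate r uses master \code{seed + r}.
#' @param eeg_params,bold_params parameter templates (seeds are overridden
#'   per replicate).
#' @param freqs,R analysis frequency grid and wavelet factor.
#' @param mask_alpha Bonferroni level for the activation mask.
#' @param verbose print one line per replicate.
#' @return Object of class \code{recovery_study}: list with \code{winners}
#'   (truths x replicates character matrix), \code{recovery_rate} (named
#'   fraction of replicates recovering each truth) and the study settings.
#' @export
model_recovery_study <- function(truths = c("TP", "FR3", "RMSF"),
                                 compare = c("TP", "FR3", "RMSF"),
                                 n_replicates = 10L,
                                 n_task_blocks = 30L,
                                 seed = 1L,
                                 eeg_params = eeg_sim_params(),
                                 bold_params = bold_sim_params(),
                                 freqs = 1:40, R = 7,
                                 mask_alpha = 0.05,
                                 verbose = FALSE) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  winners <- matrix(NA_character_, length(truths), n_replicates,
                    dimnames = list(truths, NULL))
  for (r in seq_len(n_replicates)) {
    master <- as.integer(seed) + r
    protocol <- generate_protocol(n_task_blocks, seed = master)
    ep <- eeg_params
    ep$seed <- master
    rec <- simulate_eeg(protocol, ep)
    scalp <- principal_projection(rec)
    P <- morlet_power(scalp, freqs = freqs, R = R)
    needed <- unique(c(truths, compare))
    regs <- transfer_functions(P, models = needed, rec = rec)
    basis <- canonical_hrf_basis(1 / P$sampling_rate)
    for (tr in truths) {
      bp <- bold_params
      bp$ground_truth_model <- tr
      bp$seed <- master
      sim <- simulate_bold(regs[[tr]], protocol, bp, basis)
      mask <- activation_mask(sim$bold, protocol)
      rep_cmp <- compare_models(sim$bold, regs[compare], mode = "shared",
                                mask = mask, basis = basis)
      fmax <- vapply(attr(rep_cmp, "tests"),
                     function(ts) if (length(mask)) max(ts$F[mask]) else
                       max(ts$F), numeric(1))
      winners[tr, r] <- names(fmax)[which.max(fmax)]
      if (verbose)
        message(sprintf("replicate %d, truth %-4s -> winner %-4s (F_max %s)",
                        r, tr, winners[tr, r],
                        paste(sprintf("%s %.1f", names(fmax), fmax),
                              collapse = ", ")))
    }
  }
  rate <- vapply(truths, function(tr) mean(winners[tr, ] == tr), numeric(1))
  structure(list(winners = winners, recovery_rate = rate,
                 truths = truths, compare = compare,
                 n_replicates = n_replicates, seed = seed,
                 n_task_blocks = n_task_blocks),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Model recovery over %d replicate(s), shared design {%s}:\n",
              x$n_replicates, paste(x$compare, collapse = ", ")))
  for (tr in x$truths)
    cat(sprintf("  truth %-5s recovered %2.0f%% (winners: %s)\n", tr,
                100 * x$recovery_rate[tr],
                paste(x$winners[tr, ], collapse = " ")))
  invisible(x)
}
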