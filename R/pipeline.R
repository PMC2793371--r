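# end-to-end orchestration: simulate -> features -> transfer functions ->
# design -> comparison, with a provenance manifest

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by
#' \code{\link{run_pipeline}}, with every tunable stated explicitly:
#' protocol geometry (30 task blocks of 5 scans at TR 3.06 s, i.e. 300
#' scans), EEG generator parameters, BOLD generator parameters (RMSF
#' ground truth by default), the analysis frequency grid 1-40 Hz with
#' wavelet factor 7, the 128 s high-pass, and the models entering the
#' shared comparison.
#'
#' @param seed master integer seed, expanded into named substreams.
#' @return A named list; override entries with
#'   \code{modifyList(default_config(), list(...))}.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    protocol = list(n_task_blocks = 30L, TR = 3.06, eeg_rate = 250),
    eeg = list(ssver_amplitude = 5, alpha_power_rest = 25,
               alpha_power_task = 10, noise_sd = 5,
               one_over_f_exponent = 1),
    bold = list(ground_truth_model = "RMSF", coupling_gain = 2,
                n_voxels = 200L, n_active = 40L, ar1_coefficient = 0.3,
                noise_sd = 1, drift_amplitude = 1),
    analysis = list(freqs = 1:40, R = 7, hp_cutoff = 128,
                    models = c("TP", "FR3", "RMSF"), mode = "shared",
                    alpha_fwe = 0.05, alpha_unc = 0.001, mask_alpha = 0.05)
  )
}

check_config <- function(config) {
  needed <- list(
    seed = character(0),
    protocol = c("n_task_blocks", "TR", "eeg_rate"),
    eeg = character(0),
    bold = c("ground_truth_model"),
    analysis = c("freqs", "R", "hp_cutoff", "models", "mode")
  )
  for (key in names(needed)) {
    if (is.null(config[[key]]))
      stop_invalid("validation error: missing config key `%s`", key)
    for (sub in needed[[key]])
      if (is.null(config[[key]][[sub]]))
        stop_invalid("validation error: missing config key `%s$%s`", key, sub)
  }
  invisible(config)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage from one configuration: protocol generation, EEG
#' simulation, principal projection and Morlet power, transfer-function
#' regressors, BOLD simulation under the configured ground-truth coupling,
#' activation-mask estimation, and the model comparison.  All randomness
#' derives from the master seed through named substreams, so identical
#' configurations produce identical results and manifests.
#'
#' @param config configuration list (see \code{\link{default_config}}), or
#'   a path to a JSON file with the same structure.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as delimited matrices/JSON sidecars and listed in the manifest.
#' @param keep_intermediates if TRUE the returned object retains the large
#'   intermediates (EEG recording, time-frequency power).
#' @return Object of class \code{pipeline_result}: list with
#'   \code{report} (the \code{comparison_report}), \code{mask},
#'   \code{ground_truth}, \code{ssver} summaries, stage summaries, and a
#'   \code{manifest} recording the config snapshot, seeds, package version
#'   and per-stage checksums.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         keep_intermediates = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  # the config must be complete: start from default_config() and override
  # entries with modifyList() rather than passing fragments
  check_config(config)
  seed <- config$seed

  protocol <- generate_protocol(config$protocol$n_task_blocks,
                                TR = config$protocol$TR, seed = seed,
                                eeg_rate = config$protocol$eeg_rate)
  ep <- do.call(eeg_sim_params, c(config$eeg, list(seed = seed)))
  rec <- simulate_eeg(protocol, ep)
  scalp <- principal_projection(rec)
  P <- morlet_power(scalp, freqs = config$analysis$freqs,
                    R = config$analysis$R)
  models <- unique(c(config$analysis$models, config$bold$ground_truth_model))
  regs <- transfer_functions(P, models = models, rec = rec)
  basis <- canonical_hrf_basis(1 / P$sampling_rate)

  bp_args <- config$bold
  bp_args$active_voxels <- seq_len(bp_args$n_active %||% 40L)
  bp_args$n_active <- NULL
  bp <- do.call(bold_sim_params, c(bp_args, list(seed = seed)))
  sim <- simulate_bold(regs[[config$bold$ground_truth_model]], protocol,
                       bp, basis)
  mask <- activation_mask(sim$bold, protocol,
                          alpha = config$analysis$mask_alpha %||% 0.05,
                          hp_cutoff = config$analysis$hp_cutoff)
  report <- compare_models(sim$bold, regs[config$analysis$models],
                           mode = config$analysis$mode, mask = mask,
                           basis = basis,
                           alpha_fwe = config$analysis$alpha_fwe %||% 0.05,
                           alpha_unc = config$analysis$alpha_unc %||% 0.001,
                           hp_cutoff = config$analysis$hp_cutoff)

  stages <- list(protocol = protocol, eeg = rec,
                 features = list(scalp = scalp, P = P),
                 regressors = regs, bold = sim, mask = mask,
                 report = report)
  manifest <- list(
    config = config,
    seeds = list(master = seed,
                 substreams = vapply(c("block-order", "eeg-noise",
                                       "bold-noise", "motion"),
                                     function(s) seed_stream(seed, s), 0L)),
    version = as.character(utils::packageVersion("eegbold")),
    checksums = vapply(stages, obj_checksum, character(1))
  )
  if (!is.null(out_dir)) {
    manifest$files <- write_pipeline_outputs(out_dir, protocol, rec, regs,
                                             sim, mask, report, manifest)
  }
  out <- list(report = report, mask = mask,
              ground_truth = sim$ground_truth,
              variance_explained = scalp$variance_explained,
              protocol = protocol, manifest = manifest)
  if (keep_intermediates) {
    out$eeg <- rec
    out$scalp <- scalp
    out$power <- P
    out$regressors <- regs
    out$bold <- sim$bold
  }
  structure(out, class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result (seed %d): ground truth %s, %d mask voxel(s)\n",
              x$manifest$seeds$master, x$ground_truth$model_label,
              length(x$mask)))
  print(x$report)
  invisible(x)
}

# write stage outputs as flat text + JSON sidecars; returns checksummed
# file inventory
write_pipeline_outputs <- function(out_dir, protocol, rec, regs, sim, mask,
                                   report, manifest) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(x, name) {
    path <- file.path(out_dir, name)
    if (is.data.frame(x) || is.matrix(x)) {
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    files <<- c(files, path)
    path
  }
  wr(protocol$blocks, "protocol.tsv")
  wr(list(TR = protocol$TR, n_scans = protocol$n_scans,
          eeg_rate = protocol$eeg_rate, seed = protocol$seed),
     "protocol.json")
  # EEG as a flat binary matrix + sidecar (electrodes x samples, doubles)
  eeg_path <- file.path(out_dir, "eeg.f64")
  con <- file(eeg_path, "wb")
  writeBin(as.vector(rec$data), con, size = 8)
  close(con)
  files <- c(files, eeg_path)
  wr(list(n_electrodes = nrow(rec$data), n_samples = ncol(rec$data),
          sampling_rate = rec$sampling_rate, order = "electrode-major",
          channel_labels = rec$channel_labels),
     "eeg.json")
  reg_mat <- do.call(cbind, lapply(regs, function(r) r$columns))
  colnames(reg_mat) <- unlist(lapply(regs, function(r)
    paste(r$model_label, colnames(r$columns), sep = ".")))
  wr(round(reg_mat, 6), "regressors.tsv")
  wr(round(sim$bold$Y, 6), "bold.tsv")
  wr(list(model_label = sim$ground_truth$model_label,
          active_voxels = sim$ground_truth$active_voxels,
          column_weights = sim$ground_truth$column_weights,
          regressor = sim$ground_truth$regressor),
     "ground_truth.json")
  wr(list(mask = as.integer(mask)), "mask.json")
  wr(as.data.frame(report), "report.tsv")
  wr(manifest[c("config", "seeds", "version", "checksums")], "manifest.json")
  data.frame(file = basename(files),
             md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}
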