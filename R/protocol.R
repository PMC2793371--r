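#' Reversal frequencies of the flicker paradigm
#'
#' The checkerboard reversal frequencies used in the block design, in Hz.
#' Steady-state visual evoked responses are entrained at twice these values
#' (the pattern-reversal second harmonic).
#'
#' @export
flicker_frequencies <- c(2, 3.75, 5, 6, 7.5, 10, 15, 30)

#' Construct a stimulus protocol with an explicit block order
#'
#' Builds the alternating task/rest block structure of the flicker paradigm:
#' each task block lasts 5 scans (15.3 s at TR = 3.06 s) and is followed by
#' an equally long rest block.  \code{\link{generate_protocol}} wraps this
#' constructor with a seeded random frequency ordering.
#'
#' @param frequencies numeric vector of flicker frequencies (Hz), one per
#'   task block, each drawn from \code{\link{flicker_frequencies}} unless
#'   \code{strict = FALSE}.
#' @param TR repetition time in seconds (default 3.06).
#' @param eeg_rate EEG sampling rate in Hz (default 250).
#' @param scans_per_block scans per task (and per rest) block, default 5.
#' @param strict if TRUE (default), frequencies outside the canonical set
#'   are rejected.
#' @return An object of class \code{stim_protocol}: a list with a
#'   \code{blocks} data frame (onset, duration, condition, frequency),
#'   \code{n_scans}, \code{TR}, \code{eeg_rate} and \code{duration}.
#' @examples
#' p <- stim_protocol(c(10, 6, 5))
#' p$n_scans   # 30
#' @export
stim_protocol <- function(frequencies, TR = 3.06, eeg_rate = 250,
                          scans_per_block = 5L, strict = TRUE) {
  check_positive_scalar(TR, "TR")
  check_positive_scalar(eeg_rate, "eeg_rate")
  scans_per_block <- check_count(scans_per_block, "scans_per_block")
  if (length(frequencies) < 1L || any(!is.finite(frequencies)) ||
      any(frequencies <= 0))
    stop_invalid("invalid parameter: `frequencies` must be positive and non-empty")
  if (strict && !all(frequencies %in% flicker_frequencies))
    stop_invalid("invalid parameter: frequencies must come from the flicker set (%s)",
                 paste(flicker_frequencies, collapse = ", "))
  n_task <- length(frequencies)
  block_dur <- scans_per_block * TR
  onsets <- (seq_len(2L * n_task) - 1L) * block_dur
  blocks <- data.frame(
    onset     = onsets,
    duration  = block_dur,
    condition = rep(c("task", "rest"), n_task),
    frequency = as.numeric(rbind(frequencies, NA)),
    stringsAsFactors = FALSE
  )
  structure(list(
    blocks   = blocks,
    n_scans  = 2L * n_task * scans_per_block,
    TR       = TR,
    eeg_rate = eeg_rate,
    duration = 2L * n_task * block_dur
  ), class = "stim_protocol")
}

#' Generate a randomised flicker block protocol
#'
#' Draws a seeded random sequence of flicker frequencies (sampling with
#' replacement from \code{\link{flicker_frequencies}}) and arranges them in
#' alternating 5-scan task / 5-scan rest blocks.  Two different seeds give
#' the same timing grid but different frequency orderings.
#'
#' @param n_task_blocks number of task blocks (>= 1).
#' @param TR repetition time in seconds (default 3.06).
#' @param seed integer seed for the block-order substream.
#' @param eeg_rate EEG sampling rate in Hz (default 250).
#' @return A \code{\link{stim_protocol}} object.
#' @examples
#' p <- generate_protocol(8, seed = 1)
#' p$duration   # 244.8 s
#' @export
generate_protocol <- function(n_task_blocks, TR = 3.06, seed = 1L,
                              eeg_rate = 250) {
  n_task_blocks <- check_count(n_task_blocks, "n_task_blocks")
  check_positive_scalar(TR, "TR")
  set.seed(seed_stream(seed, "block-order"))
  # random permutation-with-repetition: cycle through shuffled copies of the
  # frequency set so all frequencies appear before any repeats
  k <- length(flicker_frequencies)
  n_rep <- ceiling(n_task_blocks / k)
  freqs <- unlist(lapply(seq_len(n_rep),
                         function(i) sample(flicker_frequencies)))
  freqs <- freqs[seq_len(n_task_blocks)]
  p <- stim_protocol(freqs, TR = TR, eeg_rate = eeg_rate)
  p$seed <- as.integer(seed)
  p
}

#' @export
print.stim_protocol <- function(x, ...) {
  n_task <- sum(x$blocks$condition == "task")
  cat(sprintf("Stimulus protocol: %d task + %d rest blocks, %d scans (TR %.2f s, %.1f s)\n",
              n_task, n_task, x$n_scans, x$TR, x$duration))
  cat("Task frequencies (Hz):",
      paste(x$blocks$frequency[x$blocks$condition == "task"], collapse = " "),
      "\n")
  invisible(x)
}

# boxcar indicator of task blocks on an arbitrary time grid (seconds)
protocol_boxcar <- function(protocol, times) {
  b <- protocol$blocks[protocol$blocks$condition == "task", ]
  out <- numeric(length(times))
  for (i in seq_len(nrow(b)))
    out[times >= b$onset[i] & times < b$onset[i] + b$duration[i]] <- 1
  out
}
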