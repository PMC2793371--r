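# design-matrix assembly: HRF-expanded regressors of interest partitioned
# per model, plus per-session confounds (6 motion + 1 mean)

#' Parameter-count bookkeeping for a model comparison design
#'
#' Per session a comparison estimates \code{(sum of regressor columns
#' across models) x 3 basis functions + 7 confounds} parameters (6 motion
#' covariates and 1 session mean); sessions contribute independent blocks.
#'
#' @param n_regressors integer vector: number of regressor columns per
#'   model in the comparison (1 for scalar models, 3/5/8 for FR3/FR5/FR8).
#' @param n_sessions number of sessions (default 1).
#' @param n_basis basis functions per regressor (default 3).
#' @param n_confounds confounds per session (default 7).
#' @return A list with \code{per_session} and \code{total} parameter counts.
#' @examples
#' count_design_parameters(c(1, 3, 1), n_sessions = 9)$total   # 198
#' @export
count_design_parameters <- function(n_regressors, n_sessions = 1L,
                                    n_basis = 3L, n_confounds = 7L) {
  per <- sum(n_regressors) * n_basis + n_confounds
  list(per_session = per, total = per * n_sessions)
}

#' Assemble a partitioned multi-session design matrix
#'
#' For each session, every column of every model's regressor set is
#' expanded through the three-function HRF basis and downsampled to scan
#' rate (3 design columns per regressor column), then the session's 6
#' motion covariates and a session-mean column are appended.  Sessions are
#' block-concatenated, giving \code{(sum(n_R) * 3 + 7) * n_sessions}
#' columns in total, with a recorded partition mapping every model (and
#' "confounds") to its column indices across sessions.
#'
#' @param models a named list of \code{\link{regressor_set}} objects (one
#'   session), or a list of such lists (one element per session).  Model
#'   labels must be unique within a session.
#' @param bold a \code{\link{bold_dataset}} providing scan counts, session
#'   structure and motion covariates.
#' @param basis an \code{\link{hrf_basis}} matching the feature sampling
#'   interval, or NULL to build one per session.
#' @param hp_cutoff high-pass cutoff period in seconds, stored with the
#'   design and applied (to data and non-constant columns alike) at fit
#'   time; default 128.
#' @return Object of class \code{design_matrix}: list with \code{X},
#'   \code{column_labels}, \code{partition} (model -> column indices, plus
#'   \code{confounds}), \code{sessions}, \code{TR}, \code{hp_cutoff}.
#' @export
assemble_design <- function(models, bold, basis = NULL, hp_cutoff = 128) {
  stopifnot(inherits(bold, "bold_dataset"))
  sess_ids <- unique(bold$sessions)
  n_sess <- length(sess_ids)
  if (length(models) == 0L)
    stop_invalid("invalid parameter: empty model list")
  # normalise `models` to a per-session list
  if (inherits(models[[1L]], "regressor_set"))
    models <- rep(list(models), n_sess)
  if (length(models) != n_sess)
    stop_invalid("length mismatch: %d session(s) of regressors for %d session(s) of data",
                 length(models), n_sess)
  labels0 <- names(models[[1L]])
  if (is.null(labels0) || any(labels0 == ""))
    stop_invalid("invalid parameter: models must be a named list")
  if (anyDuplicated(labels0))
    stop_invalid("invalid parameter: duplicate model labels in the design")

  blocks <- vector("list", n_sess)
  col_labels <- character(0)
  owner <- character(0)   # which partition each column belongs to
  for (s in seq_len(n_sess)) {
    rows <- which(bold$sessions == sess_ids[s])
    n_s <- length(rows)
    ms <- models[[s]]
    if (!identical(names(ms), labels0))
      stop_invalid("invalid parameter: model labels differ across sessions")
    interest <- lapply(ms, function(q) {
      b <- if (is.null(basis)) canonical_hrf_basis(1 / q$sampling_rate) else basis
      convolve_and_downsample(q, b, bold$TR, n_s, center = TRUE)
    })
    mot <- if (!is.null(bold$motion)) bold$motion[[s]] else
      matrix(0, n_s, 6L, dimnames = list(NULL, paste0("m", 1:6)))
    conf <- cbind(mot, mean = 1)
    Xs <- cbind(do.call(cbind, interest), conf)
    blocks[[s]] <- Xs
    lab_s <- c(unlist(lapply(interest, colnames), use.names = FALSE),
               paste0("confound.", colnames(conf)))
    col_labels <- c(col_labels, paste0("sess", sess_ids[s], ".", lab_s))
    owner <- c(owner,
               rep(labels0, times = vapply(interest, ncol, 0L)),
               rep("confounds", ncol(conf)))
  }
  n_total <- nrow(bold$Y)
  X <- matrix(0, n_total, length(col_labels))
  ofs <- 0L
  for (s in seq_len(n_sess)) {
    rows <- which(bold$sessions == sess_ids[s])
    X[rows, ofs + seq_len(ncol(blocks[[s]]))] <- blocks[[s]]
    ofs <- ofs + ncol(blocks[[s]])
  }
  colnames(X) <- col_labels
  partition <- lapply(c(labels0, confounds = "confounds"),
                      function(m) which(owner == m))
  names(partition) <- c(labels0, "confounds")
  structure(list(X = X, column_labels = col_labels, partition = partition,
                 sessions = bold$sessions, TR = bold$TR,
                 hp_cutoff = hp_cutoff, model_labels = labels0),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d scans x %d columns, %d session(s), high-pass %g s\n",
              nrow(x$X), ncol(x$X), length(unique(x$sessions)), x$hp_cutoff))
  for (m in names(x$partition))
    cat(sprintf("  %-10s %d column(s)\n", m, length(x$partition[[m]])))
  invisible(x)
}
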