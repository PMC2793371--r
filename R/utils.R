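# input checking helpers, shared across modules

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("invalid parameter: `%s` must be a positive finite scalar", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop_invalid("invalid parameter: `%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

#' Derive a named substream seed from a master seed
#'
#' One master seed is expanded into independent named substreams (for
#' example \code{"eeg-noise"}, \code{"bold-noise"}, \code{"block-order"}) so
#' that one component of a simulation can be varied while the others are
#' held fixed.  The mapping is a small deterministic string hash; it is
#' stable across platforms and R sessions.
#'
#' @param master integer master seed.
#' @param stream character name of the substream.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' seed_stream(42, "eeg-noise")
#' seed_stream(42, "bold-noise")
#' @export
seed_stream <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, keeps results in integer range
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% m
  as.integer((h + (abs(master) %% m) * 7919) %% m)
}

# md5 of an R object via a temporary serialized file (used for manifests)
obj_checksum <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}
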