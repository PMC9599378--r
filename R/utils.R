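#' Derive a per-stage seed from the global seed
#'
#' Each pipeline stage seeds its own RNG with a value derived from the
#' global seed and the stage name, so stages are independently reproducible
#' and inserting a stage never perturbs the seeds of the others.
#'
#' @param seed global integer seed.
#' @param stage stage name (character scalar).
#' @return an integer in \[1, 2^31 - 2\].
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(seed %% 2147483647)
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h + 1)
}

# log messages to stderr with a stage tag
acam_log <- function(..., stage = "acam") {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
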