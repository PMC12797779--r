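#' Derive a stage-specific seed from a global seed
#'
#' Deterministically maps a (seed, label) pair to an integer in
#' `[0, 2^31 - 2]` so that pipeline stages and repeated sub-analyses get
#' decoupled but reproducible random streams.
#'
#' @param seed integer global seed.
#' @param label character label of the consumer (stage name, test id, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483587  # large prime < 2^31
  h <- as.numeric(seed) %% m
  for (v in utf8ToInt(as.character(label))) h <- (h * 131 + v) %% m
  as.integer(h)
}
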