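#' Derive a deterministic child seed
#'
#' Mixes a base seed with a string or integer salt so that per-animal /
#' per-stage random streams are reproducible and independent of processing
#' order. Result is always a positive integer below 2^31.
#'
#' @param seed Integer base seed.
#' @param salt String or integer salt.
#' @return Integer seed.
#' @export
child_seed <- function(seed, salt) {
  s <- utf8ToInt(as.character(salt))
  h <- 0
  for (v in s) h <- (h * 131 + v) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}
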