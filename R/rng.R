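#' Derive a named child seed from a root seed
#'
#' Every stochastic stage of a simulation run draws from its own named
#' substream so that adding or reordering stages never perturbs the draws of
#' earlier ones. The child seed is a deterministic hash of the root seed and
#' the stream name, kept strictly below 2^31 so it is a valid R integer seed.
#'
#' @param seed Integer root seed.
#' @param name Character stream name (e.g. `"pem"`, `"cem"`, `"targets"`).
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483563
  # 48271 is the MINSTD multiplier; all arithmetic stays exact in doubles
  as.integer((h + (abs(as.double(seed)) %% 2147483563) * 48271) %% 2147483562 + 1)
}

with_stream <- function(seed, name, expr) {
  if (!is.null(seed)) set.seed(substream_seed(seed, name))
  expr
}
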