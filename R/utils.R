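#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic stage of the pipeline consumes a seed derived
#' deterministically from the master seed and a human-readable label, so that
#' stages are reproducible independently of execution order.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the stage (e.g. `"assoc:MLI_LA"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% p
  as.integer((h * 48271 + (abs(as.numeric(seed)) %% p) * 69621) %% p)
}

# round-half-up; base round() is round-half-even which would make percentile
# cut sizes depend on parity of N
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sign convention for eigen/singular vectors: the entry with the
# largest magnitude is made positive
canonical_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}
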