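#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive reproducible sub-seeds from a master seed without exhausting the
# 32-bit integer range. Used wherever one run spawns several independent
# random streams (tree vs traits vs chain, or one chain per model).
derive_seeds <- function(seed, n, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (as.integer(seed) %% 1000000L) * 1000L + stream * 100L + seq_len(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
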