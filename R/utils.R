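# Internal helpers: classed error conditions and deterministic seed streams.

tpb_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "twophasebn_error", "error")))
}

tpb_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) tpb_error(class, msg)
  invisible(TRUE)
}

#' Derive a reproducible child seed from a base seed
#'
#' Deterministic linear-congruential mixing used wherever one user-supplied
#' seed has to drive several independent random stages (topology, parameters,
#' sampling, column shuffle, replicates).  Results always lie in
#' `[1, 2^31 - 2]` so they are valid arguments to [set.seed()].
#'
#' @param seed Integer base seed.
#' @param k Integer stream index (any non-negative integer).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 1:4)
derive_seed <- function(seed, k) {
  m <- 2147483587 # prime below 2^31; products stay exact in doubles
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(k) * 7919
  as.integer(s %% m + 1)
}

# set.seed only when a seed was actually given
seed_if <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
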