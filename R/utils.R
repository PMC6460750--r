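# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' Every stochastic operation in the package draws from a named substream of
#' a single master seed, so adding a new stochastic feature never perturbs
#' the draws of existing ones.
#'
#' @param seed master seed (single integer-like value).
#' @param name substream name, e.g. `"founders_W"`.
#' @return an integer seed below 2^31, a pure function of `(seed, name)`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(name) == 1L)
  m <- 2147483629  # largest prime < 2^31
  h <- 0
  for (k in utf8ToInt(as.character(name))) h <- (h * 131 + k) %% m
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807 + 1) %% m)
}

# Evaluate `code` under a named substream without disturbing the caller's RNG.
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# Symmetry check used before eigen decompositions.
is_symmetric_tol <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol * max(1, max(abs(x)))
}

# FNV-1a hash of a character scalar; used for config provenance hashes.
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ogb <- function(..., call. = FALSE) stop(..., call. = call.)
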