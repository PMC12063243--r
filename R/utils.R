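# Internal numerical and seeding helpers.

expit <- stats::plogis
logit <- stats::qlogis

#' FNV-1a 32-bit hash of a character key
#'
#' Used to derive named random-number substreams from a single global seed, so
#' that adding a generated column never perturbs the draws of earlier columns.
#' Arithmetic is done in 16-bit halves to stay inside double precision.
#'
#' @param key single character string.
#' @return integer-valued double in [0, 2^32).
#' @keywords internal
fnv1a32 <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  fnv_fold(utf8ToInt(key))
}

# FNV-1a over a vector of byte values; arithmetic kept within double
# precision by splitting the 32-bit state into 16-bit halves (bitwXor only
# accepts 32-bit signed integers, and the byte only touches the low half).
fnv_fold <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

#' Derive a substream seed from a base seed and a column key
#'
#' @param seed base integer seed.
#' @param key character label of the substream (e.g. a column name).
#' @return integer seed in [0, 2^31 - 2], usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, key) {
  as.integer(fnv1a32(paste0(format(seed, scientific = FALSE), ":", key)) %%
               2147483646)
}

# Evaluate `expr` under a named substream of `seed`, restoring RNG state after.
with_substream <- function(seed, key, expr) {
  withr::with_seed(substream_seed(seed, key), expr)
}

# Stable short hash of an arbitrary R object (config fingerprinting in logs).
object_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- fnv_fold(as.integer(raw))
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

is_binary01 <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
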