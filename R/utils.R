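# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' All randomness in the package flows from a single master seed. Independent
#' random streams (one per sample during imputation, one per generator stage)
#' are obtained by hashing a string key together with the master seed, so that
#' subsetting samples or reordering stages never perturbs the draws of the
#' others.
#'
#' The rule: the key is folded to an integer by a position-weighted character
#' sum, combined with the master seed by a fixed prime multiplier, and reduced
#' modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param key character scalar naming the stream.
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  codes <- utf8ToInt(as.character(key))
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

# Consistent condition signalling: configuration errors vs format errors.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cibop_config_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("cibop_format_error", "error")))
}

# Case-fold gene symbols for all set operations. Mouse symbols (Gfap) and
# human-cased lists (GFAP) must compare equal.
fold_symbols <- function(x) toupper(trimws(as.character(x)))

# First symbol of a semicolon-separated protein-group symbol string.
first_symbol <- function(x) {
  vapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(s) if (length(s)) trimws(s[[1L]]) else "", character(1))
}
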