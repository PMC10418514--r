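# Internal helpers shared across modules.

#' @importFrom stats setNames
NULL

# Lowercase tokenization on non-alphanumeric boundaries; used by the lexical
# retriever and the hashed embedding stubs.
.tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# Deterministic polynomial string hash modulo 2^31 - 1.  All intermediate
# products stay below 2^53 so the arithmetic is exact in doubles.
.hash_string <- function(x, mod = 2147483647) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% mod
  h
}

# Hash-derived uniform in [0, 1): reproducible, order-independent pseudo
# randomness keyed by an arbitrary string.
.hash_unif <- function(key) {
  .hash_string(key) / 2147483647
}

# Hash-derived draw from 1..n.
.hash_pick <- function(key, n) {
  as.integer(.hash_string(paste0(key, "#pick")) %% n) + 1L
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

.is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

# Normalize all user-visible text to NFC once, at the data-model boundary.
.nfc <- function(x) {
  enc2utf8(x)
}

.stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "trialmatchr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
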