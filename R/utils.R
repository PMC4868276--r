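# Shared constants and small helpers.

# Alphabetical single-letter amino-acid order used for every 20-wide encoding
# block (PSSM/HH probability columns, CKSAAP pair order, composition vectors).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

# Integer codes: 1..20 for AA20, 21 for gap/unknown.
aa_code <- function(x) {
  i <- match(x, AA20)
  i[is.na(i)] <- 21L
  i
}

#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Stratified k-fold plan: within each class, shuffle then deal round-robin.
# Returns an integer fold id (1..k) per sample; deterministic given seed.
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  fold <- integer(length(labels))
  rng <- local({
    set.seed(seed)
    lapply(unique(labels), function(cl) sample(which(labels == cl)))
  })
  for (idx in rng) {
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# FNV-1a 32-bit hash over the UTF-8 bytes of a string; returned as 8 hex chars.
# Used to stamp artifacts with a configuration fingerprint.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte; keep h a double to stay within 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so every intermediate stays exactly representable in a double
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # format as 8 hex chars; split into 16-bit halves since the value may
  # exceed the integer range
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config, control = "all"), collapse = ""))
}

# Format a numeric so that read.table round-trips it bit-exactly.
format_full <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
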