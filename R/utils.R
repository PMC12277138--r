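# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Stable key for an unordered node pair; global indices are 1-based.
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "-")
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

msg_line <- function(...) {
  message(sprintf(...))
}
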