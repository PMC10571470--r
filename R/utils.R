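# Internal helpers shared across modules.

# Derive a reproducible substream seed from a master seed and an index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(index)) %% 2147483629L)
}

# Stop with a consistent error class so tests can assert on failures.
stop_cafscape <- function(msg, class = "cafscape_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

upper_symbols <- function(x) toupper(trimws(x))
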