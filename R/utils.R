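# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_finite_numeric <- function(x, what = "values") {
  if (!is.numeric(x)) {
    stop(what, " must be numeric", call. = FALSE)
  }
  if (length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be non-empty and finite", call. = FALSE)
  }
  invisible(x)
}

assert_bits <- function(x, what = "state") {
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(what, " must be a 0/1 vector", call. = FALSE)
  }
  invisible(as.integer(x))
}

# MSB-first weights for a k-input truth-table index.
bit_weights <- function(k) {
  if (k == 0L) numeric(0) else 2^((k - 1L):0)
}

# Row index (1-based) into a 2^k truth table; inputs[1] is the most
# significant bit.
pattern_index <- function(bits, k) {
  if (k == 0L) return(1L)
  as.integer(sum(bits * bit_weights(k)) + 1)
}

# Bit pattern (MSB first) of truth-table row `idx` (1-based).
index_bits <- function(idx, k) {
  if (k == 0L) return(integer(0))
  as.integer(intToBits(idx - 1L))[k:1]
}

state_key <- function(bits) paste(bits, collapse = "")

# Derived seed streams: one draw per unit of work so results do not depend
# on how the work is interleaved. Seeds stay below 2^31 - 1.
draw_seeds <- function(n) sample.int(2147483646L, n)

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

geometric_mean <- function(x) exp(mean(log(x)))
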