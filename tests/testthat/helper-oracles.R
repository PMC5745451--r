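# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (exhaustive enumeration) and shares no code
# with the package internals it checks.

# MSB-first bits of integer i (0-based) over n positions.
int_to_bits <- function(i, n) {
  as.integer(intToBits(i))[n:1]
}

bits_to_int <- function(bits) {
  n <- length(bits)
  as.integer(sum(bits * 2^((n - 1):0)))
}

# Minimal SSE over ALL placements of d breaks in the sorted vector.
oracle_step_sse <- function(values, d) {
  s <- sort(values)
  n <- length(s)
  seg_sse <- function(v) sum((v - mean(v))^2)
  placements <- utils::combn(n - 1, d, simplify = FALSE)
  min(vapply(placements, function(br) {
    bounds <- c(0, br, n)
    sum(vapply(seq_len(d + 1), function(j) {
      seg_sse(s[(bounds[j] + 1):bounds[j + 1]])
    }, numeric(1)))
  }, numeric(1)))
}

# Minimal number of misclassified transition pairs over all input sets of
# size <= max_k and ALL Boolean functions on them (brute force; k <= 3).
oracle_min_error <- function(pairs, target, max_k) {
  n <- length(pairs$gene_ids)
  lab <- as.integer(pairs$states1[, target])
  best <- Inf
  for (k in 0:max_k) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      kk <- length(s)
      pat <- if (kk == 0) {
        rep(1L, nrow(pairs$states0))
      } else {
        as.integer(pairs$states0[, s, drop = FALSE] %*% 2^((kk - 1):0) + 1)
      }
      size <- 2^kk
      for (fidx in 0:(2^size - 1)) {
        tab <- as.integer(intToBits(fidx))[seq_len(size)]
        best <- min(best, sum(tab[pat] != lab))
      }
    }
  }
  best
}

# All states lying on a cycle, found from the exhaustive state transition
# graph by iterated squaring of the successor map.
oracle_cycle_states <- function(net) {
  n <- length(net$gene_ids)
  N <- 2^n
  succ <- vapply(seq_len(N), function(i) {
    bits_to_int(bn_transition(net, int_to_bits(i - 1, n))) + 1L
  }, integer(1))
  comp <- succ
  for (j in seq_len(ceiling(log2(N)) + 1L)) comp <- comp[comp]
  sort(unique(comp))
}

# Exact mean damage of a temporary single-bit flip after `horizon`
# transitions, averaged over all 2^n states and all n flip positions.
oracle_damage_mean <- function(net, horizon) {
  n <- length(net$gene_ids)
  N <- 2^n
  tot <- 0
  for (i in seq_len(N)) {
    x <- int_to_bits(i - 1, n)
    for (b in seq_len(n)) {
      y <- x
      y[b] <- 1L - y[b]
      xa <- x
      ya <- y
      for (h in seq_len(horizon)) {
        xa <- bn_transition(net, xa)
        ya <- bn_transition(net, ya)
      }
      tot <- tot + mean(abs(xa - ya))
    }
  }
  tot / (N * n)
}

# Check that a candidate function reproduces the observed next-state value
# of its target on every transition pair.
replays_exactly <- function(f, pairs, target) {
  k <- length(f$inputs)
  pred <- if (k == 0) {
    rep(f$table[1], nrow(pairs$states0))
  } else {
    idx <- as.integer(pairs$states0[, f$inputs, drop = FALSE] %*%
                        2^((k - 1):0) + 1)
    f$table[idx]
  }
  all(!is.na(pred)) && all(pred == pairs$states1[, target])
}

# Transitions object built directly from explicit pair lists (used where a
# time series would be awkward, e.g. zero pairs).
make_transitions <- function(states0, states1, gene_ids) {
  structure(list(states0 = states0, states1 = states1, gene_ids = gene_ids),
            class = "bn_transitions")
}

# Tiny named example networks used across test files.
net_and_not <- function() {
  # x1' = x1 & x2 ; x2' = !x1
  boolean_network(list(list(inputs = c(1L, 2L), table = c(0L, 0L, 0L, 1L)),
                       list(inputs = 1L, table = c(1L, 0L))),
                  c("x1", "x2"))
}

net_swap <- function() {
  boolean_network(list(list(inputs = 2L, table = c(0L, 1L)),
                       list(inputs = 1L, table = c(0L, 1L))),
                  c("x1", "x2"))
}

net_identity <- function(n) {
  boolean_network(lapply(seq_len(n), function(i) {
    list(inputs = i, table = c(0L, 1L))
  }))
}

net_constant <- function(n, value = 0L) {
  boolean_network(lapply(seq_len(n), function(i) {
    list(inputs = integer(0), table = value)
  }))
}

as_single_function_set <- function(net) {
  structure(list(gene_ids = net$gene_ids,
                 functions = lapply(net$functions, list),
                 errors = stats::setNames(rep(0, length(net$gene_ids)),
                                          net$gene_ids),
                 dependencies = data.frame(regulator = character(0),
                                           target = character(0))),
            class = "bn_function_set")
}

# Five-node XOR ring whose rules genuinely depend on both inputs, plus a
# multi-segment series covering many distinct states (segments marked by
# group labels so no pair spans a restart).
xor_ring_network <- function() {
  boolean_network(lapply(1:5, function(i) {
    list(inputs = sort(c(i %% 5L + 1L, (i + 1L) %% 5L + 1L)),
         table = c(0L, 1L, 1L, 0L))
  }))
}

xor_ring_series <- function(n_segments = 4, len = 4, seed = 5) {
  set.seed(seed)
  net <- xor_ring_network()
  mats <- lapply(seq_len(n_segments), function(s) {
    x0 <- sample(c(0L, 1L), 5, replace = TRUE)
    t(bn_simulate(net, x0, len - 1))
  })
  binary <- do.call(cbind, mats)
  rownames(binary) <- net$gene_ids
  list(net = net, binary = binary,
       groups = rep(seq_len(n_segments), each = len))
}
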