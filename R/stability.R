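# Perturbation experiments: temporary single-bit state flips, damage after
# one and five synchronous transitions measured by the normalized Hamming
# distance, aggregated over sampled networks into min/max/mean summaries and
# compared between groups with Wilcoxon rank-sum tests.

#' Normalized Hamming distance between two states
#'
#' Hn(x, x') = (1/n) * sum_i |x_i - x'_i|: the fraction of positions at
#' which two equal-length 0/1 vectors differ.
#'
#' @param x,y 0/1 vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' hamming_normalized(c(0, 1, 1), c(0, 1, 0))
hamming_normalized <- function(x, y) {
  x <- assert_bits(x)
  y <- assert_bits(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  mean(abs(x - y))
}

#' Flip random state bits
#'
#' Flips exactly `n_bits` distinct positions (drawn without replacement from
#' the current RNG stream), so the perturbed state is at normalized Hamming
#' distance `n_bits / n` from `x`.
#'
#' @param x 0/1 state vector.
#' @param n_bits Number of distinct positions to flip (1 <= n_bits <= n).
#' @param seed Optional integer seed.
#' @return The perturbed state.
#' @export
perturb_state <- function(x, n_bits = 1L, seed = NULL) {
  x <- assert_bits(x)
  n <- length(x)
  if (n_bits < 1L || n_bits > n) {
    stop("n_bits must be between 1 and the state length", call. = FALSE)
  }
  set_seed_if(seed)
  pos <- sample.int(n, n_bits)
  x[pos] <- 1L - x[pos]
  x
}

#' Damage of a temporary bitflip after h transitions
#'
#' Draws a perturbed copy of `x` with `n_bits` random bits flipped, applies
#' `horizon` synchronous transitions to both the original and the perturbed
#' state (the perturbation is temporary: nothing is re-flipped along the
#' walk), and returns the normalized Hamming distance of the two resulting
#' states.
#'
#' @param net A `boolean_network`.
#' @param x 0/1 start state.
#' @param n_bits Number of bits flipped (default 1).
#' @param horizon Number of transitions (>= 1).
#' @param seed Optional integer seed for the flip draw.
#' @return A number in \[0, 1\].
#' @export
damage_at_horizon <- function(net, x, n_bits = 1L, horizon = 1L, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"), horizon >= 1L)
  x <- assert_bits(x)
  xp <- perturb_state(x, n_bits, seed = seed)
  for (h in seq_len(horizon)) {
    x <- bn_transition(net, x)
    xp <- bn_transition(net, xp)
  }
  hamming_normalized(x, xp)
}

#' Draw start states of a given class
#'
#' `random`: uniform over the 2^n state space. `successor`: the synchronous
#' successor of a uniform draw. `attractor`: a uniformly chosen member of
#' the cycle reached from a uniform draw.
#'
#' @param net A `boolean_network`.
#' @param class One of `"random"`, `"successor"`, `"attractor"`.
#' @param n_states Number of states to draw.
#' @param seed Optional integer seed.
#' @return n_states x n 0/1 matrix, one start state per row.
#' @export
start_states <- function(net, class = c("random", "successor", "attractor"),
                         n_states, seed = NULL) {
  stopifnot(inherits(net, "boolean_network"), n_states >= 1L)
  class <- match.arg(class)
  set_seed_if(seed)
  n <- length(net$gene_ids)
  draws <- matrix(sample(c(0L, 1L), n_states * n, replace = TRUE),
                  nrow = n_states)
  switch(class,
    random = draws,
    successor = bn_transition_matrix(net, draws),
    attractor = {
      out <- draws
      for (i in seq_len(n_states)) {
        att <- find_attractor(net, draws[i, ])
        out[i, ] <- att$states[sample.int(att$length, 1L), ]
      }
      out
    }
  )
}

# Flip n_bits distinct random positions in every row of a state matrix.
perturb_matrix <- function(M, n_bits) {
  n <- ncol(M)
  if (n_bits == 1L) {
    pos <- sample.int(n, nrow(M), replace = TRUE)
    idx <- cbind(seq_len(nrow(M)), pos)
    M[idx] <- 1L - M[idx]
  } else {
    for (i in seq_len(nrow(M))) {
      pos <- sample.int(n, n_bits)
      M[i, pos] <- 1L - M[i, pos]
    }
  }
  M
}

#' Monte-Carlo stability experiment over sampled networks
#'
#' For each of `n_networks` networks sampled from the candidate set, and for
#' each start-state class, draws `n_states` start states, perturbs each by a
#' temporary flip of `n_flip_bits` random bits, and records the mean
#' normalized Hamming distance between the perturbed and unperturbed
#' trajectories after each horizon. The per-network averages (the unit of
#' the group comparison) are retained; summary cells report their
#' min/max/mean per (class, horizon). A pooled per-network mean over all
#' classes is reported as well.
#'
#' @param fs A `bn_function_set`.
#' @param n_networks Networks sampled from the candidate set (default 1000).
#' @param n_states Start states per class per network (default 1000).
#' @param n_flip_bits Bits flipped per trial (default 1).
#' @param horizons Transition horizons to evaluate (default `c(1, 5)`).
#' @param state_classes Subset of random/successor/attractor (default all).
#' @param seed Optional master seed; per-network streams are derived from it
#'   so results do not depend on loop interleaving.
#' @return Object of class `stability_summary`: `per_network` (array
#'   networks x classes x horizons of per-network average distances),
#'   `pooled` (networks x horizons, classes pooled), `table` (data.frame of
#'   min/max/mean per class and horizon) and `config`.
#' @export
stability_experiment <- function(fs, n_networks = 1000L, n_states = 1000L,
                                 n_flip_bits = 1L, horizons = c(1L, 5L),
                                 state_classes = c("random", "successor",
                                                   "attractor"),
                                 seed = NULL) {
  stopifnot(inherits(fs, "bn_function_set"),
            n_networks >= 1L, n_states >= 1L, all(horizons >= 1L))
  state_classes <- match.arg(state_classes, several.ok = TRUE)
  set_seed_if(seed)
  net_seeds <- draw_seeds(n_networks)
  hmax <- max(horizons)
  per_network <- array(
    NA_real_, c(n_networks, length(state_classes), length(horizons)),
    dimnames = list(NULL, state_classes, paste0("h", horizons))
  )
  for (i in seq_len(n_networks)) {
    set.seed(net_seeds[i])
    net <- sample_network(fs)
    for (ci in seq_along(state_classes)) {
      S <- start_states(net, state_classes[ci], n_states)
      A <- S
      B <- perturb_matrix(S, n_flip_bits)
      for (h in seq_len(hmax)) {
        A <- bn_transition_matrix(net, A)
        B <- bn_transition_matrix(net, B)
        hi <- match(h, horizons)
        if (!is.na(hi)) {
          per_network[i, ci, hi] <- mean(abs(A - B))
        }
      }
    }
  }
  pooled <- apply(per_network, c(1, 3), mean)
  cells <- expand.grid(class = state_classes, horizon = horizons,
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    v <- per_network[, cells$class[r], paste0("h", cells$horizon[r])]
    data.frame(class = cells$class[r], horizon = cells$horizon[r],
               min = min(v), max = max(v), mean = mean(v))
  }))
  structure(
    list(per_network = per_network, pooled = pooled, table = tab,
         config = list(n_networks = n_networks, n_states = n_states,
                       n_flip_bits = n_flip_bits, horizons = horizons,
                       state_classes = state_classes, seed = seed)),
    class = "stability_summary"
  )
}

#' @export
print.stability_summary <- function(x, ...) {
  cat("Stability experiment:", x$config$n_networks, "networks x",
      x$config$n_states, "states per class,",
      x$config$n_flip_bits, "bit flip(s)\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.stability_summary <- function(object, ...) object$table

#' @export
plot.stability_summary <- function(x, main = "Per-network mean damage", ...) {
  d <- x$per_network
  cls <- dimnames(d)[[2]]
  hrz <- dimnames(d)[[3]]
  cols <- as.vector(outer(cls, hrz, paste, sep = " "))
  vals <- lapply(seq_along(cols), function(j) {
    ci <- (j - 1L) %% length(cls) + 1L
    hi <- (j - 1L) %/% length(cls) + 1L
    d[, ci, hi]
  })
  names(vals) <- cols
  graphics::boxplot(vals, las = 2, ylab = "normalized Hamming distance",
                    main = main, ...)
  invisible(x)
}

#' Compare the stability of two groups
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) on the two samples of per-network average Hamming distances,
#' for every (class, horizon) cell shared by the two summaries.
#'
#' @param a,b `stability_summary` objects with identical cell structure.
#' @return Object of class `stability_comparison`: a data.frame with class,
#'   horizon, the rank-sum statistic, the p-value and the two group medians.
#' @export
compare_stability <- function(a, b) {
  stopifnot(inherits(a, "stability_summary"), inherits(b, "stability_summary"))
  da <- dimnames(a$per_network)
  db <- dimnames(b$per_network)
  if (!identical(da[2:3], db[2:3])) {
    stop("summaries have different cell structure", call. = FALSE)
  }
  if (dim(a$per_network)[1] == 0L || dim(b$per_network)[1] == 0L) {
    stop("empty per-network samples", call. = FALSE)
  }
  cells <- expand.grid(class = da[[2]], horizon = da[[3]],
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    va <- a$per_network[, cells$class[r], cells$horizon[r]]
    vb <- b$per_network[, cells$class[r], cells$horizon[r]]
    if (stats::var(c(va, vb)) == 0) {
      # fully tied cell: the samples are indistinguishable
      stat <- length(va) * length(vb) / 2
      p <- 1
    } else {
      wt <- stats::wilcox.test(va, vb, exact = FALSE, correct = TRUE)
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(class = cells$class[r], horizon = cells$horizon[r],
               statistic = stat, p_value = p,
               median_a = stats::median(va), median_b = stats::median(vb))
  }))
  structure(out, class = c("stability_comparison", "data.frame"))
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat("Wilcoxon rank-sum comparison of per-network mean Hamming distances\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
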