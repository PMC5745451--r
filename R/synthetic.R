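# Synthetic two-group studies: ground-truth random Boolean networks, binary
# trajectories with optional observation noise, and a real-valued microarray
# style emission so every pipeline stage is testable without downloads.

#' Random Boolean network
#'
#' Every node receives `k` distinct inputs drawn uniformly at random and a
#' truth table whose entries are 1 with probability `bias`.
#'
#' @param n Number of nodes.
#' @param k In-degree (0 <= k <= n).
#' @param bias Probability of a 1 entry (0 < bias < 1); default 0.5.
#' @param seed Optional integer seed.
#' @param exclude_constant If TRUE, resample any constant truth table (only
#'   meaningful for k >= 1); used when every node must be able to vary.
#' @param gene_ids Optional node names.
#' @return A `boolean_network`.
#' @export
random_network <- function(n, k, bias = 0.5, seed = NULL,
                           exclude_constant = FALSE, gene_ids = NULL) {
  if (k < 0L || k > n) stop("k must be between 0 and n", call. = FALSE)
  if (bias <= 0 || bias >= 1) stop("bias must be in (0, 1)", call. = FALSE)
  set_seed_if(seed)
  functions <- lapply(seq_len(n), function(g) {
    inputs <- if (k == 0L) integer(0) else sort(sample.int(n, k))
    tab <- stats::rbinom(2^k, 1L, bias)
    if (exclude_constant && k >= 1L) {
      tries <- 0L
      while (length(unique(tab)) == 1L && tries < 100L) {
        tab <- stats::rbinom(2^k, 1L, bias)
        tries <- tries + 1L
      }
    }
    new_bn_function(inputs, tab)
  })
  boolean_network(functions, gene_ids %||% sprintf("g%02d", seq_len(n)))
}

#' Binary time series from a ground-truth network
#'
#' Synchronous trajectory from `x0` of the given length; each observed bit
#' is then flipped independently with probability `flip_noise`.
#'
#' @param net A `boolean_network`.
#' @param length Number of timepoints (>= 2).
#' @param x0 Initial state; uniform random if omitted.
#' @param flip_noise Per-bit observation flip probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Genes x timepoints 0/1 matrix (rownames = gene ids).
#' @export
generate_binary_series <- function(net, length, x0 = NULL, flip_noise = 0,
                                   seed = NULL) {
  stopifnot(inherits(net, "boolean_network"), length >= 2L,
            flip_noise >= 0, flip_noise <= 1)
  set_seed_if(seed)
  n <- base::length(net$gene_ids)
  if (is.null(x0)) x0 <- sample(c(0L, 1L), n, replace = TRUE)
  traj <- bn_simulate(net, x0, length - 1L)
  obs <- t(traj) # genes x timepoints
  if (flip_noise > 0) {
    flips <- matrix(stats::runif(base::length(obs)) < flip_noise, nrow(obs))
    obs <- abs(obs - as.integer(flips))
  }
  rownames(obs) <- net$gene_ids
  storage.mode(obs) <- "integer"
  obs
}

#' Real-valued expression from a binary matrix
#'
#' Two-component location emission: a 1 bit draws from
#' Normal(`high_mean`, `spread`), a 0 bit from Normal(`low_mean`, `spread`),
#' values floored at a small positive constant so geometric-mean
#' aggregation stays defined. With `spread = 0` every binarizable gene takes
#' exactly two distinct values.
#'
#' @param binary Genes x timepoints 0/1 matrix.
#' @param low_mean,high_mean Emission means (positive, high > low).
#' @param spread Emission standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric matrix of the same shape and dimnames.
#' @export
generate_expression <- function(binary, low_mean = 6, high_mean = 10,
                                spread = 0.25, seed = NULL) {
  if (low_mean <= 0 || high_mean <= 0) {
    stop("emission means must be positive", call. = FALSE)
  }
  if (high_mean <= low_mean) stop("high_mean must exceed low_mean", call. = FALSE)
  set_seed_if(seed)
  mu <- ifelse(binary == 1L, high_mean, low_mean)
  vals <- stats::rnorm(length(binary), mean = mu, sd = spread)
  out <- matrix(pmax(vals, 1e-3), nrow(binary), dimnames = dimnames(binary))
  out
}

#' Specification of a synthetic two-group study
#'
#' Defaults emulate the study design of a two-group human muscle microarray
#' time series: 22 genes carrying ground-truth Boolean dynamics (in-degree
#' 2), 7 young and 8 aged timepoints, noise-free observation, and a
#' well-separated two-component emission on a log2-microarray-like scale.
#'
#' @param n_genes Total genes in the emitted matrix.
#' @param n_binarizable Genes driven by the ground-truth networks (the rest
#'   are unimodal noise genes); <= n_genes.
#' @param timepoints_young,timepoints_aged Series lengths (default 7 / 8).
#' @param in_degree Ground-truth in-degree (default 2).
#' @param bias Truth-table 1-probability (default 0.5).
#' @param flip_noise Observation bitflip probability (default 0).
#' @param low_mean,high_mean,spread Emission parameters (defaults 6 / 10 /
#'   0.25).
#' @param n_constant_aged Number of genes forced to a constant-0 function in
#'   the aged ground-truth network (default 0), mimicking genes whose
#'   expression drops below threshold in the aged phenotype.
#' @param seed Integer master seed.
#' @return Object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_genes = 22L, n_binarizable = 22L,
                                 timepoints_young = 7L, timepoints_aged = 8L,
                                 in_degree = 2L, bias = 0.5, flip_noise = 0,
                                 low_mean = 6, high_mean = 10, spread = 0.25,
                                 n_constant_aged = 0L, seed = 1L) {
  if (n_binarizable > n_genes) stop("n_binarizable > n_genes", call. = FALSE)
  if (n_constant_aged > n_binarizable) {
    stop("n_constant_aged > n_binarizable", call. = FALSE)
  }
  if (flip_noise < 0 || flip_noise > 1) stop("flip_noise must be in [0, 1]", call. = FALSE)
  if (high_mean <= low_mean) stop("high_mean must exceed low_mean", call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes), n_binarizable = as.integer(n_binarizable),
         timepoints_young = as.integer(timepoints_young),
         timepoints_aged = as.integer(timepoints_aged),
         in_degree = as.integer(in_degree), bias = bias,
         flip_noise = flip_noise, low_mean = low_mean, high_mean = high_mean,
         spread = spread, n_constant_aged = as.integer(n_constant_aged),
         seed = as.integer(seed)),
    class = "synthetic_study_spec"
  )
}

#' Generate a full synthetic two-group study
#'
#' Draws one ground-truth network per group (constant truth tables excluded
#' so every driven gene can vary), simulates the two binary series, emits
#' real-valued expression, and returns the ground truth for recovery tests.
#' Initial states (and, every few tries, the networks) are redrawn until
#' every driven, non-planted gene varies within each group's observed
#' window, so that binarization and per-group reconstruction are
#' well-posed; the search is deterministic given the spec seed.
#'
#' @param spec A `synthetic_study_spec`.
#' @return Object of class `synthetic_study`: `expression` (n_genes x
#'   (timepoints_young + timepoints_aged) matrix), `groups` (per-column
#'   labels, young then aged), and `truth` (ground-truth networks, binary
#'   series, planted constant genes, binarizable gene ids).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed)
  nb <- spec$n_binarizable
  ids <- sprintf("g%02d", seq_len(spec$n_genes))
  const_idx <- integer(0)
  net_y <- net_a <- NULL
  bin_y <- bin_a <- NULL
  found <- FALSE
  for (try in seq_len(200L)) {
    if (try %% 5L == 1L) { # fresh networks every 5th attempt
      net_y <- random_network(nb, spec$in_degree, spec$bias,
                              exclude_constant = TRUE, gene_ids = ids[seq_len(nb)])
      if (spec$n_constant_aged > 0L) {
        # planted silent genes are unregulated and unconnected: the live
        # part of the aged network is wired among the remaining genes only,
        # so no regulated gene can freeze through a silent input
        const_idx <- sort(sample.int(nb, spec$n_constant_aged))
        live <- setdiff(seq_len(nb), const_idx)
        sub <- random_network(length(live), spec$in_degree, spec$bias,
                              exclude_constant = TRUE)
        functions <- vector("list", nb)
        for (j in seq_along(live)) {
          f <- sub$functions[[j]]
          f$inputs <- live[f$inputs]
          functions[[live[j]]] <- f
        }
        for (g in const_idx) functions[[g]] <- new_bn_function(integer(0), 0L)
        net_a <- boolean_network(functions, ids[seq_len(nb)])
      } else {
        net_a <- random_network(nb, spec$in_degree, spec$bias,
                                exclude_constant = TRUE,
                                gene_ids = ids[seq_len(nb)])
      }
    }
    x0_y <- sample(c(0L, 1L), nb, replace = TRUE)
    x0_a <- sample(c(0L, 1L), nb, replace = TRUE)
    if (length(const_idx) > 0L) x0_a[const_idx] <- 0L
    bin_y <- generate_binary_series(net_y, spec$timepoints_young, x0_y,
                                    spec$flip_noise)
    bin_a <- generate_binary_series(net_a, spec$timepoints_aged, x0_a,
                                    spec$flip_noise)
    vary_y <- apply(bin_y, 1, function(r) length(unique(r)) > 1L)
    vary_a <- apply(bin_a, 1, function(r) length(unique(r)) > 1L)
    free <- setdiff(seq_len(nb), const_idx)
    if (all(vary_y[free]) && all(vary_a[free]) && all(vary_y[const_idx])) {
      found <- TRUE
      break
    }
  }
  if (!found) {
    stop("could not generate a study in which every driven gene varies; ",
         "try another seed or shorter in-degree", call. = FALSE)
  }
  binary <- cbind(bin_y, bin_a)
  expr_driven <- generate_expression(binary, spec$low_mean, spec$high_mean,
                                     spec$spread)
  expr <- expr_driven
  if (spec$n_genes > nb) {
    n_extra <- spec$n_genes - nb
    m <- ncol(binary)
    extra <- matrix(
      pmax(stats::rnorm(n_extra * m, mean = (spec$low_mean + spec$high_mean) / 2,
                        sd = max(spec$spread, 0.25)), 1e-3),
      nrow = n_extra
    )
    expr <- rbind(expr_driven, extra)
  }
  dimnames(expr) <- list(ids, sprintf("s%02d", seq_len(ncol(binary))))
  groups <- rep(c("young", "aged"), c(spec$timepoints_young, spec$timepoints_aged))
  structure(
    list(
      expression = expr,
      groups = groups,
      truth = list(
        network_young = net_y, network_aged = net_a,
        binary_young = bin_y, binary_aged = bin_a,
        binarizable = ids[seq_len(nb)],
        constant_aged = ids[const_idx]
      ),
      spec = spec
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic two-group study:", nrow(x$expression), "genes,",
      sum(x$groups == "young"), "young +", sum(x$groups == "aged"),
      "aged timepoints\n")
  cat("  driven genes:", length(x$truth$binarizable),
      " planted aged constants:", length(x$truth$constant_aged), "\n")
  invisible(x)
}

#' Planted fragile / robust candidate function sets
#'
#' Deterministic function sets with a known stability ordering, used to
#' check that the perturbation protocol discriminates. In the fragile set
#' every gene's candidates copy one of the first `n_hubs` hub genes, so a
#' flip of a hub spreads to many nodes; in the robust set every gene's
#' candidates are the two constants and the self-copy, so damage is erased
#' or at worst retained in place.
#'
#' @param n Number of genes.
#' @param n_hubs Number of hub genes in the fragile set (default 3).
#' @return A `bn_function_set`.
#' @export
fragile_function_set <- function(n, n_hubs = 3L) {
  stopifnot(n >= n_hubs, n_hubs >= 1L)
  ids <- sprintf("g%02d", seq_len(n))
  functions <- lapply(seq_len(n), function(g) {
    lapply(seq_len(n_hubs), function(h) new_bn_function(h, c(0L, 1L)))
  })
  structure(
    list(gene_ids = ids, functions = functions,
         errors = stats::setNames(rep(NA_real_, n), ids),
         dependencies = dependencies_of(functions, ids)),
    class = "bn_function_set"
  )
}

#' @rdname fragile_function_set
#' @export
robust_function_set <- function(n) {
  stopifnot(n >= 1L)
  ids <- sprintf("g%02d", seq_len(n))
  functions <- lapply(seq_len(n), function(g) {
    list(new_bn_function(integer(0), 0L),
         new_bn_function(integer(0), 1L),
         new_bn_function(g, c(0L, 1L)))
  })
  structure(
    list(gene_ids = ids, functions = functions,
         errors = stats::setNames(rep(NA_real_, n), ids),
         dependencies = dependencies_of(functions, ids)),
    class = "bn_function_set"
  )
}
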