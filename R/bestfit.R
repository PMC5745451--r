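# Best-fit inference of Boolean functions from binarized time series.
#
# For every gene the algorithm searches all input sets of size 0..max_k for
# the sets explaining the gene's next-state values with minimal error
# (partially defined Boolean functions; error counts misclassified
# transition pairs with multiplicity), then enumerates every Boolean
# function consistent with the observed patterns of each minimal set.

#' Consecutive transition pairs of a binarized time series
#'
#' Extracts all pairs (x(t), x(t+1)) from a genes-by-timepoints 0/1 matrix.
#' When `groups` is given, pairs never span a group boundary: only
#' consecutive columns with the same group label form a pair.
#'
#' @param binary Genes x timepoints 0/1 matrix (rownames = gene ids).
#' @param groups Optional per-column group labels.
#' @return Object of class `bn_transitions` with `states0` and `states1`
#'   (pairs x genes matrices: network state at t and t+1) and `gene_ids`.
#' @export
transition_pairs <- function(binary, groups = NULL) {
  if (!is.matrix(binary) || ncol(binary) < 2L) {
    stop("need a matrix with at least 2 timepoints", call. = FALSE)
  }
  if (!all(binary %in% c(0L, 1L))) stop("matrix must be 0/1", call. = FALSE)
  m <- ncol(binary)
  keep <- if (is.null(groups)) {
    rep(TRUE, m - 1L)
  } else {
    if (length(groups) != m) stop("groups must match columns", call. = FALSE)
    groups[-m] == groups[-1L]
  }
  if (!any(keep)) stop("no within-group transition pair", call. = FALSE)
  states <- t(binary)
  structure(
    list(
      states0 = states[-m, , drop = FALSE][keep, , drop = FALSE],
      states1 = states[-1L, , drop = FALSE][keep, , drop = FALSE],
      gene_ids = rownames(binary) %||% paste0("g", seq_len(nrow(binary)))
    ),
    class = "bn_transitions"
  )
}

#' @export
print.bn_transitions <- function(x, ...) {
  cat("Transition pairs:", nrow(x$states0), "pairs over",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

# Error of a pattern/label multiset: any Boolean function must commit to one
# output per pattern, so the minimal number of misclassified pairs is
# sum over patterns of min(#true, #false).
pdbf_error <- function(patterns, labels, size) {
  cT <- tabulate(patterns[labels == 1L], nbins = size)
  cF <- tabulate(patterns[labels == 0L], nbins = size)
  sum(pmin(cT, cF))
}

#' Build a partially defined Boolean function for one target gene
#'
#' Collects, over all transition pairs, the input patterns of `input_set` at
#' time t labelled by the target's value at t+1 (the true/false example
#' multisets), and computes the error: the number of pairs any single
#' Boolean function must misclassify, i.e. the sum over conflicting patterns
#' of the minority count. With all pattern counts equal to one this reduces
#' to the number of patterns occurring as both a true and a false example.
#'
#' @param pairs A `bn_transitions` object.
#' @param target Gene index (column) of the regulated gene.
#' @param input_set Ordered distinct gene indices (possibly empty).
#' @return Object of class `bn_pdbf`: `target`, `inputs`, `patterns`
#'   (1-based truth-table row per pair, inputs\[1\] = most significant bit),
#'   `labels`, `error`.
#' @export
build_pdbf <- function(pairs, target, input_set) {
  stopifnot(inherits(pairs, "bn_transitions"))
  input_set <- as.integer(input_set)
  if (anyDuplicated(input_set)) {
    stop("input_set must not contain duplicates", call. = FALSE)
  }
  k <- length(input_set)
  m <- nrow(pairs$states0)
  patterns <- if (k == 0L) {
    rep(1L, m)
  } else {
    as.integer(pairs$states0[, input_set, drop = FALSE] %*% bit_weights(k) + 1)
  }
  labels <- as.integer(pairs$states1[, target])
  structure(
    list(
      target = as.integer(target),
      inputs = input_set,
      patterns = patterns,
      labels = labels,
      error = pdbf_error(patterns, labels, 2^k)
    ),
    class = "bn_pdbf"
  )
}

#' Minimal-error input sets for one target gene
#'
#' Examines every input set of size 0..`max_k` and returns all sets
#' achieving the globally minimal error, restricted to the smallest
#' cardinality at which that error is achieved (supersets of a zero-error
#' set are thereby never returned).
#'
#' @inheritParams build_pdbf
#' @param max_k Maximal input-set size (clamped to the gene count with a
#'   warning).
#' @return List with `error` (minimal error), `k` (cardinality) and
#'   `input_sets` (list of integer vectors).
#' @export
best_fit_inputs <- function(pairs, target, max_k = 5L) {
  stopifnot(inherits(pairs, "bn_transitions"))
  n <- length(pairs$gene_ids)
  if (max_k < 0L) stop("max_k must be >= 0", call. = FALSE)
  if (max_k > n) {
    warning("max_k exceeds the gene count; clamped to ", n)
    max_k <- n
  }
  labels <- as.integer(pairs$states1[, target])
  best <- list(error = Inf, k = NA_integer_, input_sets = list())
  for (k in 0:max_k) {
    sets <- utils::combn(n, k, simplify = FALSE)
    errs <- vapply(sets, function(s) {
      patterns <- if (k == 0L) {
        rep(1L, length(labels))
      } else {
        as.integer(pairs$states0[, s, drop = FALSE] %*% bit_weights(k) + 1)
      }
      pdbf_error(patterns, labels, 2^k)
    }, numeric(1))
    mn <- min(errs)
    if (mn < best$error) {
      best <- list(error = mn, k = k, input_sets = sets[errs == mn])
    }
    if (best$error == 0) break # smaller cardinality always preferred
  }
  best
}

new_bn_function <- function(inputs, table) {
  list(inputs = as.integer(inputs), table = as.integer(table))
}

function_key <- function(f) {
  paste(paste(f$inputs, collapse = ","),
        paste(ifelse(is.na(f$table), "?", f$table), collapse = ""),
        sep = ";")
}

#' Enumerate Boolean functions consistent with a pdBf
#'
#' Fills the 2^k truth table from the observed examples: a pattern seen only
#' as a true (false) example becomes 1 (0); a conflicting pattern is
#' resolved to its majority label (tie -> 0); unobserved patterns stay
#' undefined (don't-care, stored as `NA`). All completions of the undefined
#' entries are returned while their number is at most `expansion_cap`;
#' beyond the cap, the canonical completion (all don't-cares -> 0) plus the
#' don't-care template itself are returned, and the template's undefined
#' bits are instantiated uniformly at network-sampling time.
#'
#' @param pdbf A `bn_pdbf`.
#' @param expansion_cap Maximal number of completions to enumerate
#'   (default 2^10).
#' @return List of Boolean functions, each a list with `inputs` (ordered
#'   gene indices, inputs\[1\] = most significant truth-table bit) and
#'   `table` (2^k entries in \{0, 1, NA\}).
#' @export
enumerate_functions <- function(pdbf, expansion_cap = 1024L) {
  stopifnot(inherits(pdbf, "bn_pdbf"))
  k <- length(pdbf$inputs)
  size <- 2^k
  cT <- tabulate(pdbf$patterns[pdbf$labels == 1L], nbins = size)
  cF <- tabulate(pdbf$patterns[pdbf$labels == 0L], nbins = size)
  seen <- (cT + cF) > 0L
  template <- ifelse(seen, as.integer(cT > cF), NA_integer_)
  free <- which(is.na(template))
  if (length(free) == 0L) {
    return(list(new_bn_function(pdbf$inputs, template)))
  }
  if (2^length(free) <= expansion_cap) {
    grid <- as.matrix(expand.grid(rep(list(0:1), length(free)),
                                  KEEP.OUT.ATTRS = FALSE))
    lapply(seq_len(nrow(grid)), function(i) {
      tab <- template
      tab[free] <- grid[i, ]
      new_bn_function(pdbf$inputs, tab)
    })
  } else {
    canonical <- template
    canonical[free] <- 0L
    list(new_bn_function(pdbf$inputs, canonical),
         new_bn_function(pdbf$inputs, template))
  }
}

#' Reconstruct candidate Boolean functions for every gene
#'
#' Runs the best-fit search per gene over one group's binarized series,
#' enumerates consistent functions for every minimal input set, and
#' deduplicates. The result is a probabilistic-network-style function set:
#' each gene carries >= 1 candidate, all with equal weight.
#'
#' @param binary Genes x timepoints 0/1 matrix (one group's series), or a
#'   `bn_transitions` object.
#' @param max_k Maximal input-set size (default 5).
#' @param expansion_cap Passed to [enumerate_functions()].
#' @return Object of class `bn_function_set`: `gene_ids`, `functions`
#'   (per-gene list of candidates), `errors` (minimal error per gene),
#'   `dependencies` (data.frame of regulator/target gene-id pairs, the union
#'   over candidates of their inputs).
#' @export
reconstruct <- function(binary, max_k = 5L, expansion_cap = 1024L) {
  pairs <- if (inherits(binary, "bn_transitions")) binary else transition_pairs(binary)
  n <- length(pairs$gene_ids)
  functions <- vector("list", n)
  errors <- numeric(n)
  for (g in seq_len(n)) {
    bf <- best_fit_inputs(pairs, g, max_k)
    errors[g] <- bf$error
    cands <- list()
    for (s in bf$input_sets) {
      cands <- c(cands, enumerate_functions(build_pdbf(pairs, g, s),
                                            expansion_cap))
    }
    keys <- vapply(cands, function_key, character(1))
    functions[[g]] <- cands[!duplicated(keys)]
  }
  deps <- do.call(rbind, lapply(seq_len(n), function(g) {
    regs <- sort(unique(unlist(lapply(functions[[g]], `[[`, "inputs"))))
    if (length(regs) == 0L) return(NULL)
    data.frame(regulator = pairs$gene_ids[regs],
               target = pairs$gene_ids[g],
               stringsAsFactors = FALSE)
  }))
  if (is.null(deps)) {
    deps <- data.frame(regulator = character(0), target = character(0))
  }
  structure(
    list(gene_ids = pairs$gene_ids, functions = functions,
         errors = stats::setNames(errors, pairs$gene_ids),
         dependencies = deps),
    class = "bn_function_set"
  )
}

#' Number of candidate functions per gene
#' @param fs A `bn_function_set`.
#' @return Named integer vector.
#' @export
function_counts <- function(fs) {
  stopifnot(inherits(fs, "bn_function_set"))
  stats::setNames(lengths(fs$functions), fs$gene_ids)
}

#' Mean number of inputs per candidate function
#'
#' Arithmetic mean of the input-set size over all candidate functions of all
#' genes; constant functions count zero inputs.
#'
#' @param fs A `bn_function_set`.
#' @return A single number.
#' @export
mean_inputs_per_function <- function(fs) {
  stopifnot(inherits(fs, "bn_function_set"))
  sizes <- unlist(lapply(fs$functions, function(cands) {
    vapply(cands, function(f) length(f$inputs), numeric(1))
  }))
  if (length(sizes) == 0L) stop("empty function set", call. = FALSE)
  mean(sizes)
}

#' @export
print.bn_function_set <- function(x, ...) {
  cnt <- function_counts(x)
  cat("Boolean function set:", length(x$gene_ids), "genes\n")
  cat("  candidate functions per gene: min", min(cnt), " mean",
      round(mean(cnt), 2), " max", max(cnt), "\n")
  cat("  mean inputs per function:",
      round(mean_inputs_per_function(x), 3), "\n")
  cat("  dependencies:", nrow(x$dependencies),
      " genes with error 0:", sum(x$errors == 0), "\n")
  invisible(x)
}
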