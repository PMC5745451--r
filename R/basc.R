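# Step-function binarization (BASC A style).
#
# A real-valued series is sorted ascending; dynamic programming yields, for
# every number of discontinuities d = 1..n-2, the step function with globally
# minimal squared distance to the sorted data. Each optimal step function
# votes for its strongest discontinuity, and the binarization threshold is
# the midpoint of the two sorted values flanking the median voted rank.

# SSE of every contiguous segment of the sorted vector `s`:
# C[i, j] = sum over s[i..j] of (s - segment mean)^2.
segment_cost_matrix <- function(s) {
  n <- length(s)
  cs <- c(0, cumsum(s))
  cs2 <- c(0, cumsum(s^2))
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i:n
    len <- j - i + 1
    C[i, j] <- (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / len
  }
  C[C < 0] <- 0 # guard against negative rounding residue
  C
}

new_basc_step <- function(breaks, levels, sse, n) {
  structure(
    list(breaks = as.integer(breaks), levels = as.numeric(levels),
         sse = as.numeric(sse), n = as.integer(n)),
    class = "basc_step"
  )
}

#' Initial step function of a sorted series
#'
#' Rearranges the input values in ascending order; the resulting step
#' function has one step per value (`n - 1` discontinuities) and zero
#' squared error, and is the starting point for the dynamic-programming
#' search over coarser step functions.
#'
#' @param values Numeric vector (length >= 2, finite).
#' @return An object of class `basc_step` with fields `breaks` (positions in
#'   the sorted order after which a discontinuity occurs), `levels` (segment
#'   means), `sse` and `n`.
#' @seealso [optimal_step_functions()], [binarize_gene()]
#' @export
#' @examples
#' initial_step_function(c(3, 1, 2))
initial_step_function <- function(values) {
  assert_finite_numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  s <- sort(values)
  new_basc_step(seq_len(n - 1L), s, 0, n)
}

#' Optimal step functions with d = 1..n-2 discontinuities
#'
#' For each number of discontinuities `d`, computes by dynamic programming
#' the step function over the sorted values whose sum of squared deviations
#' from the data is globally minimal among all placements of `d` breaks.
#' Segment levels are the arithmetic means of their segment's sorted values.
#'
#' @param values Numeric vector (length >= 3, finite).
#' @return List of `basc_step` objects, element `d` having exactly `d`
#'   breaks, ordered by increasing `d`.
#' @export
#' @examples
#' optimal_step_functions(c(1, 2, 10, 11))[[1]]
optimal_step_functions <- function(values) {
  assert_finite_numeric(values)
  n <- length(values)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  s <- sort(values)
  C <- segment_cost_matrix(s)
  dp_step_functions(s, C)
}

# Core DP shared with the fast bootstrap path. `s` sorted, `C` its cost
# matrix. Returns the list of basc_step objects for d = 1..n-2.
dp_step_functions <- function(s, C) {
  n <- length(s)
  max_seg <- n - 1L # up to n-2 breaks
  # E[m, j]: minimal SSE of partitioning s[1..j] into m segments.
  E <- matrix(Inf, max_seg, n)
  P <- matrix(0L, max_seg, n) # argmin position of the last break
  E[1, ] <- C[1, ]
  if (max_seg >= 2L) {
    for (m in 2:max_seg) {
      for (j in m:n) {
        i <- (m - 1L):(j - 1L)
        cand <- E[m - 1L, i] + C[cbind(i + 1L, j)]
        w <- which.min(cand)
        E[m, j] <- cand[w]
        P[m, j] <- i[w]
      }
    }
  }
  cs <- c(0, cumsum(s))
  lapply(seq_len(n - 2L), function(d) {
    m <- d + 1L
    breaks <- integer(d)
    j <- n
    for (mm in m:2) {
      breaks[mm - 1L] <- P[mm, j]
      j <- breaks[mm - 1L]
    }
    bounds <- c(0L, breaks, n)
    levels <- (cs[bounds[-1] + 1L] - cs[bounds[-length(bounds)] + 1L]) /
      diff(bounds)
    new_basc_step(breaks, levels, E[m, n], n)
  })
}

# Score every break of a step function: jump height divided by the SSE of
# the best two-segment approximation splitting the full sorted vector at
# that break (plus machine epsilon). Larger = stronger discontinuity.
break_scores <- function(step, C) {
  n <- step$n
  b <- step$breaks
  h <- diff(step$levels)
  e <- C[cbind(1L, b)] + C[cbind(b + 1L, n)]
  h / (e + .Machine$double.eps)
}

#' Strongest discontinuity of a step function
#'
#' Scores each discontinuity by its jump height (difference of adjacent
#' segment levels) divided by the squared error of the two-segment
#' approximation that splits the full sorted vector at that break (plus
#' machine epsilon), and returns the break with the largest score. Ties go
#' to the lowest break position.
#'
#' @param step A `basc_step` with at least one break.
#' @param sorted_values The ascending-sorted value vector the step function
#'   was fitted to.
#' @return List with `break_index` (position in the sorted order after which
#'   the discontinuity occurs), `jump` (height) and `score`.
#' @export
strongest_discontinuity <- function(step, sorted_values) {
  if (!inherits(step, "basc_step")) stop("step must be a basc_step", call. = FALSE)
  if (length(step$breaks) < 1L) {
    stop("step function has no breaks", call. = FALSE)
  }
  if (length(sorted_values) != step$n || is.unsorted(sorted_values)) {
    stop("sorted_values must be the ascending sorted data of length n", call. = FALSE)
  }
  C <- segment_cost_matrix(sorted_values)
  sc <- break_scores(step, C)
  w <- which.max(sc) # first maximum = lowest break index on ties
  list(break_index = step$breaks[w], jump = diff(step$levels)[w], score = sc[w])
}

# Threshold location for one series. Returns the voted sorted rank r, the
# threshold (midpoint of sorted values r, r+1) and the normalized jump
# statistic used by the bootstrap test.
basc_threshold <- function(values) {
  n <- length(values)
  s <- sort(values)
  C <- segment_cost_matrix(s)
  steps <- dp_step_functions(s, C)
  votes <- vapply(steps, function(st) {
    sc <- break_scores(st, C)
    st$breaks[which.max(sc)]
  }, integer(1))
  # lower median keeps the rank attained for an even number of votes
  r <- as.integer(floor(stats::median(votes)))
  list(
    rank = r,
    threshold = (s[r] + s[r + 1L]) / 2,
    statistic = (s[r + 1L] - s[r]) / (s[n] - s[1L]),
    votes = votes
  )
}

no_threshold_error <- function(msg) {
  structure(
    class = c("bn_no_threshold", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Binarize one gene's expression series
#'
#' Places a shared threshold at the strongest discontinuity voted across all
#' optimal step functions (median of the per-d strongest-break sorted ranks;
#' midpoint of the two flanking sorted values) and tests significance with a
#' seeded bootstrap: the statistic is the threshold jump divided by the value
#' range, and the null distribution is obtained from `n_bootstrap` samples of
#' n values uniform on the observed \[min, max\]. The bootstrap test is a
#' stand-in for the original BASC significance test (see the package
#' vignette); p = (1 + #\{null >= observed\}) / (1 + n_bootstrap).
#'
#' @param values Numeric vector, length >= 3, finite; time order preserved.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param n_bootstrap Number of bootstrap null samples; default 1000.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return Object of class `bn_binarization`: `threshold`, `binary_values`
#'   (0/1 in original sample order, 1 iff value > threshold), `p_value`,
#'   `significant`.
#' @export
#' @examples
#' binarize_gene(c(1, 1, 2, 10, 10, 11), seed = 1)
binarize_gene <- function(values, alpha = 0.05, n_bootstrap = 1000L,
                          seed = NULL) {
  assert_finite_numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop(no_threshold_error("constant series has no binarization threshold"))
  }
  set_seed_if(seed)
  obs <- basc_threshold(values)
  n <- length(values)
  null_stats <- vapply(seq_len(n_bootstrap), function(b) {
    basc_threshold(stats::runif(n, rng[1], rng[2]))$statistic
  }, numeric(1))
  p <- (1 + sum(null_stats >= obs$statistic)) / (1 + n_bootstrap)
  structure(
    list(
      threshold = obs$threshold,
      binary_values = as.integer(values > obs$threshold),
      p_value = p,
      significant = p < alpha
    ),
    class = "bn_binarization"
  )
}

#' @export
print.bn_binarization <- function(x, ...) {
  cat("Binarization: threshold", format(x$threshold),
      " p =", format(x$p_value),
      if (x$significant) "(significant)" else "(not significant)", "\n")
  cat("  ", paste(x$binary_values, collapse = " "), "\n")
  invisible(x)
}

#' Binarize an expression matrix with one shared threshold per gene
#'
#' Each gene is thresholded over ALL samples pooled across groups (one
#' threshold per gene); genes whose bootstrap p-value is not below `alpha`
#' are dropped, as are constant genes (never significant, p = 1). Group
#' splitting is the caller's job and happens after binarization.
#'
#' @param x Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns in time order.
#' @inheritParams binarize_gene
#' @return Object of class `bn_binarized`: `binary` (retained genes x
#'   samples 0/1 matrix), `thresholds`, `p_values`, `retained` (logical per
#'   gene), `alpha`.
#' @export
binarize_matrix <- function(x, alpha = 0.05, n_bootstrap = 1000L,
                            seed = NULL) {
  if (!is.matrix(x) || nrow(x) == 0L || ncol(x) == 0L) {
    stop("x must be a non-empty numeric matrix", call. = FALSE)
  }
  ids <- rownames(x) %||% paste0("g", seq_len(nrow(x)))
  set_seed_if(seed)
  gene_seeds <- draw_seeds(nrow(x))
  thresholds <- rep(NA_real_, nrow(x))
  p_values <- rep(1, nrow(x))
  binary <- matrix(NA_integer_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (g in seq_len(nrow(x))) {
    res <- tryCatch(
      binarize_gene(x[g, ], alpha, n_bootstrap, seed = gene_seeds[g]),
      bn_no_threshold = function(e) NULL
    )
    if (!is.null(res)) {
      thresholds[g] <- res$threshold
      p_values[g] <- res$p_value
      binary[g, ] <- res$binary_values
    }
  }
  retained <- p_values < alpha
  structure(
    list(
      gene_ids = ids,
      binary = binary[retained, , drop = FALSE],
      thresholds = stats::setNames(thresholds, ids),
      p_values = stats::setNames(p_values, ids),
      retained = stats::setNames(retained, ids),
      alpha = alpha
    ),
    class = "bn_binarized"
  )
}

#' @export
print.bn_binarized <- function(x, ...) {
  cat("Binarized expression matrix\n")
  cat("  genes:", length(x$gene_ids),
      " retained (p <", x$alpha, "):", sum(x$retained), "\n")
  cat("  samples:", ncol(x$binary), "\n")
  invisible(x)
}
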