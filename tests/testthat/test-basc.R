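# Step-function binarization: DP optimality, threshold placement,
# bootstrap significance.

test_that("the initial step function is the sorted data with zero error", {
  s <- initial_step_function(c(3, 1, 2))
  expect_equal(s$breaks, c(1L, 2L))
  expect_equal(s$levels, c(1, 2, 3))
  expect_equal(s$sse, 0)

  s <- initial_step_function(c(5, 5, 5))
  expect_equal(s$levels, c(5, 5, 5))
  expect_equal(s$sse, 0)

  s <- initial_step_function(c(10, 1))
  expect_equal(s$levels, c(1, 10))

  expect_error(initial_step_function(7), "at least 2")
  expect_error(initial_step_function(c(1, NA, 3)), "finite")
  expect_error(initial_step_function(c(1, Inf, 3)), "finite")
})

test_that("optimal step functions reproduce hand-derived single-break fits", {
  st <- optimal_step_functions(c(1, 2, 10, 11))[[1]]
  expect_equal(st$breaks, 2L)
  expect_equal(st$levels, c(1.5, 10.5))
  expect_equal(st$sse, 1.0)

  st <- optimal_step_functions(c(1, 1, 1, 9))[[1]]
  expect_equal(st$breaks, 3L)
  expect_equal(st$levels, c(1, 9))
  expect_equal(st$sse, 0)

  # monotone arithmetic sequence: symmetric problem, optimum ties with its
  # mirror; the achieved sse must equal the exhaustive minimum
  st <- optimal_step_functions(1:6)[[1]]
  expect_equal(st$sse, oracle_step_sse(1:6, 1))
  expect_equal(st$breaks, 3L)
  expect_equal(st$levels, c(2, 5))

  expect_error(optimal_step_functions(c(1, 2)), "at least 3")
})

test_that("DP step functions match exhaustive search for random data", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(3:10, 1)
    values <- round(stats::rnorm(n, sd = 3), 2)
    steps <- optimal_step_functions(values)
    expect_length(steps, n - 2)
    sses <- vapply(steps, `[[`, numeric(1), "sse")
    for (d in seq_len(n - 2)) {
      expect_equal(steps[[d]]$sse, oracle_step_sse(values, d),
                   tolerance = 1e-10)
      expect_length(steps[[d]]$breaks, d)
      # levels are strictly the segment means of the sorted data
      s <- sort(values)
      bounds <- c(0, steps[[d]]$breaks, n)
      means <- vapply(seq_len(d + 1), function(j) {
        mean(s[(bounds[j] + 1):bounds[j + 1]])
      }, numeric(1))
      expect_equal(steps[[d]]$levels, means)
    }
    # sse non-increasing in d, and zero at d = n - 1 (initial step function)
    expect_true(all(diff(sses) <= 1e-12))
    expect_equal(initial_step_function(values)$sse, 0)
  }
})

test_that("the strongest discontinuity is the dominant jump, ties to the lowest break", {
  s <- sort(c(1, 2, 10, 11))
  st <- optimal_step_functions(c(1, 2, 10, 11))[[1]]
  res <- strongest_discontinuity(st, s)
  expect_equal(res$break_index, 2L)
  expect_equal(res$jump, 9)

  # jumps {1, 8}: the jump-8 break wins under the jump/error score
  v <- c(1, 2, 10)
  st2 <- optimal_step_functions(v)  # d = 1 only for n = 3; use initial for 2 breaks
  init <- initial_step_function(v)
  res2 <- strongest_discontinuity(init, sort(v))
  expect_equal(res2$break_index, 2L)
  expect_equal(res2$jump, 8)

  # equal jumps {4, 4} on symmetric data: lowest break index
  v3 <- c(1, 5, 9)
  res3 <- strongest_discontinuity(initial_step_function(v3), sort(v3))
  expect_equal(res3$break_index, 1L)

  expect_error(
    strongest_discontinuity(
      structure(list(breaks = integer(0), levels = 1, sse = 0, n = 3),
                class = "basc_step"), c(1, 2, 3)),
    "no breaks")
})

test_that("binarize_gene places the voted threshold and is deterministic", {
  b <- binarize_gene(c(1, 1, 2, 10, 10, 11), seed = 1)
  expect_equal(b$threshold, 6.0)
  expect_equal(b$binary_values, c(0L, 0L, 0L, 1L, 1L, 1L))

  expect_error(binarize_gene(c(5, 5, 5, 5)), class = "bn_no_threshold")
  expect_error(binarize_gene(c(1, 2, 3), alpha = 1.5), "alpha")

  # perfect interleaved separation must be significant
  b2 <- binarize_gene(c(0.1, 9.9, 0.2, 10.0, 0.15, 10.1),
                      n_bootstrap = 1000, seed = 2)
  expect_equal(b2$binary_values, c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_lt(b2$p_value, 0.05)

  # deterministic for a fixed seed
  b3 <- binarize_gene(c(0.1, 9.9, 0.2, 10.0, 0.15, 10.1),
                      n_bootstrap = 200, seed = 9)
  b4 <- binarize_gene(c(0.1, 9.9, 0.2, 10.0, 0.15, 10.1),
                      n_bootstrap = 200, seed = 9)
  expect_identical(b3, b4)
  expect_gte(b3$p_value, 0)
  expect_lte(b3$p_value, 1)
})

test_that("binarization depends only on the value multiset and is affine-equivariant", {
  set.seed(7)
  for (rep in 1:5) {
    v <- stats::rnorm(9, sd = 2)
    b <- binarize_gene(v, n_bootstrap = 100, seed = 3)
    # permutation: same threshold, binary values permuted alike
    perm <- sample(length(v))
    bp <- binarize_gene(v[perm], n_bootstrap = 100, seed = 3)
    expect_equal(bp$threshold, b$threshold)
    expect_equal(bp$binary_values, b$binary_values[perm])
    # strictly increasing affine transform: binary output unchanged
    a <- stats::runif(1, 0.5, 3)
    c0 <- stats::runif(1, -5, 5)
    ba <- binarize_gene(a * v + c0, n_bootstrap = 100, seed = 3)
    expect_equal(ba$binary_values, b$binary_values)
    expect_equal(ba$threshold, a * b$threshold + c0, tolerance = 1e-8)
  }
})

test_that("binarize_matrix pools samples, drops constants and is reproducible", {
  m <- rbind(
    g1 = c(1, 1, 2, 10, 10, 11),
    g2 = c(0.1, 9.9, 0.2, 10.0, 0.15, 10.1),
    g3 = c(5, 5, 5, 5, 5, 5)
  )
  res <- binarize_matrix(m, n_bootstrap = 300, seed = 4)
  expect_equal(sum(res$retained), 2)
  expect_false(res$retained[["g3"]])
  expect_equal(res$p_values[["g3"]], 1)
  expect_true(is.na(res$thresholds[["g3"]]))
  expect_equal(rownames(res$binary), c("g1", "g2"))

  res2 <- binarize_matrix(m, n_bootstrap = 300, seed = 4)
  expect_identical(res, res2)

  expect_error(binarize_matrix(matrix(numeric(0), 0, 0)), "non-empty")
})
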