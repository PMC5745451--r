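# Best-fit inference: pdBf construction, minimal-error input search,
# consistent-function enumeration.

test_that("transition pairs are consecutive and never cross a group boundary", {
  bm <- matrix(sample(c(0L, 1L), 3 * 7, replace = TRUE), 3,
               dimnames = list(paste0("g", 1:3), NULL))
  tp <- transition_pairs(bm)
  expect_equal(nrow(tp$states0), 6)
  expect_equal(tp$states0[2, ], bm[, 2])
  expect_equal(tp$states1[2, ], bm[, 3])

  bm2 <- bm[, 1:2]
  expect_equal(nrow(transition_pairs(bm2)$states0), 1)
  expect_error(transition_pairs(bm[, 1, drop = FALSE]), "2 timepoints")

  # young and aged concatenated: no pair spans the boundary
  groups <- rep(c("young", "aged"), c(4, 3))
  tpg <- transition_pairs(bm, groups)
  expect_equal(nrow(tpg$states0), 5)
  expect_equal(tpg$states0[4, ], bm[, 5]) # first aged pair starts at col 5
})

test_that("pdBf collects true/false examples and counts conflicts with multiplicity", {
  # series: x(t) = (0,1), (1,1), (1,0), (0,0)
  bm <- rbind(g1 = c(0L, 1L, 1L, 0L), g2 = c(1L, 1L, 0L, 0L))
  tp <- transition_pairs(bm)
  pd <- build_pdbf(tp, target = 1L, input_set = c(1L, 2L))
  # patterns 01, 11, 10 labelled 1, 1, 0: no conflict
  expect_equal(pd$patterns, c(2L, 4L, 3L))
  expect_equal(pd$labels, c(1L, 1L, 0L))
  expect_equal(pd$error, 0)
  expect_equal(oracle_min_error(tp, 1L, 2L), 0)

  # pairs (1 -> 1), (1 -> 0), (0 -> 0) on a single input: one conflict
  bm2 <- rbind(g1 = c(1L, 1L, 0L, 0L))
  pd2 <- build_pdbf(transition_pairs(bm2), 1L, 1L)
  expect_equal(pd2$error, 1)
  expect_equal(oracle_min_error(transition_pairs(bm2), 1L, 1L), 1)

  # empty pair list: error 0, no examples
  tp0 <- make_transitions(matrix(integer(0), 0, 2), matrix(integer(0), 0, 2),
                          c("g1", "g2"))
  pd0 <- build_pdbf(tp0, 1L, 1L)
  expect_equal(pd0$error, 0)
  expect_length(pd0$patterns, 0)

  expect_error(build_pdbf(tp, 1L, c(1L, 1L)), "duplicates")
})

test_that("best-fit keeps only the smallest input sets achieving the minimal error", {
  set.seed(11)
  target_vals <- c(0L, 1L, 1L, 0L, 1L)
  bm <- rbind(g1 = sample(c(0L, 1L), 6, replace = TRUE),
              g2 = c(9L, target_vals) * 0L, # placeholder, overwritten below
              g3 = sample(c(0L, 1L), 6, replace = TRUE))
  # make gene 2 copy gene 1 with one step of delay
  bm["g2", ] <- c(0L, bm["g1", 1:5])
  tp <- transition_pairs(bm)
  bf <- best_fit_inputs(tp, target = 2L, max_k = 3L)
  expect_equal(bf$error, 0)
  expect_equal(bf$k, 1L)
  expect_true(any(vapply(bf$input_sets, identical, logical(1), 1L)))

  # constant target: the empty input set wins
  bmc <- rbind(g1 = sample(c(0L, 1L), 6, replace = TRUE),
               g2 = rep(1L, 6))
  bfc <- best_fit_inputs(transition_pairs(bmc), 2L, 2L)
  expect_equal(bfc$error, 0)
  expect_equal(bfc$k, 0L)
  expect_equal(bfc$input_sets, list(integer(0)))

  expect_warning(best_fit_inputs(tp, 1L, max_k = 10L), "clamped")
})

test_that("enumeration fills the table by majority and expands don't-cares", {
  # observed rows: 01 -> 1, 10 -> 0, 11 -> 1; row 00 undefined
  bm <- rbind(g1 = c(0L, 1L, 1L, 0L), g2 = c(1L, 1L, 0L, 0L))
  tp <- transition_pairs(bm)
  pd <- build_pdbf(tp, 1L, c(1L, 2L))
  fns <- enumerate_functions(pd)
  expect_length(fns, 2)
  tables <- lapply(fns, `[[`, "table")
  expect_true(any(vapply(tables, identical, logical(1), c(0L, 1L, 0L, 1L))))
  expect_true(any(vapply(tables, identical, logical(1), c(1L, 1L, 0L, 1L))))
  # the first completion is the projection f = x2
  expect_true(all(vapply(fns, replays_exactly, logical(1), tp, 1L)))

  # fully defined table: exactly one function
  bmf <- rbind(g1 = c(0L, 1L, 0L, 1L, 0L))
  pdf <- build_pdbf(transition_pairs(bmf), 1L, 1L)
  expect_length(enumerate_functions(pdf), 1)

  # k = 0 with only true examples: the constant-1 function
  bm1 <- rbind(g1 = c(0L, 1L, 1L, 1L))
  pd1 <- build_pdbf(transition_pairs(bm1), 1L, integer(0))
  f1 <- enumerate_functions(pd1)
  expect_length(f1, 1)
  expect_equal(f1[[1]]$table, 1L)
  expect_length(f1[[1]]$inputs, 0)

  # above the expansion cap: canonical completion plus the template
  tp_small <- make_transitions(
    matrix(c(0L, 0L, 0L), 1, 3), matrix(c(1L, 1L, 1L), 1, 3),
    c("a", "b", "c"))
  pd_cap <- build_pdbf(tp_small, 1L, c(1L, 2L, 3L))
  capped <- enumerate_functions(pd_cap, expansion_cap = 4L)
  expect_length(capped, 2)
  expect_false(anyNA(capped[[1]]$table))
  expect_equal(sum(is.na(capped[[2]]$table)), 7)
})

test_that("reconstruction finds NOT-self for an alternating gene and is reproducible", {
  bm <- matrix(c(0L, 1L, 0L, 1L), 1, dimnames = list("g1", NULL))
  fs <- reconstruct(bm, max_k = 1)
  expect_gte(length(fs$functions[[1]]), 1)
  has_not_self <- any(vapply(fs$functions[[1]], function(f) {
    identical(f$inputs, 1L) && identical(f$table, c(1L, 0L))
  }, logical(1)))
  expect_true(has_not_self)

  fs2 <- reconstruct(bm, max_k = 1)
  expect_identical(fs, fs2)
})

test_that("minimal error matches the exhaustive function-space oracle", {
  set.seed(23)
  for (rep in 1:4) {
    n <- sample(3:5, 1)
    m <- sample(5:7, 1)
    bm <- matrix(sample(c(0L, 1L), n * m, replace = TRUE), n,
                 dimnames = list(paste0("g", 1:n), NULL))
    tp <- transition_pairs(bm)
    for (target in seq_len(n)) {
      bf <- best_fit_inputs(tp, target, max_k = 3L)
      expect_equal(bf$error, oracle_min_error(tp, target, 3L))
      # zero-error candidates replay the training series exactly
      if (bf$error == 0) {
        for (s in bf$input_sets) {
          fns <- enumerate_functions(build_pdbf(tp, target, s))
          expect_true(all(vapply(fns, replays_exactly, logical(1),
                                 tp, target)))
        }
      }
    }
  }
})

test_that("true input sets are recovered from a pattern-covering XOR-ring series", {
  xs <- xor_ring_series()
  tp <- transition_pairs(xs$binary, xs$groups)
  expect_gte(nrow(unique(tp$states0)), 10)
  for (g in 1:5) {
    bf <- best_fit_inputs(tp, g, max_k = 3L)
    expect_equal(bf$error, 0)
    truth <- xs$net$functions[[g]]$inputs
    expect_true(any(vapply(bf$input_sets, identical, logical(1), truth)))
    # and the true XOR rule is among the enumerated candidates
    fns <- enumerate_functions(build_pdbf(tp, g, truth))
    expect_true(any(vapply(fns, function(f) {
      all(f$table[!is.na(f$table)] ==
            xs$net$functions[[g]]$table[!is.na(f$table)])
    }, logical(1))))
  }
})

test_that("function sets from a noise-free network replay their series without error", {
  set.seed(31)
  net <- random_network(8, 2, seed = 31, exclude_constant = TRUE)
  bm <- generate_binary_series(net, 10, seed = 32)
  fs <- reconstruct(bm, max_k = 3)
  expect_true(all(fs$errors == 0))
  expect_true(all(lengths(fs$functions) >= 1))
  tp <- transition_pairs(bm)
  for (g in seq_along(fs$functions)) {
    expect_true(all(vapply(fs$functions[[g]], function(f) {
      if (anyNA(f$table)) {
        f$table[is.na(f$table)] <- 0L # any completion of a template replays
      }
      replays_exactly(f, tp, g)
    }, logical(1))))
  }
  # dependency table mirrors the union of candidate inputs
  expect_true(all(fs$dependencies$regulator %in% rownames(bm)))
  expect_equal(mean_inputs_per_function(fs) >= 0, TRUE)
})
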