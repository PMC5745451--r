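# Ground-truth generators: random networks, noisy binary series,
# expression emission and the full two-group study.

test_that("random networks respect in-degree, bias and seeding", {
  net0 <- random_network(5, 0, seed = 1)
  expect_true(all(vapply(net0$functions, function(f) length(f$inputs) == 0,
                         logical(1))))

  expect_identical(random_network(10, 2, seed = 3),
                   random_network(10, 2, seed = 3))
  expect_error(random_network(4, 5), "between 0 and n")
  expect_error(random_network(4, 2, bias = 1.2), "bias")

  # mean truth-table density 0.5 +/- 0.05 over 100 networks (binomial bound)
  set.seed(4)
  dens <- vapply(seq_len(100), function(i) {
    net <- random_network(22, 2)
    mean(unlist(lapply(net$functions, `[[`, "table")))
  }, numeric(1))
  expect_lt(abs(mean(dens) - 0.5), 0.05)

  # excluded-constant tables always vary
  net_nc <- random_network(20, 2, seed = 6, exclude_constant = TRUE)
  expect_true(all(vapply(net_nc$functions, function(f) {
    length(unique(f$table)) > 1
  }, logical(1))))
})

test_that("binary series replay the network and flip noise acts per bit", {
  net <- random_network(8, 2, seed = 7, exclude_constant = TRUE)
  bm <- generate_binary_series(net, 9, flip_noise = 0, seed = 8)
  expect_equal(dim(bm), c(8, 9))
  # noise-free series replays exactly under the true network
  for (t in 1:8) {
    expect_equal(unname(bn_transition(net, bm[, t])), unname(bm[, t + 1]))
  }

  x0 <- rep(0L, 8)
  clean <- generate_binary_series(net, 5, x0 = x0, flip_noise = 0)
  flipped <- generate_binary_series(net, 5, x0 = x0, flip_noise = 1)
  expect_equal(unname(flipped), unname(1L - clean))

  set.seed(9)
  big <- random_network(100, 1, seed = 10)
  noisy <- generate_binary_series(big, 10, flip_noise = 0.1, seed = 11)
  ref <- generate_binary_series(big, 10, flip_noise = 0, seed = 11)
  n_flips <- sum(noisy != ref)
  expect_gt(n_flips, 100 - 30 - 1) # 1000 bits, binomial 3 sigma
  expect_lt(n_flips, 100 + 30 + 1)
})

test_that("expression emission inverts binarization when separation dominates spread", {
  bm <- matrix(sample(c(0L, 1L), 60, replace = TRUE), 6,
               dimnames = list(paste0("g", 1:6), NULL))
  # zero spread: exactly the two emission means
  e0 <- generate_expression(bm, low_mean = 2, high_mean = 8, spread = 0,
                            seed = 12)
  expect_setequal(unique(as.vector(e0)), c(2, 8))

  expect_error(generate_expression(bm, low_mean = -1, high_mean = 2),
               "positive")
  expect_error(generate_expression(bm, low_mean = 5, high_mean = 5),
               "exceed")

  # strong separation: binarization recovers the planted binary matrix and
  # flags every row significant
  bm2 <- do.call(rbind, lapply(1:5, function(i) {
    v <- sample(c(0L, 1L), 10, replace = TRUE)
    if (length(unique(v)) == 1L) v[1] <- 1L - v[1]
    v
  }))
  rownames(bm2) <- paste0("g", 1:5)
  e <- generate_expression(bm2, low_mean = 6, high_mean = 10, spread = 0.25,
                           seed = 13)
  res <- binarize_matrix(e, n_bootstrap = 300, seed = 14)
  expect_true(all(res$retained))
  expect_equal(unname(res$binary), unname(bm2))

  # zero separation cannot be achieved (high > low enforced); a spread far
  # larger than the separation makes planted rows mostly non-significant
  e_flat <- generate_expression(bm2, low_mean = 7.99, high_mean = 8.01,
                                spread = 1, seed = 15)
  res_flat <- binarize_matrix(e_flat, n_bootstrap = 300, seed = 16)
  expect_lt(mean(res_flat$retained), 0.5)
})

test_that("generated studies have the two-group shape and are bit-identical per seed", {
  spec <- synthetic_study_spec(seed = 21)
  st <- generate_study(spec)
  expect_equal(ncol(st$expression), 15)
  expect_equal(sum(st$groups == "young"), 7)
  expect_equal(sum(st$groups == "aged"), 8)
  expect_equal(nrow(st$expression), 22)
  expect_true(all(st$expression > 0))
  # every driven gene varies within each group's window
  expect_true(all(apply(st$truth$binary_young, 1, stats::var) > 0))

  st2 <- generate_study(synthetic_study_spec(seed = 21))
  expect_identical(st, st2)

  # planted constant-0 genes in the aged network stay off for all aged samples
  spec_c <- synthetic_study_spec(n_constant_aged = 4, seed = 22)
  st_c <- generate_study(spec_c)
  expect_length(st_c$truth$constant_aged, 4)
  idx <- match(st_c$truth$constant_aged, rownames(st_c$truth$binary_aged))
  expect_true(all(st_c$truth$binary_aged[idx, ] == 0L))
  # and those genes still vary in the young series (pooled binarizability)
  expect_true(all(apply(st_c$truth$binary_young[idx, ], 1, stats::var) > 0))

  # unimodal filler genes appear when n_genes > n_binarizable
  st_f <- generate_study(synthetic_study_spec(n_genes = 30, n_binarizable = 20,
                                              seed = 23))
  expect_equal(nrow(st_f$expression), 30)
  expect_length(st_f$truth$binarizable, 20)

  expect_error(synthetic_study_spec(n_binarizable = 30), "n_binarizable")
})

test_that("planted fragile and robust candidate sets have the intended wiring", {
  fr <- fragile_function_set(10, n_hubs = 3)
  expect_true(all(lengths(fr$functions) == 3))
  expect_true(all(unlist(lapply(fr$functions, function(cands) {
    vapply(cands, function(f) f$inputs <= 3, logical(1))
  }))))
  ro <- robust_function_set(10)
  expect_true(all(lengths(ro$functions) == 3))
  # robust candidates are constants or the self-copy
  for (g in seq_len(10)) {
    ks <- vapply(ro$functions[[g]], function(f) length(f$inputs), numeric(1))
    expect_equal(sort(ks), c(0, 0, 1))
    expect_equal(ro$functions[[g]][[3]]$inputs, g)
  }
})
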