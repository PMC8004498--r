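test_that("transition matrices of the partitioning processes are stochastic", {
  cfg <- generate_random_model(71, n = 3, n_demes = 2)
  Tul <- build_T_unlabelled(cfg$model$r)
  expect_equal(unname(rowSums(Tul$matrix)), rep(1, length(Tul$states)),
               tolerance = 1e-12)
  Tm <- build_T(cfg$model)
  expect_equal(unname(rowSums(Tm$matrix)), rep(1, length(Tm$states)),
               tolerance = 1e-12)
  expect_true(all(Tm$matrix >= 0))
  # transitions only refine the base partition
  for (i in seq_along(Tm$states)) {
    nz <- which(Tm$matrix[i, ] > 0)
    for (j in nz)
      expect_true(is_finer(partition_base(Tm$states[[j]]),
                           partition_base(Tm$states[[i]])))
  }
})

test_that("the product form of T equals its migration factorisation", {
  for (seed in c(81, 82)) {
    cfg <- generate_random_model(seed, n = 3, n_demes = 2)
    a <- build_T(cfg$model)
    b <- build_T_factorised(cfg$model)
    expect_identical(a$keys, b$keys)
    expect_lt(max(abs(a$matrix - b$matrix)), 1e-13)
  }
})

test_that("worked-example sojourn probabilities are exact rationals", {
  Tul <- build_T_unlabelled(fixture_two_pair_example()$model$r)
  s <- sojourn_probabilities(Tul, exact = TRUE)
  keys <- Tul$keys
  expect_true(s[match("1,2,3,4", keys)] == rational(2, 5))
  expect_true(s[match("1,2|3,4", keys)] == rational(1, 4))
  expect_true(s[match("1|2|3|4", keys)] == rational(1))
})

test_that("the recombinator vector at the one-block state is the deme measure", {
  cfg <- generate_random_model(91, n = 3, n_demes = 2)
  states <- list(max_labelled_partition(1:3, "deme1"),
                 max_labelled_partition(1:3, "deme2"))
  R <- recombinator_vector(cfg$initial, states)
  for (k in 1:2) {
    deme <- paste0("deme", k)
    expect_equal(unname(R$values[k, ]),
                 as.vector(cfg$initial$measures[[deme]]$table))
  }
})

test_that("matrix powers of T solve the nonlinear iteration", {
  cfg <- generate_random_model(101, n = 3, n_demes = 2)
  tr <- mre_iterate(cfg$initial, cfg$model, 8)
  Tm <- build_T(cfg$model)
  for (t in c(0, 1, 4, 8)) {
    lin <- solve_by_matrix_powers(cfg$initial, cfg$model, t, Tmat = Tm)
    expect_lt(meta_dist(lin, tr$states[[t + 1]]), 1e-10)
  }
})
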