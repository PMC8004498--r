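test_that("the continuous-time generator has zero row sums and refining moves", {
  cfg <- generate_random_model(151, n = 3, n_demes = 2, mode = "continuous")
  Q <- build_generator_Q(cfg$ct)
  expect_lt(max(abs(rowSums(Q$matrix))), 1e-12)
  for (i in seq_along(Q$states)) {
    nz <- setdiff(which(Q$matrix[i, ] != 0), i)
    expect_true(all(Q$matrix[i, nz] >= 0))
    for (j in nz)
      expect_true(is_finer(partition_base(Q$states[[j]]),
                           partition_base(Q$states[[i]])))
  }
})

test_that("a one-block rate is accepted but ignored", {
  space <- type_space(replicate(2, c("0", "1"), simplify = FALSE))
  N <- matrix(c(-1, 1, 2, -2), 2, byrow = TRUE)
  expect_message(
    ct <- ct_model(space, N, list(min_partition(1:2), max_partition(1:2)),
                   c(0.7, 3), demes = c("a", "b")),
    "ignored")
  expect_length(ct$rate_parts, 1L)
  expect_equal(ct$rates, 0.7)
})

test_that("matrix-exponential and ODE solvers agree", {
  cfg <- generate_random_model(5, n = 3, n_demes = 2, mode = "continuous")
  s1 <- ct_solve(cfg$initial, cfg$ct, 2.0, method = "expm")
  s2 <- ct_solve(cfg$initial, cfg$ct, 2.0, method = "ode")
  expect_lt(meta_dist(s1, s2), 1e-6)
  for (m in s1$measures) {
    expect_equal(sum(m$table), 1, tolerance = 1e-10)
    expect_true(all(m$table >= 0))
  }
  # t = 0 returns the initial state
  expect_lt(meta_dist(ct_solve(cfg$initial, cfg$ct, 0, "expm"), cfg$initial),
            1e-12)
})

test_that("zero recombination rates give the pure migration semigroup", {
  cfg <- generate_random_model(161, n = 2, n_demes = 2, mode = "continuous")
  ct0 <- ct_model(cfg$ct$space, cfg$ct$N, list(min_partition(1:2)), 0,
                  demes = cfg$ct$demes)
  t <- 1.7
  sol <- ct_solve(cfg$initial, ct0, t, "expm")
  Et <- as.matrix(Matrix::expm(t * cfg$ct$N))
  for (k in seq_along(cfg$ct$demes)) {
    ref <- Reduce(`+`, Map(function(w, m) w * m$table,
                           Et[k, ], cfg$initial$measures))
    expect_lt(tab_dist(sol$measures[[k]], ref), 1e-10)
  }
})

test_that("the derivative of the recombinator vector is its generator image", {
  # duality: forward solutions pulled through the recombinators follow the
  # linear flow of the generator
  cfg <- generate_random_model(171, n = 3, n_demes = 2, mode = "continuous")
  Q <- build_generator_Q(cfg$ct)
  t <- 1.2
  sol <- ct_solve(cfg$initial, cfg$ct, t, "expm")
  Rt <- recombinator_vector(sol, Q$states)
  R0 <- recombinator_vector(cfg$initial, Q$states)
  lin <- as.matrix(Matrix::expm(t * Q$matrix)) %*% R0$values
  expect_lt(max(abs(Rt$values - lin)), 1e-6)
})

test_that("the two-site quadrature solution matches the matrix exponential", {
  cfg <- generate_random_model(8, n = 2, n_demes = 2, mode = "continuous")
  ref <- ct_solve(cfg$initial, cfg$ct, 1.5, "expm")
  for (a in cfg$ct$demes) {
    got <- ct_two_site(cfg$initial, cfg$ct, 1.5, a)
    expect_lt(tab_dist(got, ref$measures[[a]]$table), 1e-8)
    at0 <- ct_two_site(cfg$initial, cfg$ct, 0, a)
    expect_lt(tab_dist(at0, cfg$initial$measures[[a]]$table), 1e-12)
  }
  expect_error(
    ct_two_site(generate_random_model(5, n = 3, n_demes = 2,
                                      mode = "continuous")$initial,
                generate_random_model(5, n = 3, n_demes = 2,
                                      mode = "continuous")$ct, 1, "deme1"),
    "two sites")
})

test_that("site marginals follow the pure migration semigroup exactly", {
  # recombination preserves one-site marginals, so each site marginal
  # evolves by e^{tN} alone
  cfg <- generate_random_model(181, n = 2, n_demes = 2, mode = "continuous")
  t <- 3
  sol <- ct_solve(cfg$initial, cfg$ct, t, "expm")
  Et <- as.matrix(Matrix::expm(t * cfg$ct$N))
  for (i in 1:2) {
    for (k in seq_along(cfg$ct$demes)) {
      ref <- Reduce(`+`, Map(function(w, m) w * marginalise(m, i)$table,
                             Et[k, ], cfg$initial$measures))
      expect_lt(max(abs(marginalise(sol$measures[[k]], i)$table - ref)), 1e-8)
    }
  }
})
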