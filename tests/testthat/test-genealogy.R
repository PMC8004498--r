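test_that("trajectories are reproducible and only refine the base", {
  cfg <- generate_random_model(111, n = 3, n_demes = 2)
  start <- max_labelled_partition(1:3, "deme1")
  tr1 <- sample_trajectory(start, cfg$model, 12, seed = 9)
  tr2 <- sample_trajectory(start, cfg$model, 12, seed = 9)
  k1 <- vapply(tr1$states, function(s) migrec:::labelled_key(s), "")
  k2 <- vapply(tr2$states, function(s) migrec:::labelled_key(s), "")
  expect_identical(k1, k2)
  for (i in seq_len(length(tr1$states) - 1))
    expect_true(is_finer(partition_base(tr1$states[[i + 1]]),
                         partition_base(tr1$states[[i]])))
  expect_true(all(tr1$jump_times %in% 1:12))
  # a different seed gives a different trajectory with positive probability
  tr3 <- sample_trajectory(start, cfg$model, 12, seed = 10)
  k3 <- vapply(tr3$states, function(s) migrec:::labelled_key(s), "")
  expect_false(identical(k1, k3))
})

test_that("the one-step law of the process matches the transition matrix row", {
  cfg <- generate_random_model(2, n = 3, n_demes = 2)
  Tm <- build_T(cfg$model)
  start <- max_labelled_partition(1:3, "deme1")
  i0 <- match(migrec:::labelled_key(start), Tm$keys)
  sampler <- migrec:::lpp_sampler(cfg$model)
  n <- 4000
  draws <- vapply(seq_len(n), function(i) {
    set.seed(substream_seed(99, i))
    migrec:::labelled_key(lpp_step(start, cfg$model, sampler))
  }, "")
  emp <- table(factor(draws, levels = Tm$keys)) / n
  theo <- Tm$matrix[i0, ]
  # 5-sigma binomial envelope per state
  tol <- 5 * sqrt(pmax(theo * (1 - theo), 1e-8) / n)
  expect_true(all(abs(as.numeric(emp) - theo) < tol))
})

test_that("duality estimates converge to the forward solution", {
  cfg <- generate_random_model(11, n = 3, n_demes = 2)
  t <- 3
  est <- duality_estimate(cfg$initial, cfg$model, t, "deme1",
                          replicates = 1500, seed = 7)
  truth <- trajectory_final(mre_iterate(cfg$initial, cfg$model, t))
  z <- abs(est$estimate$table - truth$measures$deme1$table) /
    pmax(est$se, 1e-12)
  expect_lt(max(z), 4)
  expect_equal(sum(est$estimate$table), 1, tolerance = 1e-12)
})

test_that("the two-site closed form reproduces the iteration", {
  cfg <- generate_random_model(121, n = 2, n_demes = 2)
  tr <- mre_iterate(cfg$initial, cfg$model, 10)
  for (t in c(0, 1, 5, 10)) {
    for (a in cfg$model$demes) {
      cf <- two_site_closed_form(cfg$initial, cfg$model, t, a)
      expect_lt(tab_dist(cf, tr$states[[t + 1]]$measures[[a]]$table), 1e-10)
    }
  }
  expect_error(
    two_site_closed_form(generate_random_model(1, n = 3)$initial,
                         generate_random_model(1, n = 3)$model, 1, "deme1"),
    "two sites")
})
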