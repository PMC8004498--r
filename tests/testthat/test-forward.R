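test_that("one generation preserves mass and positivity", {
  cfg <- generate_random_model(21, n = 3, n_demes = 2)
  mu1 <- mre_step(cfg$initial, cfg$model)
  for (m in mu1$measures) {
    expect_equal(sum(m$table), 1, tolerance = 1e-12)
    expect_true(all(m$table >= 0))
  }
})

test_that("migration-then-recombination equals the labelled-partition mixture", {
  for (seed in c(31, 32, 33)) {
    cfg <- generate_random_model(seed, n = 3, n_demes = 2)
    a <- mre_step(cfg$initial, cfg$model)
    b <- mre_step_labelled(cfg$initial, cfg$model)
    expect_lt(meta_dist(a, b), 1e-12)
  }
})

test_that("degenerate recombination reduces to known maps", {
  space <- type_space(replicate(3, c("0", "1"), simplify = FALSE))
  set.seed(5)
  tab <- runif(8); tab <- tab / sum(tab)
  mu <- metapopulation(list(pop = pop_measure(tab, 1:3, space)))
  Mid <- migration_model(matrix(1, 1, 1), demes = "pop")
  # point mass on the one-block partition: recombination is the identity
  r1 <- recomb_dist(list(max_partition(1:3)), 1)
  mu1 <- mre_step(mu, mr_model(space, Mid, r1))
  expect_lt(meta_dist(mu1, mu), 1e-14)
  # point mass on the singleton partition: one step reaches full linkage
  # equilibrium, the product of the site marginals
  r0 <- recomb_dist(list(min_partition(1:3)), 1)
  mu0 <- mre_step(mu, mr_model(space, Mid, r0))
  prod <- migrec:::measure_product(lapply(1:3, function(i)
    marginalise(mu$measures$pop, i)))
  expect_lt(tab_dist(mu0$measures$pop, prod$table), 1e-14)
})

test_that("identity migration leaves the metapopulation unchanged", {
  cfg <- generate_random_model(44, n = 3, n_demes = 2)
  Mid <- migration_model(diag(2), demes = cfg$model$demes)
  expect_lt(meta_dist(migration_step(cfg$initial, Mid), cfg$initial), 1e-15)
})

test_that("the marginal dynamics on a subset is autonomous", {
  cfg <- generate_random_model(55, n = 3, n_demes = 2)
  for (U in list(1L, c(1L, 3L), c(2L, 3L), 1:3)) {
    a <- marginal_mre_step(marginalise_meta(cfg$initial, U), cfg$model, U)
    b <- marginalise_meta(mre_step(cfg$initial, cfg$model), U)
    expect_lt(meta_dist(a, b), 1e-12)
  }
})

test_that("trajectories record the requested generations", {
  cfg <- generate_random_model(66, n = 2, n_demes = 1)
  tr <- mre_iterate(cfg$initial, cfg$model, 4)
  expect_equal(tr$times, 0:4)
  expect_length(tr$states, 5L)
  trh <- mre_iterate(cfg$initial, cfg$model, 2, record_half = TRUE)
  expect_equal(trh$times, c(0, 0.5, 1, 1.5, 2))
  # final state equals composing the two half steps
  expect_lt(meta_dist(trajectory_final(trh),
                      mre_step(mre_step(cfg$initial, cfg$model), cfg$model)),
            1e-13)
})
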