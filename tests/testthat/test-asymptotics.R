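test_that("primitivity detection separates mixing from periodic matrices", {
  expect_true(is_primitive(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))$primitive)
  # a pure swap is irreducible but periodic
  expect_false(is_primitive(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))$primitive)
  # reducible matrix
  expect_false(is_primitive(diag(2))$primitive)
})

test_that("the stationary distribution is a fixed point of the backward flow", {
  cfg <- generate_random_model(131, n = 2, n_demes = 3)
  q <- stationary_distribution(cfg$model$M)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_lt(max(abs(as.vector(q %*% cfg$model$M$backward) - q)), 1e-12)
})

test_that("separability holds iff the support meets in the singleton partition", {
  expect_true(check_separability(fixture_two_pair_example()$model$r)$separable)
  r_bad <- recomb_dist(list(partition(list(c(1, 2), c(3, 4))),
                            max_partition(1:4)), c(0.6, 0.4))
  chk <- check_separability(r_bad)
  expect_false(chk$separable)
  expect_identical(migrec:::partition_key(partition(chk$clusters)), "1,2|3,4")
  # collapsing the never-separated clusters restores separability
  red <- collapse_clusters(r_bad)
  expect_true(check_separability(red$r)$separable)
  expect_identical(red$r$ground, 1:2)
})

test_that("the trajectory converges geometrically to the product-form limit", {
  cfg <- generate_random_model(141, n = 3, n_demes = 2)
  lim <- limiting_metapopulation(cfg$initial, cfg$model)
  tr <- mre_iterate(cfg$initial, cfg$model, 40)
  d <- vapply(seq(5, 40, by = 5), function(t)
    meta_dist(tr$states[[t + 1]], lim), 1)
  expect_lt(d[length(d)], 1e-8)
  expect_true(all(diff(d) <= 1e-12))
  fit <- fit_geometric_rate(d)
  expect_lt(fit$gamma, 1)
  expect_gt(fit$gamma, 0)
})

test_that("sojourn probabilities are not monotone along refinement paths", {
  r <- fixture_two_pair_example()$model$r
  Tul <- build_T_unlabelled(r)
  s <- sojourn_probabilities(Tul)
  path <- c("1,2,3,4", "1,2|3,4", "1,2|3|4")
  expect_equal(unname(s[path]), c(2 / 5, 1 / 4, 1 / 2))
  # decreases, then increases: non-monotone
  expect_lt(s[["1,2|3,4"]], s[["1,2,3,4"]])
  expect_gt(s[["1,2|3|4"]], s[["1,2|3,4"]])
})

test_that("maximal sojourn states of the worked example carry eta = 1/2", {
  r <- fixture_two_pair_example()$model$r
  info <- sojourn_eta_F(r)
  expect_true(info$eta_exact == rational(1, 2))
  expect_setequal(info$F_keys, c("1,2|3|4", "1|2|3,4"))
  expect_equal(info$eta_prime, 2 / 5)
  reach <- reachable_states(r)
  expect_setequal(reach$keys,
                  c("1,2,3,4", "1,2|3,4", "1,2|3|4", "1|2|3,4", "1|2|3|4"))
})

test_that("every maximal-sojourn state either stays put or absorbs", {
  # the one-step dichotomy behind the quasi-limiting analysis, on random
  # full-support models
  for (seed in 201:210) {
    r <- full_support_recomb(seed, n = 4)
    Tul <- build_T_unlabelled(r)
    info <- sojourn_eta_F(Tul)
    i0 <- match(migrec:::partition_key(min_partition(1:4)), Tul$keys)
    for (i in info$F_indices)
      expect_equal(Tul$matrix[i, i] + Tul$matrix[i, i0], 1, tolerance = 1e-12)
  }
})

test_that("the quasi-limiting law matches the conditional law at large times", {
  r <- fixture_two_pair_example()$model$r
  ql <- qlim_unlabelled(r)
  expect_equal(unname(ql$law), c(0.5, 0.5), tolerance = 1e-12)
  cl <- conditional_law_exact(r, t = 300)
  tv <- 0.5 * (sum(abs(cl[ql$F_keys] - ql$law)) +
                 sum(cl[setdiff(names(cl), ql$F_keys)]))
  expect_lt(tv, 1e-8)
})

test_that("the labelled quasi-limit is the base law times stationary labels", {
  cfg <- fixture_two_pair_example(demes = c("a", "b"))
  ql <- qlim_labelled(cfg$model)
  expect_equal(sum(ql$law), 1, tolerance = 1e-12)
  expect_equal(unname(ql$q), c(0.5, 0.5), tolerance = 1e-12)
  # each of the two base states has 3 blocks and 2 labels per block
  expect_length(ql$states, 2 * 2^3)
  expect_equal(unname(ql$law), rep(1 / 16, 16), tolerance = 1e-12)
})
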