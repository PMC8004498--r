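test_that("flat tables follow the lexicographic order with the last site fastest", {
  space <- type_space(list(c("A", "B"), c("x", "y", "z")))
  flat <- (1:6) / 21
  m <- pop_measure(flat, 1:2, space)
  # site 1 most significant: entry (A, z) is the third flat value
  expect_equal(m$table["A", "z"], flat[3])
  expect_equal(m$table["B", "x"], flat[4])
  expect_equal(measure_flat(m), flat)
})

test_that("measure validation enforces probability structure", {
  space <- type_space(list(c("A", "B")))
  expect_error(pop_measure(c(0.4, 0.4), 1, space), "sum to 1")
  expect_error(pop_measure(c(1.2, -0.2), 1, space), "negative")
  expect_error(pop_measure(c(0.5, 0.25, 0.25), 1, space), "length")
})

test_that("marginalisation and tensor products are consistent", {
  space <- type_space(replicate(3, c("0", "1"), simplify = FALSE))
  set.seed(42)
  tab <- runif(8); tab <- tab / sum(tab)
  m <- pop_measure(tab, 1:3, space)
  m12 <- marginalise(m, c(1, 2))
  expect_equal(sum(m12$table), 1)
  expect_equal(marginalise(m12, 1)$table, marginalise(m, 1)$table)
  # marginalising a product measure recovers its factors
  prod <- migrec:::measure_product(list(marginalise(m, c(1, 3)), marginalise(m, 2)))
  expect_identical(prod$sites, 1:3)
  expect_equal(marginalise(prod, c(1, 3))$table, marginalise(m, c(1, 3))$table)
  expect_equal(marginalise(prod, 2)$table, marginalise(m, 2)$table)
})

test_that("recombination distributions validate and marginalise exactly", {
  r <- fixture_two_pair_example()$model$r
  expect_error(recomb_dist(r$parts, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(recomb_dist(r$parts[c(1, 1, 2)], c(0.5, 0.4, 0.1)), "duplicate")
  # marginal on {1,2}: the two-pair and one-block partitions both restrict to
  # the single block {1,2}, so its marginal weight is 1/10 + 2/5 = 1/2 exactly
  mr <- marginal_recombination(r, c(1, 2))
  keys <- vapply(mr$parts, function(p) migrec:::partition_key(p), "")
  expect_setequal(keys, c("1|2", "1,2"))
  expect_true(mr$exact[match("1,2", keys)] == rational(1, 2))
  expect_true(mr$exact[match("1|2", keys)] == rational(1, 2))
  # marginal on the full site set is the distribution itself
  full <- marginal_recombination(r, 1:4)
  expect_equal(sum(full$probs), 1)
  expect_length(full$parts, 3L)
})

test_that("backward matrix from forward matrix matches the flow balance", {
  fwd <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  # sizes (2, 1) are preserved by this flow: no consistency warning
  expect_silent(bm <- backward_from_forward(fwd, c(2, 1), demes = c("a", "b")))
  # backward(a, b) proportional to size(b) * forward(b, a)
  expect_equal(unname(bm$backward),
               matrix(c(1.8, 0.2, 0.2, 0.8), 2, byrow = TRUE) / c(2, 1))
  expect_equal(rowSums(bm$backward), c(a = 1, b = 1))
  # an unbalanced pair triggers the conservation warning
  expect_warning(backward_from_forward(fwd, c(1, 1), demes = c("a", "b")),
                 "not constant")
})

test_that("migration-recombination probabilities form a distribution", {
  cfg <- generate_random_model(3, n = 3, n_demes = 2)
  p <- mr_probabilities(cfg$model, "deme1")
  expect_equal(sum(p$probs), 1, tolerance = 1e-12)
  expect_true(all(p$probs >= 0))
  # marginal version on a subset also sums to one
  pm <- marginal_mr_probabilities(cfg$model, c(1, 3), "deme2")
  expect_equal(sum(pm$probs), 1, tolerance = 1e-12)
})
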