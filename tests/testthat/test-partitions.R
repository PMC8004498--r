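test_that("partition lattice enumeration has Bell-number size and canonical order", {
  for (n in 1:5) {
    states <- enumerate_partitions(seq_len(n))
    expect_length(states, bell_number(n))
    keys <- vapply(states, function(p) migrec:::partition_key(p), "")
    expect_false(anyDuplicated(keys) > 0)
  }
  e4 <- enumerate_partitions(1:4)
  # restricted-growth order starts at the one-block partition and ends at
  # the singleton partition
  expect_identical(migrec:::partition_key(e4[[1]]),
                   migrec:::partition_key(max_partition(1:4)))
  expect_identical(migrec:::partition_key(e4[[length(e4)]]),
                   migrec:::partition_key(min_partition(1:4)))
})

test_that("labelled enumeration counts sum 2^blocks over the base lattice", {
  states <- enumerate_labelled_partitions(1:4, c("a", "b"))
  base <- enumerate_partitions(1:4)
  expect_length(states, sum(vapply(base, function(p) 2^length(p$blocks), 1)))
  expect_length(states, 94L)
  states1 <- enumerate_labelled_partitions(1:3, "a")
  expect_length(states1, bell_number(3))
})

test_that("canonical form sorts blocks by minimum and sites ascending", {
  p <- partition(list(c(4, 3), c(2, 1)))
  expect_identical(migrec:::partition_key(p), "1,2|3,4")
  lp <- labelled_partition(list(c(3, 2), 1), c("b", "a"), ground = 1:3)
  expect_identical(migrec:::labelled_key(lp), "1:a|2,3:b")
})

test_that("partition validation rejects non-partitions", {
  expect_error(partition(list(c(1, 2), c(2, 3))), "disjoint")
  expect_error(partition(list(1, 2), ground = 1:3), "cover")
  expect_error(labelled_partition(list(1:2), c("a", "b")), "one label per block")
})

test_that("meet and refinement order behave lattice-theoretically", {
  p <- partition(list(c(1, 2), c(3, 4)))
  q <- partition(list(c(1, 3), c(2, 4)))
  expect_identical(migrec:::partition_key(meet(p, q)),
                   migrec:::partition_key(min_partition(1:4)))
  expect_identical(migrec:::partition_key(meet(p, p)),
                   migrec:::partition_key(p))
  expect_true(is_finer(min_partition(1:4), p))
  expect_true(is_finer(p, max_partition(1:4)))
  expect_false(is_finer(p, q))
  expect_true(is_finer(p, p))
})

test_that("restriction keeps induced blocks on the subset", {
  p <- partition(list(c(1, 2), c(3, 4)))
  expect_identical(migrec:::partition_key(restrict_partition(p, c(1, 3))), "1|3")
  expect_identical(migrec:::partition_key(restrict_partition(p, c(1, 2))), "1,2")
  expect_identical(migrec:::partition_key(restrict_partition(max_partition(1:4), c(2, 4))),
                   "2,4")
})

test_that("plain-list round trip preserves partitions", {
  p <- partition(list(c(1, 2), 3, c(4, 5)))
  expect_identical(migrec:::partition_key(partition_from_list(partition_to_list(p), 1:5)),
                   migrec:::partition_key(p))
})
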