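test_that("configuration files round-trip semantically in YAML and JSON", {
  cfg <- generate_random_model(2, n = 3, n_demes = 2)
  for (ext in c(".yaml", ".json")) {
    path <- temp_path(ext)
    write_model_config(cfg, path)
    back <- read_model_config(path)
    expect_lt(max(abs(back$model$M$backward - cfg$model$M$backward)), 1e-12)
    expect_identical(back$model$r$keys, cfg$model$r$keys)
    expect_lt(max(abs(back$model$r$probs - cfg$model$r$probs)), 1e-12)
    expect_lt(meta_dist(back$initial, cfg$initial), 1e-12)
  }
})

test_that("fraction-string weights survive the round trip exactly", {
  cfg <- fixture_two_pair_example()
  path <- temp_path(".yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_false(is.null(back$model$r$exact))
  expect_true(all(back$model$r$exact == cfg$model$r$exact))
})

test_that("continuous-time configurations round-trip", {
  cfg <- generate_random_model(9, n = 2, n_demes = 2, mode = "continuous")
  path <- temp_path(".yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_false(is.null(back$ct))
  expect_lt(max(abs(back$ct$N - cfg$ct$N)), 1e-12)
  expect_lt(max(abs(back$ct$rates - cfg$ct$rates)), 1e-12)
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(model_config_from_list(list(n = 2)), "missing required key")
  expect_error(model_config_from_list(
    list(n = 2, alphabets = list(c("0", "1")), demes = list("a"))),
    "one alphabet per site")
  expect_error(model_config_from_list(
    list(n = 1, alphabets = list(c("0", "1")), demes = list("a"),
         migration = list(backward = list(list(1))))),
    "discrete nor a continuous")
})

test_that("the random-model generator is deterministic and well-posed", {
  a <- generate_random_model(7, n = 3, n_demes = 2)
  b <- generate_random_model(7, n = 3, n_demes = 2)
  pa <- temp_path(".yaml"); write_model_config(a, pa)
  pb <- temp_path(".yaml"); write_model_config(b, pb)
  expect_identical(readLines(pa), readLines(pb))
  for (seed in 301:310) {
    cfg <- generate_random_model(seed, n = 3, n_demes = 2)
    expect_true(check_separability(cfg$model$r)$separable)
    expect_true(is_primitive(cfg$model$M)$primitive)
    # singleton partition carries mass at least 0.05
    i0 <- match(migrec:::partition_key(min_partition(1:3)), cfg$model$r$keys)
    expect_gte(cfg$model$r$probs[i0], 0.05)
  }
})

test_that("the worked-example fixture is the exact published model", {
  cfg <- fixture_two_pair_example()
  r <- cfg$model$r
  expect_true(migrec:::rat_sum(r$exact) == rational(1))
  expect_setequal(r$keys, c("1|2|3|4", "1,2|3,4", "1,2,3,4"))
  expect_true(r$exact[match("1|2|3|4", r$keys)] == rational(1, 2))
  expect_true(r$exact[match("1,2|3,4", r$keys)] == rational(1, 10))
  expect_true(r$exact[match("1,2,3,4", r$keys)] == rational(2, 5))
  expect_equal(sum(cfg$initial$measures$pop$table), 1)
})
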