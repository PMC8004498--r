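# ---------------------------------------------------------------------------
# Configuration I/O, the worked-example fixture, and the seeded random-model
# generator.  Model files are YAML or JSON with keys:
#   n, alphabets, demes, recombination (list of {partition, prob}),
#   migration ({backward} or {forward, sizes}), initial (per-deme flat
#   tables in the declared linear order), and optionally rates + generator
#   for the continuous-time variant.  Probabilities written as fraction
#   strings ("2/5") are kept exact.
# ---------------------------------------------------------------------------

#' Read a model configuration file
#'
#' Parses a YAML or JSON model file, validates all components and returns
#' the assembled model objects.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return Object of class `model_config`: fields `model` (an `mr_model`),
#'   `initial` (a `metapopulation` or `NULL`), `ct` (a `ct_model` or
#'   `NULL`), `path`.
#' @export
read_model_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  model_config_from_list(raw, path = path)
}

#' Assemble a model configuration from a plain list
#'
#' @param raw list with the configuration keys (see [read_model_config()]).
#' @param path optional provenance path.
#' @return A `model_config`.
#' @export
model_config_from_list <- function(raw, path = NULL) {
  for (key in c("n", "alphabets", "demes"))
    if (is.null(raw[[key]]))
      stop("model config is missing required key: ", key, call. = FALSE)
  n <- as.integer(raw$n)
  alphabets <- lapply(raw$alphabets, function(a) as.character(unlist(a)))
  if (length(alphabets) != n)
    stop("need one alphabet per site", call. = FALSE)
  space <- type_space(alphabets)
  demes <- as.character(unlist(raw$demes))
  # migration
  if (is.null(raw$migration) && is.null(raw$generator))
    stop("model config needs a migration block or a generator", call. = FALSE)
  M <- NULL
  if (!is.null(raw$migration)) {
    mig <- raw$migration
    to_matrix <- function(x) do.call(rbind, lapply(x, function(row) as.numeric(unlist(row))))
    if (!is.null(mig$backward)) {
      M <- migration_model(to_matrix(mig$backward), demes = demes)
    } else if (!is.null(mig$forward)) {
      M <- backward_from_forward(to_matrix(mig$forward),
                                 as.numeric(unlist(mig$sizes)), demes = demes)
    } else stop("migration block needs 'backward' or 'forward' + 'sizes'", call. = FALSE)
  }
  # recombination distribution
  model <- NULL
  if (!is.null(raw$recombination) && !is.null(M)) {
    rp <- parse_weighted_partitions(raw$recombination, n, "prob")
    r <- recomb_dist(rp$parts, rp$values, rp$exact)
    model <- mr_model(space, M, r)
  }
  # continuous time
  ct <- NULL
  if (!is.null(raw$rates) && !is.null(raw$generator)) {
    rp <- parse_weighted_partitions(raw$rates, n, "rate")
    gen <- do.call(rbind, lapply(raw$generator, function(row) as.numeric(unlist(row))))
    ct <- ct_model(space, gen, rp$parts, rp$values, demes = demes)
  }
  if (is.null(model) && is.null(ct))
    stop("model config defines neither a discrete nor a continuous-time model",
         call. = FALSE)
  # initial metapopulation
  initial <- NULL
  if (!is.null(raw$initial)) {
    meas <- lapply(demes, function(a) {
      tab <- raw$initial[[a]]
      if (is.null(tab)) stop("initial table missing for deme ", a, call. = FALSE)
      pop_measure(as.numeric(unlist(tab)), seq_len(n), space)
    })
    initial <- metapopulation(setNames(meas, demes))
  }
  structure(list(model = model, initial = initial, ct = ct, path = path),
            class = "model_config")
}

parse_weighted_partitions <- function(entries, n, value_key) {
  parts <- list(); values <- numeric(0); raw_strings <- character(0)
  all_fractions <- TRUE
  for (e in entries) {
    parts[[length(parts) + 1L]] <-
      partition(lapply(e$partition, function(b) as.integer(unlist(b))), seq_len(n))
    v <- e[[value_key]]
    if (is.character(v)) {
      raw_strings <- c(raw_strings, v)
      values <- c(values, as.numeric(parse_rational(v)))
    } else {
      all_fractions <- FALSE
      raw_strings <- c(raw_strings, NA_character_)
      values <- c(values, as.numeric(v))
    }
  }
  exact <- if (all_fractions && length(raw_strings)) parse_rational(raw_strings)
  list(parts = parts, values = values, exact = exact)
}

#' @export
print.model_config <- function(x, ...) {
  cat("model configuration",
      if (!is.null(x$path)) sprintf(" (%s)", x$path) else "", "\n", sep = "")
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$ct)) print(x$ct)
  invisible(x)
}

#' Write a model configuration file
#'
#' Canonical serialisation; reading the result back yields a semantically
#' identical configuration.
#'
#' @param config a `model_config`.
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  model <- config$model
  space <- if (!is.null(model)) model$space else config$ct$space
  demes <- if (!is.null(model)) model$demes else config$ct$demes
  raw <- list(n = space$n, alphabets = space$alphabets, demes = as.list(demes))
  if (!is.null(model)) {
    raw$migration <- list(backward = apply(model$M$backward, 1, as.list, simplify = FALSE))
    raw$recombination <- lapply(seq_along(model$r$parts), function(i) {
      list(partition = partition_to_list(model$r$parts[[i]]),
           prob = if (!is.null(model$r$exact)) format(model$r$exact[i])
                  else model$r$probs[i])
    })
  }
  if (!is.null(config$ct)) {
    raw$generator <- apply(config$ct$N, 1, as.list, simplify = FALSE)
    raw$rates <- lapply(seq_along(config$ct$rate_parts), function(i) {
      list(partition = partition_to_list(config$ct$rate_parts[[i]]),
           rate = config$ct$rates[i])
    })
  }
  if (!is.null(config$initial)) {
    raw$initial <- lapply(config$initial$measures, measure_flat)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path, precision = 15)
  }
  invisible(path)
}

#' Worked-example recombination model on four sites
#'
#' A single-deme model illustrating that sojourn probabilities need not be
#' monotone along refinement paths: with singleton-partition weight 1/2, the
#' two-pair partition weight 1/10 and one-block weight 2/5, the one-block
#' state has sojourn probability 2/5 while its refinement into two pairs has
#' the smaller sojourn probability 1/4.  Weights are exact rationals.
#'
#' @param demes deme names (default a single deme); with several demes the
#'   backward matrix is the uniform (symmetric) one.
#' @return A `model_config` with binary alphabets, the exact recombination
#'   distribution and a uniform initial state.
#' @export
fixture_two_pair_example <- function(demes = "pop") {
  n <- 4L
  space <- type_space(replicate(n, c("0", "1"), simplify = FALSE))
  parts <- list(min_partition(1:4),
                partition(list(c(1, 2), c(3, 4))),
                max_partition(1:4))
  r <- recomb_dist(parts, c(1/2, 1/10, 2/5),
                   exact = parse_rational(c("1/2", "1/10", "2/5")))
  L <- length(demes)
  M <- migration_model(matrix(1 / L, L, L), demes = demes)
  model <- mr_model(space, M, r)
  meas <- setNames(lapply(demes, function(a)
    pop_measure(rep(1 / 16, 16), 1:4, space)), demes)
  structure(list(model = model, initial = metapopulation(meas), ct = NULL,
                 path = NULL),
            class = "model_config")
}

#' Seeded random model generator
#'
#' Draws a random migration-recombination model for testing: Dirichlet
#' recombination weights on a random support that always contains the
#' singleton partition with mass at least 0.05 (so the separability
#' assumption holds by construction), strictly positive Dirichlet migration
#' rows (hence a primitive backward matrix), and per-deme Dirichlet initial
#' tables.  Deterministic in the seed.
#'
#' @param seed integer seed.
#' @param n number of sites.
#' @param alphabet_size letters per site.
#' @param n_demes number of demes.
#' @param support_size number of partitions in the recombination support
#'   (capped at the number of available partitions).
#' @param concentration Dirichlet concentration for all weight draws.
#' @param mode `"discrete"` for the generational model, `"continuous"` to
#'   also attach a continuous-time model (random rates, random generator).
#' @return A `model_config` with `model` and `initial` (and `ct` in
#'   continuous mode).
#' @export
generate_random_model <- function(seed, n = 3, alphabet_size = 2, n_demes = 2,
                                  support_size = 3, concentration = 1,
                                  mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  space <- type_space(replicate(n, LETTERS[seq_len(alphabet_size)],
                                simplify = FALSE))
  demes <- paste0("deme", seq_len(n_demes))
  all_parts <- enumerate_partitions(seq_len(n))
  key0 <- partition_key(min_partition(seq_len(n)))
  i0 <- match(key0, vapply(all_parts, partition_key, ""))
  support_size <- min(support_size, length(all_parts))
  pick <- unique(c(i0, sample(seq_along(all_parts), support_size)))
  w <- stats::rgamma(length(pick), shape = concentration)
  w <- w / sum(w)
  # guarantee singleton-partition mass of at least 0.05
  w <- 0.95 * w
  w[1] <- w[1] + 0.05
  r <- recomb_dist(all_parts[pick], w)
  Mrows <- matrix(stats::rgamma(n_demes^2, shape = concentration), n_demes)
  Mrows <- Mrows / rowSums(Mrows)
  M <- migration_model(Mrows, demes = demes)
  model <- mr_model(space, M, r)
  meas <- setNames(lapply(demes, function(a) {
    tab <- stats::rgamma(prod(space_dims(space, seq_len(n))), shape = concentration)
    pop_measure(tab / sum(tab), seq_len(n), space)
  }), demes)
  ct <- NULL
  if (mode == "continuous") {
    rates <- stats::rgamma(length(pick), shape = concentration)
    gen <- matrix(stats::rgamma(n_demes^2, shape = concentration), n_demes)
    diag(gen) <- 0
    diag(gen) <- -rowSums(gen)
    keep <- vapply(all_parts[pick], partition_key, "") !=
      partition_key(max_partition(seq_len(n)))
    ct <- ct_model(space, gen, all_parts[pick][keep], rates[keep], demes = demes)
  }
  structure(list(model = model, initial = metapopulation(meas), ct = ct,
                 path = NULL),
            class = "model_config")
}
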