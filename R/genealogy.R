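# ---------------------------------------------------------------------------
# The labelled partitioning process (LPP) as a simulable Markov chain, and
# the Monte-Carlo solution of the forward dynamics via duality.
#
# One backward generation replaces each labelled block (d, l) independently:
# the block first splits according to the marginal recombination distribution
# on d, then every fragment is relabelled independently by a draw from
# M(l, .) (splitting before relabelling, matching the forward order
# migration-then-recombination read in reverse).
#
# Reproducibility: every trajectory reseeds R's generator with a substream
# seed derived from (master seed, trajectory index) by a fixed integer hash;
# within a step, blocks are processed in canonical block order.
# ---------------------------------------------------------------------------

#' Derive a substream seed
#'
#' Maps a master seed and a stream index to a seed below `2^31` by a fixed
#' integer hash, so that replicated simulations are reproducible from a
#' single seed while using independent-looking streams.
#'
#' @param seed master integer seed.
#' @param i stream index (non-negative integer).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, i) {
  x <- ((as.double(seed) %% 2147483647) * 1000003 + as.double(i)) %% 2147483647
  as.integer(x) + 1L
}

# precomputed per-(block, label) one-step laws for fast repeated sampling
lpp_sampler <- function(model, cap = 2e5) {
  cache <- new.env(parent = emptyenv())
  list(
    model = model,
    get = function(d, l) {
      key <- paste(paste(d, collapse = ","), l, sep = "@")
      if (is.null(cache[[key]]))
        cache[[key]] <- marginal_mr_probabilities(model, d, l, cap = cap)
      cache[[key]]
    }
  )
}

#' One backward generation of the labelled partitioning process
#'
#' Each labelled block `(d, l)` of the state is replaced, independently of
#' the others, by a labelled partition of `d` drawn from the marginal
#' migration-recombination law at `l`; the result is the union of the draws.
#' Uses R's current random stream.
#'
#' @param state a `labelled_partition` of the full site set.
#' @param model an `mr_model`.
#' @param sampler optional precomputed sampler (internal use).
#' @return The next `labelled_partition`.
#' @export
lpp_step <- function(state, model, sampler = NULL) {
  stopifnot(inherits(state, "labelled_partition"))
  if (is.null(sampler)) sampler <- lpp_sampler(model)
  draws <- vector("list", length(state$blocks))
  for (b in seq_along(state$blocks)) {
    p <- sampler$get(state$blocks[[b]], state$labels[[b]])
    k <- sample.int(length(p$probs), 1L, prob = p$probs)
    draws[[b]] <- p$states[[k]]
  }
  union_labelled(draws)
}

#' Sample a trajectory of the labelled partitioning process
#'
#' @param start starting `labelled_partition`.
#' @param model an `mr_model`.
#' @param steps number of backward generations.
#' @param seed master seed; the trajectory is bit-reproducible from
#'   `(seed, model, start, steps)`.
#' @param stream substream index (used by replicated estimators).
#' @return Object of class `lpp_trajectory`: fields `seed`, `states` (list of
#'   `labelled_partition`, generations `0..steps`) and `jump_times`
#'   (generations at which the base strictly refined).
#' @export
sample_trajectory <- function(start, model, steps, seed, stream = 0L) {
  stopifnot(steps >= 0, steps == round(steps))
  set.seed(substream_seed(seed, stream))
  sampler <- lpp_sampler(model)
  states <- vector("list", steps + 1L)
  states[[1]] <- start
  jumps <- integer(0)
  if (steps > 0) for (t in seq_len(steps)) {
    states[[t + 1L]] <- lpp_step(states[[t]], model, sampler)
    if (length(states[[t + 1L]]$blocks) > length(states[[t]]$blocks) ||
        !identical(lapply(states[[t + 1L]]$blocks, identity),
                   lapply(states[[t]]$blocks, identity)))
      jumps <- c(jumps, t)
  }
  structure(list(seed = seed, states = states, jump_times = jumps),
            class = "lpp_trajectory")
}

#' @export
print.lpp_trajectory <- function(x, ...) {
  cat(sprintf("LPP trajectory, %d generations, %d base refinements\n",
              length(x$states) - 1L, length(x$jump_times)))
  invisible(x)
}

#' Monte-Carlo solution of the forward dynamics via duality
#'
#' By the duality between the forward flow and the labelled partitioning
#' process, the deme-`alpha` population at generation `t` equals the
#' expectation of the labelled recombinator of the initial state evaluated at
#' the LPP state after `t` backward generations started from the one-block
#' partition labelled `alpha`.  This estimator averages that recombinator
#' over independent trajectories and reports a per-cell standard error
#' (sample standard deviation divided by the square root of the number of
#' replicates).
#'
#' @param mu0 initial `metapopulation`.
#' @param model an `mr_model`.
#' @param t number of generations.
#' @param alpha deme name.
#' @param replicates number of independent trajectories (>= 1).
#' @param seed master seed; replicate `i` uses substream `i`.
#' @return Object of class `duality_estimate`: fields `deme`, `estimate`
#'   (a `pop_measure`), `se` (array of standard errors), `replicates`.
#' @export
duality_estimate <- function(mu0, model, t, alpha, replicates, seed) {
  stopifnot(replicates >= 1, alpha %in% model$demes)
  sampler <- lpp_sampler(model)
  start <- max_labelled_partition(mu0$sites, alpha)
  sum1 <- NULL; sum2 <- NULL
  for (i in seq_len(replicates)) {
    set.seed(substream_seed(seed, i))
    state <- start
    if (t > 0) for (s in seq_len(t)) state <- lpp_step(state, model, sampler)
    val <- recombinator(state, mu0)$table
    if (is.null(sum1)) { sum1 <- val; sum2 <- val^2 }
    else { sum1 <- sum1 + val; sum2 <- sum2 + val^2 }
  }
  mean_tab <- sum1 / replicates
  var_tab <- pmax(sum2 / replicates - mean_tab^2, 0) * replicates / max(replicates - 1, 1)
  se <- sqrt(var_tab / replicates)
  structure(list(deme = alpha,
                 estimate = new_measure(mean_tab, mu0$sites),
                 se = se, replicates = replicates),
            class = "duality_estimate")
}

#' @export
print.duality_estimate <- function(x, ...) {
  cat(sprintf("duality estimate at deme %s from %d replicates (max SE %.3g)\n",
              x$deme, x$replicates, max(x$se)))
  print(x$estimate)
  invisible(x)
}

#' Closed-form solution for two sites
#'
#' For `n = 2` the genealogy has a single splitting event, which yields an
#' explicit formula: with probability `r1^t` the sites are never separated
#' and the sequence descends from a single ancestor whose deme follows the
#' `t`-step migration kernel; otherwise, summing over the splitting
#' generation `s` and the deme `g` where the split occurred, the two sites
#' descend from independent ancestors performing migration random walks of
#' length `t - s + 1`.
#'
#' @param mu0 initial `metapopulation` over two sites.
#' @param model an `mr_model` with `n = 2`.
#' @param t number of generations.
#' @param alpha deme name.
#' @return The deme-`alpha` population at generation `t`, a `pop_measure`.
#' @export
two_site_closed_form <- function(mu0, model, t, alpha) {
  if (model$space$n != 2)
    stop("closed form requires exactly two sites", call. = FALSE)
  stopifnot(alpha %in% model$demes, t >= 0, t == round(t))
  demes <- model$demes
  M <- model$M$backward
  key1 <- partition_key(max_partition(1:2))
  key0 <- partition_key(min_partition(1:2))
  r1 <- if (key1 %in% model$r$keys) model$r$probs[match(key1, model$r$keys)] else 0
  r0 <- if (key0 %in% model$r$keys) model$r$probs[match(key0, model$r$keys)] else 0
  # matrix powers M^0 .. M^t
  pows <- vector("list", t + 1L)
  pows[[1]] <- diag(length(demes)); dimnames(pows[[1]]) <- dimnames(M)
  if (t > 0) for (k in seq_len(t)) pows[[k + 1]] <- pows[[k]] %*% M
  # unseparated term: r1^t * sum_b (M^t)(alpha, b) mu0(b)
  w <- pows[[t + 1]][alpha, demes]
  tab <- r1^t * Reduce(`+`, mapply(function(wb, m) wb * m$table,
                                   w, mu0$measures[demes], SIMPLIFY = FALSE))
  # one-site marginals of mu0 per deme
  m1 <- lapply(mu0$measures, function(m) marginalise(m, 1L)$table)
  m2 <- lapply(mu0$measures, function(m) marginalise(m, 2L)$table)
  if (t > 0) for (s in seq_len(t)) {
    Wsplit <- pows[[s]][alpha, demes]            # (M^(s-1))(alpha, g)
    Wwalk <- pows[[t - s + 2]]                   # M^(t-s+1)
    for (g in demes) {
      if (Wsplit[[g]] == 0) next
      v1 <- Reduce(`+`, mapply(function(wb, v) wb * v, Wwalk[g, demes], m1[demes],
                               SIMPLIFY = FALSE))
      v2 <- Reduce(`+`, mapply(function(wb, v) wb * v, Wwalk[g, demes], m2[demes],
                               SIMPLIFY = FALSE))
      tab <- tab + r1^(s - 1) * r0 * Wsplit[[g]] * outer(v1, v2)
    }
  }
  dimnames(tab) <- model$space$alphabets[1:2]
  new_measure(tab, 1:2)
}
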