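# ---------------------------------------------------------------------------
# The nonlinear forward dynamics.  One generation = migration (mixing of the
# deme populations by the backward matrix M) followed by recombination
# (replacement of each deme's population by the r-mixture of partition
# product measures of its own marginals).
# ---------------------------------------------------------------------------

#' Migration step
#'
#' Mixes the deme populations by the backward migration matrix:
#' `mu'(a) = sum_b M(a, b) mu(b)`.
#'
#' @param mu a `metapopulation`.
#' @param M a `migration_model` (or an `mr_model`, whose migration part is
#'   used).
#' @return The post-migration `metapopulation`.
#' @export
migration_step <- function(mu, M) {
  if (inherits(M, "mr_model")) M <- M$M
  stopifnot(inherits(mu, "metapopulation"), inherits(M, "migration_model"))
  if (!identical(mu$demes, M$demes))
    stop("deme sets of metapopulation and migration model differ", call. = FALSE)
  out <- lapply(M$demes, function(a)
    measure_axpy(M$backward[a, mu$demes], mu$measures))
  metapopulation(setNames(out, M$demes))
}

#' Recombination step
#'
#' Replaces each deme's population by the mixture, over partitions `delta`
#' with weight `r_delta`, of the product of its own block marginals.
#'
#' @param mu a `metapopulation`.
#' @param r a `recomb_dist` (or an `mr_model`, whose recombination part is
#'   used).  Its ground set must equal the sites of `mu`.
#' @return The post-recombination `metapopulation`.
#' @export
recombination_step <- function(mu, r) {
  if (inherits(r, "mr_model")) r <- r$r
  stopifnot(inherits(mu, "metapopulation"), inherits(r, "recomb_dist"))
  if (!identical(r$ground, mu$sites))
    stop("recombination distribution and metapopulation site sets differ",
         call. = FALSE)
  out <- lapply(mu$measures, function(nu) {
    comps <- lapply(r$parts, recombinator_unlabelled, nu = nu)
    mix <- measure_axpy(r$probs, comps)
    # the map preserves mass exactly; renormalising removes the roundoff
    # drift that the block products would otherwise amplify geometrically
    mix$table <- mix$table / sum(mix$table)
    mix
  })
  metapopulation(out)
}

#' One generation of the migration-recombination dynamics
#'
#' Applies migration then recombination.  This is the dynamical map whose
#' iteration defines the forward trajectory; it coincides with the mixture,
#' over labelled partitions, of labelled recombinators weighted by the
#' migration-recombination probabilities (see [mre_step_labelled()]).
#'
#' @param mu a `metapopulation`.
#' @param model an `mr_model`.
#' @return The next-generation `metapopulation`.
#' @export
mre_step <- function(mu, model) {
  stopifnot(inherits(model, "mr_model"))
  recombination_step(migration_step(mu, model$M), model$r)
}

#' One generation via the labelled-partition mixture
#'
#' Computes the same map as [mre_step()] from its labelled form:
#' `mu'(a) = sum over labelled partitions bdelta of p_bdelta(a) *
#' R_bdelta(mu)`.  Exposed separately so the two independent formulas can be
#' compared.
#'
#' @inheritParams mre_step
#' @return The next-generation `metapopulation`.
#' @export
mre_step_labelled <- function(mu, model) {
  stopifnot(inherits(mu, "metapopulation"), inherits(model, "mr_model"))
  out <- lapply(model$demes, function(a) {
    p <- mr_probabilities(model, a)
    comps <- lapply(p$states, recombinator, mu = mu)
    measure_axpy(p$probs, comps)
  })
  metapopulation(setNames(out, model$demes))
}

#' One generation of the marginal dynamics on a site subset
#'
#' The marginal system on `U` is autonomous: stepping the `U`-marginals with
#' the marginal migration-recombination probabilities equals marginalising a
#' full-system step.
#'
#' @param muU a `metapopulation` over `U`.
#' @param model an `mr_model`.
#' @param U non-empty site subset.
#' @return The next-generation marginal `metapopulation`.
#' @export
marginal_mre_step <- function(muU, model, U) {
  U <- check_siteset(U)
  stopifnot(inherits(muU, "metapopulation"), identical(muU$sites, U))
  out <- lapply(model$demes, function(a) {
    p <- marginal_mr_probabilities(model, U, a)
    comps <- lapply(p$states, recombinator, mu = muU)
    measure_axpy(p$probs, comps)
  })
  metapopulation(setNames(out, model$demes))
}

#' Iterate the migration-recombination dynamics
#'
#' @param mu0 initial `metapopulation`.
#' @param model an `mr_model`.
#' @param steps number of generations (non-negative integer).
#' @param record_half also record the post-migration (half-integer time)
#'   states.
#' @return Object of class `mre_trajectory`: fields `times` (numeric,
#'   integers and optionally half-integers) and `states` (list of
#'   `metapopulation`s).
#' @export
mre_iterate <- function(mu0, model, steps, record_half = FALSE) {
  stopifnot(steps >= 0, steps == round(steps))
  times <- 0
  states <- list(mu0)
  mu <- mu0
  if (steps > 0) for (t in seq_len(steps)) {
    half <- migration_step(mu, model$M)
    if (record_half) {
      times <- c(times, t - 0.5)
      states[[length(states) + 1L]] <- half
    }
    mu <- recombination_step(half, model$r)
    times <- c(times, t)
    states[[length(states) + 1L]] <- mu
  }
  structure(list(times = times, states = states), class = "mre_trajectory")
}

#' @export
print.mre_trajectory <- function(x, ...) {
  cat(sprintf("trajectory with %d recorded states, times %s..%s\n",
              length(x$states), min(x$times), max(x$times)))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj an `mre_trajectory`.
#' @return The last recorded `metapopulation`.
#' @export
trajectory_final <- function(traj) traj$states[[length(traj$states)]]

#' Sup-norm distance between two metapopulations
#'
#' Largest absolute cellwise difference across all demes; the metric used in
#' all solver cross-checks.
#'
#' @param a,b `metapopulation`s on the same sites and demes.
#' @return Numeric scalar.
#' @export
meta_dist <- function(a, b) {
  max(mapply(function(x, y) max(abs(x$table - y$table)), a$measures, b$measures))
}
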