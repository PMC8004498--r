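# ---------------------------------------------------------------------------
# Haldane linearisation.  The nonlinear dynamics becomes linear for the
# vector of recombinators R(mu) indexed by labelled partitions of the full
# site set: R(mu_{t+1}) = T R(mu_t), with T the transition matrix of the
# labelled partitioning process.  T acts blockwise on the measure-valued
# vector; measures are flattened so the action is one matrix product per
# generation.
# ---------------------------------------------------------------------------

#' Transition matrix of the unlabelled partitioning process
#'
#' Builds `T^ul`, indexed by the partitions of the ground set in canonical
#' enumeration order.  The entry at `(delta, epsilon)` is the product over
#' the blocks `d` of `delta` of the marginal recombination probability
#' `r^d` of the induced partition `epsilon|_d`, for `epsilon` finer than
#' `delta`, and zero otherwise.  Rows are stochastic; the row at the
#' singleton partition is absorbing.  When the recombination distribution
#' carries exact rational weights, entries are computed exactly and the
#' numerator/denominator matrices are attached.
#'
#' @param r a `recomb_dist`.
#' @param cap cap on the ground-set size for enumeration.
#' @return Object of class `unlabelled_T`: fields `states` (list of
#'   `site_partition`), `keys`, `matrix`, and optionally `exact_num`,
#'   `exact_den`.
#' @export
build_T_unlabelled <- function(r, cap = 10L) {
  stopifnot(inherits(r, "recomb_dist"))
  states <- enumerate_partitions(r$ground, cap = cap)
  keys <- vapply(states, partition_key, "")
  index <- setNames(seq_along(states), keys)
  ns <- length(states)
  Tm <- matrix(0, ns, ns, dimnames = list(keys, keys))
  exact <- !is.null(r$exact)
  if (exact) {
    num <- matrix(0, ns, ns, dimnames = list(keys, keys))
    den <- matrix(1, ns, ns, dimnames = list(keys, keys))
  }
  # marginal recombination distribution per distinct block
  blocks_seen <- new.env(parent = emptyenv())
  get_marg <- function(d) {
    key <- paste(d, collapse = ",")
    if (is.null(blocks_seen[[key]]))
      blocks_seen[[key]] <- marginal_recombination(r, d)
    blocks_seen[[key]]
  }
  for (i in seq_along(states)) {
    delta <- states[[i]]
    margs <- lapply(delta$blocks, get_marg)
    # nonzero targets are unions of per-block support choices
    choice <- expand.grid(lapply(margs, function(m) seq_along(m$parts)))
    for (row in seq_len(nrow(choice))) {
      sel <- as.integer(choice[row, ])
      sub_blocks <- list(); prob <- 1
      if (exact) prob_ex <- rational(1)
      for (b in seq_along(margs)) {
        m <- margs[[b]]
        sub_blocks <- c(sub_blocks, m$parts[[sel[b]]]$blocks)
        prob <- prob * m$probs[sel[b]]
        if (exact) prob_ex <- prob_ex * m$exact[sel[b]]
      }
      eps <- partition(sub_blocks, delta$ground)
      j <- index[[partition_key(eps)]]
      Tm[i, j] <- Tm[i, j] + prob
      if (exact) {
        cur <- rational(num[i, j], den[i, j]) + prob_ex
        num[i, j] <- cur$num; den[i, j] <- cur$den
      }
    }
  }
  out <- list(states = states, keys = keys, matrix = Tm)
  if (exact) { out$exact_num <- num; out$exact_den <- den }
  structure(out, class = "unlabelled_T")
}

#' @export
print.unlabelled_T <- function(x, ...) {
  cat(sprintf("unlabelled partitioning transition matrix, %d states%s\n",
              length(x$states), if (!is.null(x$exact_num)) " (exact)" else ""))
  invisible(x)
}

#' Sojourn probabilities (diagonal of the unlabelled transition matrix)
#'
#' @param Tul an `unlabelled_T`.
#' @param exact return exact rationals when available.
#' @return Named numeric vector (or `rational`) of diagonal entries.
#' @export
sojourn_probabilities <- function(Tul, exact = FALSE) {
  if (exact) {
    if (is.null(Tul$exact_num)) stop("no exact entries available", call. = FALSE)
    return(rational(diag(Tul$exact_num), diag(Tul$exact_den)))
  }
  setNames(diag(Tul$matrix), Tul$keys)
}

#' Transition matrix of the labelled partitioning process
#'
#' Builds `T`, indexed by the labelled partitions of the full site set in
#' canonical enumeration order.  A transition from `bdelta` replaces every
#' labelled block `(d, l)` independently by a labelled partition of `d`
#' drawn from the marginal migration-recombination law at `l`; the entry at
#' `(bdelta, beps)` is therefore the product over the blocks of `bdelta` of
#' `p^d(l)` evaluated at the induced labelled partition `beps|_d`.
#'
#' @param model an `mr_model`.
#' @param cap cap on the labelled state-space size.
#' @return Object of class `labelled_T`: fields `states`
#'   (`labelled_partition`s), `keys`, `matrix`, `demes`.
#' @export
build_T <- function(model, cap = 2e5) {
  stopifnot(inherits(model, "mr_model"))
  ground <- seq_len(model$space$n)
  states <- enumerate_labelled_partitions(ground, model$demes, cap = cap)
  keys <- vapply(states, labelled_key, "")
  index <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) index[[keys[i]]] <- i
  ns <- length(states)
  Tm <- matrix(0, ns, ns, dimnames = list(keys, keys))
  # per-(block, label) one-step laws, cached
  cache <- new.env(parent = emptyenv())
  get_p <- function(d, l) {
    key <- paste(paste(d, collapse = ","), l, sep = "@")
    if (is.null(cache[[key]]))
      cache[[key]] <- marginal_mr_probabilities(model, d, l, cap = cap)
    cache[[key]]
  }
  for (i in seq_along(states)) {
    bdelta <- states[[i]]
    ps <- mapply(get_p, bdelta$blocks, bdelta$labels, SIMPLIFY = FALSE)
    choice <- expand.grid(lapply(ps, function(p) seq_along(p$states)))
    for (row in seq_len(nrow(choice))) {
      sel <- as.integer(choice[row, ])
      prob <- 1; parts <- vector("list", length(ps))
      for (b in seq_along(ps)) {
        prob <- prob * ps[[b]]$probs[sel[b]]
        parts[[b]] <- ps[[b]]$states[[sel[b]]]
      }
      if (prob == 0) next
      beps <- union_labelled(parts)
      j <- index[[labelled_key(beps)]]
      Tm[i, j] <- Tm[i, j] + prob
    }
  }
  structure(list(states = states, keys = keys, matrix = Tm, demes = model$demes),
            class = "labelled_T")
}

#' @export
print.labelled_T <- function(x, ...) {
  cat(sprintf("labelled partitioning transition matrix, %d states, demes: %s\n",
              length(x$states), paste(x$demes, collapse = ", ")))
  invisible(x)
}

#' Labelled transition matrix via the label factorisation
#'
#' Independent reconstruction of `T`: each entry is the unlabelled entry
#' `T^ul` at the bases times the product, over the labelled blocks `(d, l)`
#' of the source and the blocks of the target induced on `d`, of the
#' migration probabilities `M(l, label)`.  Used as a cross-check against
#' [build_T()].
#'
#' @inheritParams build_T
#' @return A `labelled_T`.
#' @export
build_T_factorised <- function(model, cap = 2e5) {
  stopifnot(inherits(model, "mr_model"))
  ground <- seq_len(model$space$n)
  Tul <- build_T_unlabelled(model$r)
  ul_index <- setNames(seq_along(Tul$keys), Tul$keys)
  states <- enumerate_labelled_partitions(ground, model$demes, cap = cap)
  keys <- vapply(states, labelled_key, "")
  ns <- length(states)
  M <- model$M$backward
  Tm <- matrix(0, ns, ns, dimnames = list(keys, keys))
  bases <- lapply(states, partition_base)
  base_idx <- vapply(bases, function(b) ul_index[[partition_key(b)]], 1L)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      tul <- Tul$matrix[base_idx[i], base_idx[j]]
      if (tul == 0) next
      if (!is_finer(bases[[j]], bases[[i]])) next
      fac <- 1
      beps <- states[[j]]
      for (b in seq_along(states[[i]]$blocks)) {
        d <- states[[i]]$blocks[[b]]; l <- states[[i]]$labels[[b]]
        ind <- restrict_partition(beps, d)
        fac <- fac * prod(M[l, ind$labels])
      }
      Tm[i, j] <- tul * fac
    }
  }
  structure(list(states = states, keys = keys, matrix = Tm, demes = model$demes),
            class = "labelled_T")
}

#' Recombinator vector of a metapopulation
#'
#' Evaluates the labelled recombinator of `mu` at every labelled partition of
#' the full site set.  Component measures are flattened into the rows of a
#' matrix so the transition matrix can act on them by ordinary matrix
#' multiplication; the component at the one-block partition labelled `a` is
#' `mu(a)` itself.
#'
#' @param mu a `metapopulation` over the full site set.
#' @param states optional list of `labelled_partition`s fixing the state
#'   order (e.g. from [build_T()]); defaults to canonical enumeration.
#' @param cap cap on the labelled state-space size.
#' @return Object of class `recomb_vector`: fields `states`, `keys`,
#'   `values` (matrix, one flattened measure per row), `sites`, `dims`.
#' @export
recombinator_vector <- function(mu, states = NULL, cap = 2e5) {
  stopifnot(inherits(mu, "metapopulation"))
  if (is.null(states))
    states <- enumerate_labelled_partitions(mu$sites, mu$demes, cap = cap)
  meas <- lapply(states, recombinator, mu = mu)
  dims <- dim(meas[[1]]$table)
  if (is.null(dims)) dims <- length(meas[[1]]$table)
  values <- do.call(rbind, lapply(meas, function(m) as.vector(m$table)))
  rownames(values) <- vapply(states, labelled_key, "")
  structure(list(states = states, keys = rownames(values), values = values,
                 sites = mu$sites, dims = dims),
            class = "recomb_vector")
}

#' @export
print.recomb_vector <- function(x, ...) {
  cat(sprintf("recombinator vector: %d labelled partitions, measures on sites {%s}\n",
              length(x$states), paste(x$sites, collapse = ",")))
  invisible(x)
}

# rebuild the metapopulation from the maximal components of a recombinator
# vector (rows of a values matrix in the order of `states`)
meta_from_vector <- function(values, states, demes, sites, dims) {
  keys <- vapply(states, labelled_key, "")
  out <- lapply(demes, function(a) {
    key <- labelled_key(max_labelled_partition(sites, a))
    row <- values[match(key, keys), ]
    new_measure(array(row, dim = dims), sites)
  })
  metapopulation(setNames(out, demes))
}

#' Solve the migration-recombination equation by matrix powers
#'
#' Exact solution of the nonlinear forward dynamics through the linearised
#' system: propagates the recombinator vector of the initial state with `t`
#' applications of the labelled transition matrix and reads off the
#' components at the one-block labelled partitions.
#'
#' @param mu0 initial `metapopulation` over the full site set.
#' @param model an `mr_model`.
#' @param t number of generations.
#' @param Tmat optional precomputed [build_T()] result.
#' @param cap cap on the labelled state-space size.
#' @return The `metapopulation` at generation `t`.
#' @export
solve_by_matrix_powers <- function(mu0, model, t, Tmat = NULL, cap = 2e5) {
  stopifnot(t >= 0, t == round(t))
  if (is.null(Tmat)) Tmat <- build_T(model, cap = cap)
  rv <- recombinator_vector(mu0, states = Tmat$states, cap = cap)
  V <- rv$values
  if (t > 0) for (s in seq_len(t)) V <- Tmat$matrix %*% V
  meta_from_vector(V, Tmat$states, model$demes, mu0$sites, rv$dims)
}
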