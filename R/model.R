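# ---------------------------------------------------------------------------
# Model data: type space, population measures, metapopulations,
# recombination distributions, migration matrices, recombinators and the
# migration-recombination probabilities.
#
# A population measure over a site subset U is stored as a dense numeric
# array, one dimension per site of U in ascending site order, dimnames the
# per-site alphabets.  The external linear order (used in config files and
# flat exports) is lexicographic over sites ascending with letters in
# declared alphabet order, i.e. the last site varies fastest.
# ---------------------------------------------------------------------------

#' Type space: per-site alphabets
#'
#' The type space is the Cartesian product of finite per-site alphabets; a
#' type is a full sequence of letters over the sites `1..n`.
#'
#' @param alphabets list of character vectors, one non-empty alphabet per
#'   site.
#' @param cap maximum allowed product-space size.
#' @return An object of class `type_space` with fields `n` and `alphabets`.
#' @examples
#' type_space(list(c("A", "a"), c("B", "b")))
#' @export
type_space <- function(alphabets, cap = 1e6) {
  stopifnot(is.list(alphabets), length(alphabets) >= 1)
  alphabets <- lapply(alphabets, as.character)
  if (any(vapply(alphabets, length, 1L) == 0))
    stop("each alphabet must be non-empty", call. = FALSE)
  size <- prod(vapply(alphabets, length, 1L))
  if (size > cap)
    stop(sprintf("type space has %.3g states, exceeding the cap of %.3g", size, cap),
         call. = FALSE)
  structure(list(n = length(alphabets), alphabets = alphabets), class = "type_space")
}

#' @export
print.type_space <- function(x, ...) {
  cat(sprintf("type space over %d sites; alphabet sizes: %s\n", x$n,
              paste(vapply(x$alphabets, length, 1L), collapse = " ")))
  invisible(x)
}

space_dims <- function(space, sites) vapply(space$alphabets[sites], length, 1L)

#' Population measure on a marginal type space
#'
#' A probability distribution over the types restricted to a site subset `U`,
#' stored as a dense array (one dimension per site, ascending).  The empty
#' site set gives the trivial unit mass on the empty sequence, which acts as
#' the scalar 1 in measure products.
#'
#' @param table numeric array (or vector in the declared linear order) of
#'   probabilities.
#' @param sites integer vector of sites (ascending), possibly empty.
#' @param space the `type_space`.
#' @param validate check nonnegativity and total mass 1 (tolerance 1e-12).
#' @return Object of class `pop_measure` with fields `sites` and `table`.
#' @export
pop_measure <- function(table, sites, space, validate = TRUE) {
  sites <- check_siteset(sites, allow_empty = TRUE)
  if (length(sites) == 0) return(measure_unit())
  dims <- space_dims(space, sites)
  if (is.null(dim(table))) {
    if (length(table) != prod(dims))
      stop("table length does not match the marginal type space", call. = FALSE)
    # flat input arrives in lexicographic order: last site fastest
    table <- aperm(array(as.numeric(table), dim = rev(dims)), rev(seq_along(dims)))
  }
  dimnames(table) <- space$alphabets[sites]
  if (validate) {
    if (any(table < -1e-15)) stop("measure has negative entries", call. = FALSE)
    if (abs(sum(table) - 1) > 1e-12)
      stop("measure does not sum to 1", call. = FALSE)
  }
  structure(list(sites = sites, table = table), class = "pop_measure")
}

new_measure <- function(table, sites) {
  structure(list(sites = sites, table = table), class = "pop_measure")
}

measure_unit <- function() {
  structure(list(sites = integer(0), table = 1), class = "pop_measure")
}

#' @export
print.pop_measure <- function(x, ...) {
  if (length(x$sites) == 0) {
    cat("unit measure on the empty site set\n")
  } else {
    cat(sprintf("probability measure on sites {%s}\n", paste(x$sites, collapse = ",")))
    print(x$table)
  }
  invisible(x)
}

#' Flatten a measure in the declared linear order
#'
#' @param nu a `pop_measure`.
#' @return Numeric vector, lexicographic over sites ascending (last site
#'   varies fastest).
#' @export
measure_flat <- function(nu) {
  if (length(nu$sites) == 0) return(1)
  d <- dim(nu$table)
  if (is.null(d)) return(as.vector(nu$table))
  as.vector(aperm(nu$table, rev(seq_along(d))))
}

#' Marginal distribution of a population measure
#'
#' Pushes a measure on sites `U` forward to a subset `V` by summing over the
#' discarded sites; linear and mass-preserving.  `V` may equal `U` (identity)
#' or be empty (trivial unit measure).
#'
#' @param nu a `pop_measure` over sites `U`.
#' @param V integer vector, subset of `U`.
#' @return A `pop_measure` over `V`.
#' @export
marginalise <- function(nu, V) {
  V <- check_siteset(V, allow_empty = TRUE)
  if (!all(V %in% nu$sites))
    stop("V must be a subset of the measure's sites", call. = FALSE)
  if (length(V) == 0) return(measure_unit())
  if (identical(V, nu$sites)) return(nu)
  keep <- match(V, nu$sites)
  tab <- apply(nu$table, keep, sum)
  if (length(V) == 1L) tab <- array(tab, dim = length(tab), dimnames = list(names(tab)))
  new_measure(tab, V)
}

# tensor product of measures on disjoint site sets, respecting site order
tensor_measures <- function(a, b) {
  if (length(a$sites) == 0) return(b)
  if (length(b$sites) == 0) return(a)
  sites <- c(a$sites, b$sites)
  if (anyDuplicated(sites)) stop("measures overlap in sites", call. = FALSE)
  tab <- outer(a$table, b$table)
  perm <- order(sites)
  if (!identical(perm, seq_along(sites))) tab <- aperm(tab, perm)
  new_measure(tab, sites[perm])
}

measure_product <- function(measures) {
  Reduce(tensor_measures, measures, measure_unit())
}

# a*nu + b*nu' on identical site sets (no validation; used by the dynamics)
measure_axpy <- function(coefs, measures) {
  tab <- coefs[[1]] * measures[[1]]$table
  if (length(measures) > 1)
    for (i in 2:length(measures)) tab <- tab + coefs[[i]] * measures[[i]]$table
  new_measure(tab, measures[[1]]$sites)
}

#' Metapopulation: one population measure per deme
#'
#' @param measures named list of `pop_measure` objects over a common site
#'   set, names the deme names in declaration order.
#' @return Object of class `metapopulation` with fields `demes`, `sites` and
#'   `measures`.
#' @export
metapopulation <- function(measures) {
  stopifnot(is.list(measures), length(measures) >= 1, !is.null(names(measures)))
  sites <- measures[[1]]$sites
  for (m in measures) {
    stopifnot(inherits(m, "pop_measure"))
    if (!identical(m$sites, sites))
      stop("all deme measures must share the same site set", call. = FALSE)
  }
  structure(list(demes = names(measures), sites = sites, measures = measures),
            class = "metapopulation")
}

#' @export
print.metapopulation <- function(x, ...) {
  cat(sprintf("metapopulation over sites {%s}, demes: %s\n",
              paste(x$sites, collapse = ","), paste(x$demes, collapse = ", ")))
  invisible(x)
}

#' Marginalise every deme of a metapopulation
#' @param mu a `metapopulation`.
#' @param V site subset.
#' @return A `metapopulation` over `V`.
#' @export
marginalise_meta <- function(mu, V) {
  metapopulation(lapply(mu$measures, marginalise, V = V))
}

#' Recombination distribution over partitions of the site set
#'
#' Sparse probability distribution `r` over the partition lattice of the full
#' site set; partitions outside the support carry probability zero.  Exact
#' rational weights may be attached for the exact-arithmetic mode.
#'
#' @param parts list of `site_partition` objects (the support).
#' @param probs numeric probabilities, summing to 1 within 1e-12.
#' @param exact optional `rational` vector of the same weights; when present
#'   the sum must be exactly 1 and quantities derived from `r` alone are
#'   computed exactly.
#' @return Object of class `recomb_dist`.
#' @export
recomb_dist <- function(parts, probs, exact = NULL) {
  stopifnot(is.list(parts), length(parts) == length(probs),
            all(vapply(parts, inherits, TRUE, "site_partition")))
  ground <- parts[[1]]$ground
  for (p in parts) same_ground(p, parts[[1]])
  if (any(probs < 0)) stop("recombination probabilities must be >= 0", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("recombination probabilities must sum to 1", call. = FALSE)
  keys <- vapply(parts, partition_key, "")
  if (anyDuplicated(keys)) stop("duplicate partitions in support", call. = FALSE)
  if (!is.null(exact)) {
    stopifnot(inherits(exact, "rational"), length(exact) == length(parts))
    if (!(rat_sum(exact) == rational(1)))
      stop("exact weights must sum to exactly 1", call. = FALSE)
  }
  structure(list(ground = ground, parts = parts, probs = as.numeric(probs),
                 exact = exact, keys = keys),
            class = "recomb_dist")
}

#' @export
print.recomb_dist <- function(x, ...) {
  cat(sprintf("recombination distribution on %d sites, support size %d\n",
              length(x$ground), length(x$parts)))
  for (i in seq_along(x$parts))
    cat(sprintf("  %s : %s\n", format(x$parts[[i]]),
                if (!is.null(x$exact)) format(x$exact[i]) else format(x$probs[i])))
  invisible(x)
}

#' Migration model: backward migration matrix over the demes
#'
#' The backward matrix `M` is row-stochastic; `M[a, b]` is the probability
#' that an individual now at deme `a` has migrated from deme `b`.
#'
#' @param backward square numeric matrix; rows must sum to 1 within 1e-12.
#'   Row/column names, if absent, are taken from `demes`.
#' @param demes character vector of deme names in declaration order.
#' @param forward,sizes optionally, the forward matrix and deme sizes from
#'   which `backward` was derived (kept for reporting).
#' @return Object of class `migration_model`.
#' @export
migration_model <- function(backward, demes = rownames(backward),
                            forward = NULL, sizes = NULL) {
  backward <- as.matrix(backward)
  if (is.null(demes)) demes <- paste0("deme", seq_len(nrow(backward)))
  demes <- as.character(demes)
  stopifnot(nrow(backward) == ncol(backward), length(demes) == nrow(backward))
  dimnames(backward) <- list(demes, demes)
  if (any(backward < 0)) stop("migration probabilities must be >= 0", call. = FALSE)
  if (any(abs(rowSums(backward) - 1) > 1e-12))
    stop("backward migration matrix must be row-stochastic", call. = FALSE)
  structure(list(demes = demes, backward = backward, forward = forward,
                 sizes = sizes), class = "migration_model")
}

#' @export
print.migration_model <- function(x, ...) {
  cat("backward migration matrix:\n")
  print(x$backward)
  invisible(x)
}

#' Backward migration matrix from a forward matrix and deme sizes
#'
#' Converts a forward migration matrix (probability of moving from `b` to
#' `a`) and constant local population sizes into the backward matrix
#' `M(a, b) = c(b) * Mf(b, a) / c(a)`, normalising rows.  Constancy of the
#' deme sizes under the forward flow is checked; a violation (population
#' regulation happening after migration) is reported as a warning, not an
#' error.
#'
#' @param forward row-stochastic forward migration matrix.
#' @param sizes strictly positive deme sizes.
#' @param demes optional deme names.
#' @return A `migration_model`.
#' @export
backward_from_forward <- function(forward, sizes, demes = rownames(forward)) {
  forward <- as.matrix(forward)
  if (any(sizes <= 0)) stop("deme sizes must be strictly positive", call. = FALSE)
  if (any(forward < 0) || any(abs(rowSums(forward) - 1) > 1e-12))
    stop("forward migration matrix must be row-stochastic", call. = FALSE)
  if (is.null(demes)) demes <- paste0("deme", seq_len(nrow(forward)))
  inflow <- as.vector(sizes %*% forward)  # sum_b c(b) Mf(b, a)
  if (any(abs(inflow - sizes) > 1e-9 * max(sizes)))
    warning("deme sizes are not constant under the forward flow; ",
            "assuming population regulation after migration and normalising rows",
            call. = FALSE)
  # M[a, b] = c(b) Mf(b, a) / c(a); rows a index the current deme
  M <- sweep(t(forward * sizes), 1, sizes, "/")
  M <- sweep(M, 1, rowSums(M), "/")
  migration_model(M, demes = demes, forward = forward, sizes = sizes)
}

#' Full model for the migration-recombination equation
#'
#' Bundles the type space, the ordered deme set, the recombination
#' distribution on partitions of the full site set, and the backward
#' migration model.
#'
#' @param space a `type_space`.
#' @param migration a `migration_model`.
#' @param recombination a `recomb_dist` on the sites `1..n`.
#' @return Object of class `mr_model`.
#' @export
mr_model <- function(space, migration, recombination) {
  stopifnot(inherits(space, "type_space"), inherits(migration, "migration_model"),
            inherits(recombination, "recomb_dist"))
  if (!identical(recombination$ground, seq_len(space$n)))
    stop("recombination distribution must live on the full site set", call. = FALSE)
  structure(list(space = space, demes = migration$demes, M = migration,
                 r = recombination), class = "mr_model")
}

#' @export
print.mr_model <- function(x, ...) {
  cat(sprintf("migration-recombination model: %d sites, %d demes, support size %d\n",
              x$space$n, length(x$demes), length(x$r$parts)))
  invisible(x)
}

#' Labelled recombinator
#'
#' Applies the labelled recombinator to a metapopulation: the returned
#' measure is the tensor product, over the labelled blocks `(d, l)`, of the
#' `d`-marginal of the deme-`l` population.  It is the type distribution of
#' an offspring whose sites in block `d` descend from a parent sampled at
#' deme `l`.
#'
#' @param bdelta a `labelled_partition` whose ground set equals the sites of
#'   `mu` and whose labels are demes of `mu`.
#' @param mu a `metapopulation`.
#' @return A `pop_measure` over the ground set of `bdelta`.
#' @export
recombinator <- function(bdelta, mu) {
  stopifnot(inherits(bdelta, "labelled_partition"), inherits(mu, "metapopulation"))
  if (!identical(bdelta$ground, mu$sites))
    stop("labelled partition and metapopulation live on different site sets",
         call. = FALSE)
  if (!all(bdelta$labels %in% mu$demes))
    stop("unknown deme label in labelled partition", call. = FALSE)
  measure_product(mapply(function(b, l) marginalise(mu$measures[[l]], b),
                         bdelta$blocks, bdelta$labels, SIMPLIFY = FALSE))
}

#' Unlabelled recombinator
#'
#' Product of the block-marginals of a single population measure: the
#' distribution of an offspring recombined according to `delta` within one
#' deme.
#'
#' @param delta a `site_partition` on the sites of `nu`.
#' @param nu a `pop_measure`.
#' @return A `pop_measure`.
#' @export
recombinator_unlabelled <- function(delta, nu) {
  stopifnot(inherits(delta, "site_partition"), inherits(nu, "pop_measure"))
  if (!identical(delta$ground, nu$sites))
    stop("partition and measure live on different site sets", call. = FALSE)
  measure_product(lapply(delta$blocks, function(b) marginalise(nu, b)))
}

#' Migration-recombination probabilities at a deme
#'
#' The probability of a labelled partition `bdelta` in one backward
#' generation seen from deme `alpha`: the recombination probability of the
#' base times the product over labelled blocks of the backward migration
#' probabilities `M(alpha, label)`.  Sparse over labelled partitions whose
#' base has positive recombination probability; sums to 1 per deme.
#'
#' @param model an `mr_model`.
#' @param alpha deme name.
#' @return Object of class `mr_probs`: parallel lists `states`
#'   (`labelled_partition`s) and `probs`.
#' @export
mr_probabilities <- function(model, alpha) {
  stopifnot(inherits(model, "mr_model"), alpha %in% model$demes)
  labelled_weights(model$r, model$M, alpha)
}

# shared worker: expand a recombination distribution on some ground set into
# the labelled law at deme alpha
labelled_weights <- function(r, M, alpha) {
  demes <- M$demes
  # keep names even when there is a single deme (drop would lose them)
  Mrow <- setNames(as.vector(M$backward[alpha, , drop = FALSE]), demes)
  states <- list(); probs <- numeric(0)
  for (i in seq_along(r$parts)) {
    if (r$probs[i] == 0) next
    p <- r$parts[[i]]
    nb <- length(p$blocks)
    for (lab in label_tuples(demes, nb)) {
      states[[length(states) + 1L]] <-
        structure(list(ground = p$ground, blocks = p$blocks, labels = lab),
                  class = "labelled_partition")
      probs <- c(probs, r$probs[i] * prod(Mrow[lab]))
    }
  }
  structure(list(deme = alpha, states = states, probs = probs,
                 keys = vapply(states, labelled_key, "")),
            class = "mr_probs")
}

#' @export
print.mr_probs <- function(x, ...) {
  cat(sprintf("migration-recombination distribution at deme %s (%d states)\n",
              x$deme, length(x$states)))
  invisible(x)
}

#' Marginal recombination distribution on a site subset
#'
#' `r^U` assigns to each partition of `U` the total probability of all
#' partitions of the full site set that induce it on `U`.  Exact weights are
#' propagated when present.
#'
#' @param r a `recomb_dist`.
#' @param U non-empty subset of the ground set.
#' @return A `recomb_dist` on `U`.
#' @export
marginal_recombination <- function(r, U) {
  stopifnot(inherits(r, "recomb_dist"))
  U <- check_siteset(U)
  if (!all(U %in% r$ground)) stop("U must be a subset of the sites", call. = FALSE)
  if (identical(U, r$ground)) return(r)
  acc <- list()  # key -> list(part, prob, exact)
  for (i in seq_along(r$parts)) {
    ind <- restrict_partition(r$parts[[i]], U)
    key <- partition_key(ind)
    if (is.null(acc[[key]])) {
      acc[[key]] <- list(part = ind, prob = r$probs[i],
                         exact = if (!is.null(r$exact)) r$exact[i])
    } else {
      acc[[key]]$prob <- acc[[key]]$prob + r$probs[i]
      if (!is.null(r$exact)) acc[[key]]$exact <- acc[[key]]$exact + r$exact[i]
    }
  }
  parts <- lapply(acc, `[[`, "part")
  probs <- vapply(acc, `[[`, 1, "prob")
  exact <- NULL
  if (!is.null(r$exact)) {
    nums <- vapply(acc, function(a) a$exact$num, 1)
    dens <- vapply(acc, function(a) a$exact$den, 1)
    exact <- rational(nums, dens)
  }
  recomb_dist(unname(parts), unname(probs), exact)
}

#' Marginal migration-recombination probabilities
#'
#' The one-generation law of the labelled partitioning process restricted to
#' a site subset `U`, using the product form: marginal recombination
#' probability of the base times the migration factors of the labels.  Equals
#' the sum of full-system probabilities over all labelled partitions inducing
#' the given one on `U`.
#'
#' @param model an `mr_model`.
#' @param U non-empty site subset.
#' @param alpha deme name.
#' @param cap cap on the marginal labelled state space.
#' @return An `mr_probs` object over labelled partitions of `U`.
#' @export
marginal_mr_probabilities <- function(model, U, alpha, cap = 2e5) {
  stopifnot(inherits(model, "mr_model"), alpha %in% model$demes)
  rU <- marginal_recombination(model$r, U)
  nlab <- sum(length(model$demes)^vapply(rU$parts, function(p) length(p$blocks), 1L))
  if (nlab > cap)
    stop(sprintf("marginal labelled support has %.0f states, exceeding the cap of %.0f",
                 nlab, cap), call. = FALSE)
  labelled_weights(rU, model$M, alpha)
}
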