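# ---------------------------------------------------------------------------
# Continuous-time variant: recombination happens at per-partition rates and
# migration is driven by a Markov generator N on the demes.  The type
# distribution solves a measure-valued ODE; the backward process is a
# continuous-time labelled partitioning process whose generator acts by
# single-block splits (keeping the label) and single-block relabellings, and
# the solution is obtained from its matrix exponential applied to the
# recombinator vector.
# ---------------------------------------------------------------------------

#' Continuous-time migration-recombination model
#'
#' @param space a `type_space`.
#' @param generator square matrix `N` over the demes: nonnegative
#'   off-diagonals, zero row sums.
#' @param rate_parts list of `site_partition`s of the full site set.
#' @param rates nonnegative recombination rates, one per partition.  A rate
#'   on the one-block partition is accepted but ignored with a note, since
#'   recombining according to it is the identity.
#' @param demes optional deme names (default from the generator dimnames).
#' @return Object of class `ct_model`.
#' @export
ct_model <- function(space, generator, rate_parts, rates, demes = rownames(generator)) {
  stopifnot(inherits(space, "type_space"))
  generator <- as.matrix(generator)
  if (is.null(demes)) demes <- paste0("deme", seq_len(nrow(generator)))
  demes <- as.character(demes)
  stopifnot(nrow(generator) == ncol(generator), length(demes) == nrow(generator))
  dimnames(generator) <- list(demes, demes)
  off <- generator; diag(off) <- 0
  if (any(off < 0)) stop("generator off-diagonals must be >= 0", call. = FALSE)
  if (any(abs(rowSums(generator)) > 1e-12))
    stop("generator rows must sum to 0", call. = FALSE)
  stopifnot(is.list(rate_parts), length(rate_parts) == length(rates))
  if (any(rates < 0)) stop("recombination rates must be >= 0", call. = FALSE)
  ground <- seq_len(space$n)
  for (p in rate_parts)
    if (!identical(p$ground, ground))
      stop("rate partitions must live on the full site set", call. = FALSE)
  key1 <- partition_key(max_partition(ground))
  keys <- vapply(rate_parts, partition_key, "")
  if (any(keys == key1 & rates > 0)) {
    message("rate on the one-block partition is a no-op and is ignored")
    keep <- !(keys == key1)
    rate_parts <- rate_parts[keep]; rates <- rates[keep]; keys <- keys[keep]
  }
  structure(list(space = space, demes = demes, N = generator,
                 rate_parts = rate_parts, rates = as.numeric(rates), keys = keys),
            class = "ct_model")
}

#' @export
print.ct_model <- function(x, ...) {
  cat(sprintf("continuous-time model: %d sites, %d demes, %d rate partitions\n",
              x$space$n, length(x$demes), length(x$rate_parts)))
  invisible(x)
}

# marginal recombination rates on a subset U: rate of inducing each partition
# of U (no normalisation; rates need not sum to anything)
marginal_rates <- function(ctmodel, U) {
  acc_parts <- list(); acc_rates <- numeric(0); acc_keys <- character(0)
  for (i in seq_along(ctmodel$rate_parts)) {
    ind <- restrict_partition(ctmodel$rate_parts[[i]], U)
    key <- partition_key(ind)
    j <- match(key, acc_keys)
    if (is.na(j)) {
      acc_parts[[length(acc_parts) + 1L]] <- ind
      acc_rates <- c(acc_rates, ctmodel$rates[i])
      acc_keys <- c(acc_keys, key)
    } else acc_rates[j] <- acc_rates[j] + ctmodel$rates[i]
  }
  list(parts = acc_parts, rates = acc_rates, keys = acc_keys)
}

#' Right-hand side of the continuous-time dynamics
#'
#' The time derivative of the metapopulation: a migration flow driven by the
#' generator plus, for each partition with positive rate, the difference
#' between the recombined and the current population.  Each component is a
#' signed table summing to zero.
#'
#' @param omega a `metapopulation`.
#' @param ctmodel a `ct_model`.
#' @return Named list of numeric arrays (one signed table per deme).
#' @export
ct_rhs <- function(omega, ctmodel) {
  stopifnot(inherits(omega, "metapopulation"), inherits(ctmodel, "ct_model"))
  out <- lapply(ctmodel$demes, function(a) {
    mig <- Reduce(`+`, mapply(function(w, m) w * m$table,
                              ctmodel$N[a, omega$demes], omega$measures,
                              SIMPLIFY = FALSE))
    rec <- 0
    for (i in seq_along(ctmodel$rate_parts)) {
      delta <- ctmodel$rate_parts[[i]]
      rec <- rec + ctmodel$rates[i] *
        (recombinator_unlabelled(delta, omega$measures[[a]])$table -
           omega$measures[[a]]$table)
    }
    mig + rec
  })
  setNames(out, ctmodel$demes)
}

#' Generator of the continuous-time labelled partitioning process
#'
#' Off-diagonal entries: a single labelled block `(d, l)` is replaced by a
#' proper refinement of `d` with every fragment keeping label `l`, at the
#' marginal recombination rate of that refinement; or exactly one block's
#' label changes from `a` to `b`, at the migration rate `N(a, b)`.  Diagonal
#' entries make rows sum to zero.
#'
#' @param ctmodel a `ct_model`.
#' @param cap cap on the labelled state-space size.
#' @return Object of class `ct_generator`: fields `states`, `keys`,
#'   `matrix`, `demes`.
#' @export
build_generator_Q <- function(ctmodel, cap = 2e5) {
  stopifnot(inherits(ctmodel, "ct_model"))
  ground <- seq_len(ctmodel$space$n)
  states <- enumerate_labelled_partitions(ground, ctmodel$demes, cap = cap)
  keys <- vapply(states, labelled_key, "")
  index <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) index[[keys[i]]] <- i
  ns <- length(states)
  Q <- matrix(0, ns, ns, dimnames = list(keys, keys))
  marg_cache <- new.env(parent = emptyenv())
  get_marg <- function(d) {
    key <- paste(d, collapse = ",")
    if (is.null(marg_cache[[key]])) marg_cache[[key]] <- marginal_rates(ctmodel, d)
    marg_cache[[key]]
  }
  for (i in seq_along(states)) {
    bdelta <- states[[i]]
    for (b in seq_along(bdelta$blocks)) {
      d <- bdelta$blocks[[b]]; l <- bdelta$labels[[b]]
      # splitting transitions: proper refinements of d, fragments keep l
      if (length(d) > 1) {
        marg <- get_marg(d)
        dkey <- partition_key(max_partition(d))
        for (k in seq_along(marg$parts)) {
          if (marg$keys[k] == dkey || marg$rates[k] == 0) next
          frag <- marg$parts[[k]]$blocks
          newb <- c(bdelta$blocks[-b], frag)
          newl <- c(bdelta$labels[-b], rep(l, length(frag)))
          j <- index[[labelled_key(labelled_partition(newb, newl, ground))]]
          Q[i, j] <- Q[i, j] + marg$rates[k]
        }
      }
      # relabelling transitions
      for (bb in ctmodel$demes) {
        if (bb == l || ctmodel$N[l, bb] == 0) next
        newl <- bdelta$labels; newl[b] <- bb
        j <- index[[labelled_key(labelled_partition(bdelta$blocks, newl, ground))]]
        Q[i, j] <- Q[i, j] + ctmodel$N[l, bb]
      }
    }
    Q[i, i] <- Q[i, i] - sum(Q[i, -i])
  }
  structure(list(states = states, keys = keys, matrix = Q, demes = ctmodel$demes),
            class = "ct_generator")
}

#' @export
print.ct_generator <- function(x, ...) {
  cat(sprintf("continuous-time partitioning generator, %d states\n",
              length(x$states)))
  invisible(x)
}

#' Solve the continuous-time dynamics
#'
#' Two routes: `"expm"` applies the matrix exponential of the backward
#' generator to the recombinator vector of the initial state (the Kolmogorov
#' backward solution); `"ode"` integrates the nonlinear right-hand side with
#' an adaptive solver (relative tolerance 1e-9).  The two agree to high
#' accuracy and serve as mutual checks.
#'
#' @param omega0 initial `metapopulation`.
#' @param ctmodel a `ct_model`.
#' @param t time horizon (>= 0).
#' @param method `"expm"` or `"ode"`.
#' @param cap cap on the labelled state-space size (expm route).
#' @return The `metapopulation` at time `t`.
#' @export
ct_solve <- function(omega0, ctmodel, t, method = c("expm", "ode"), cap = 2e5) {
  method <- match.arg(method)
  stopifnot(t >= 0)
  if (method == "expm") {
    Q <- build_generator_Q(ctmodel, cap = cap)
    rv <- recombinator_vector(omega0, states = Q$states, cap = cap)
    E <- as.matrix(Matrix::expm(t * Q$matrix))
    V <- E %*% rv$values
    return(meta_from_vector(V, Q$states, ctmodel$demes, omega0$sites, rv$dims))
  }
  dims <- dim(omega0$measures[[1]]$table)
  if (is.null(dims)) dims <- length(omega0$measures[[1]]$table)
  cell <- prod(dims)
  demes <- ctmodel$demes
  unpack <- function(y) {
    metapopulation(setNames(lapply(seq_along(demes), function(k) {
      new_measure(array(y[(k - 1) * cell + seq_len(cell)], dim = dims), omega0$sites)
    }), demes))
  }
  deriv <- function(time, y, parms) {
    rhs <- ct_rhs(unpack(y), ctmodel)
    list(unlist(lapply(rhs, as.vector), use.names = FALSE))
  }
  y0 <- unlist(lapply(omega0$measures[demes], function(m) as.vector(m$table)),
               use.names = FALSE)
  sol <- deSolve::ode(y = y0, times = c(0, t), func = deriv, parms = NULL,
                      rtol = 1e-9, atol = 1e-12)
  yt <- sol[nrow(sol), -1]
  out <- unpack(as.numeric(yt))
  # clip tiny negative integration residues
  out$measures <- lapply(out$measures, function(m) {
    if (any(m$table < 0)) {
      if (any(m$table < -1e-10))
        warning("negative entries beyond tolerance clipped in ODE solution",
                call. = FALSE)
      m$table <- pmax(m$table, 0)
    }
    m
  })
  out
}

#' Closed-form continuous-time solution for two sites
#'
#' With a single two-site split at rate equal to the singleton-partition
#' rate, the solution splits into the unseparated contribution (migration
#' semigroup for the whole sequence) and an integral over the exponentially
#' distributed splitting time, after which the two sites migrate
#' independently from the deme where the split occurred.  The integral is
#' evaluated by adaptive quadrature (absolute tolerance 1e-9).
#'
#' @param omega0 initial `metapopulation` over two sites.
#' @param ctmodel a `ct_model` with `n = 2`.
#' @param t time horizon.
#' @param alpha deme name.
#' @return The deme-`alpha` population at time `t`, a `pop_measure`.
#' @export
ct_two_site <- function(omega0, ctmodel, t, alpha) {
  if (ctmodel$space$n != 2)
    stop("closed form requires exactly two sites", call. = FALSE)
  stopifnot(alpha %in% ctmodel$demes, t >= 0)
  demes <- ctmodel$demes
  N <- ctmodel$N
  key0 <- partition_key(min_partition(1:2))
  rho0 <- if (key0 %in% ctmodel$keys) ctmodel$rates[match(key0, ctmodel$keys)] else 0
  expN <- local({
    cache <- new.env(parent = emptyenv())
    function(s) {
      key <- sprintf("%.17g", s)
      if (is.null(cache[[key]])) cache[[key]] <- as.matrix(Matrix::expm(s * N))
      cache[[key]]
    }
  })
  m1 <- lapply(omega0$measures, function(m) marginalise(m, 1L)$table)
  m2 <- lapply(omega0$measures, function(m) marginalise(m, 2L)$table)
  Et <- expN(t)
  tab <- exp(-rho0 * t) *
    Reduce(`+`, mapply(function(w, m) w * m$table, Et[alpha, demes],
                       omega0$measures[demes], SIMPLIFY = FALSE))
  if (rho0 > 0 && t > 0) {
    dims <- dim(tab)
    for (c1 in seq_len(dims[1])) for (c2 in seq_len(dims[2])) {
      f <- function(sig) vapply(sig, function(s) {
        E1 <- expN(s); E2 <- expN(t - s)
        total <- 0
        for (g in demes) {
          v1 <- sum(E2[g, demes] * vapply(m1[demes], `[`, 1, c1))
          v2 <- sum(E2[g, demes] * vapply(m2[demes], `[`, 1, c2))
          total <- total + E1[alpha, g] * v1 * v2
        }
        exp(-rho0 * s) * total
      }, 1)
      tab[c1, c2] <- tab[c1, c2] +
        rho0 * stats::integrate(f, 0, t, abs.tol = 1e-9, rel.tol = 1e-9)$value
    }
  }
  dimnames(tab) <- ctmodel$space$alphabets[1:2]
  new_measure(tab, 1:2)
}
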