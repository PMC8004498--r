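# ---------------------------------------------------------------------------
# Limiting and quasi-limiting behaviour.
#
# Under a primitive backward migration matrix and a separating recombination
# distribution, the forward dynamics converges geometrically to spatial
# stationarity and linkage equilibrium: every deme tends to the product of
# the q-mixed one-site marginals of the initial state, q the stationary
# distribution of M.  Conditioned on non-absorption, the unlabelled
# partitioning process settles on the reachable states of maximal sojourn
# probability, with weights given by exponentially discounted hitting times;
# the labelled law factorises into that law times stationary labels.
# ---------------------------------------------------------------------------

#' Primitivity check for a stochastic matrix
#'
#' A nonnegative matrix is primitive iff some power is entrywise positive;
#' for an `L x L` stochastic matrix it suffices to check exponents up to
#' `(L - 1)^2 + 1` (Wielandt's bound).
#'
#' @param M a `migration_model` or a square stochastic matrix.
#' @return List with `primitive` (logical) and `witness` (smallest exponent
#'   with positive power, or `NA`).
#' @export
is_primitive <- function(M) {
  if (inherits(M, "migration_model")) M <- M$backward
  L <- nrow(M)
  bound <- (L - 1L)^2 + 1L
  P <- diag(L)
  for (k in seq_len(bound)) {
    P <- (P %*% M) > 0  # boolean reachability powers, no underflow
    P <- P * 1
    if (all(P > 0)) return(list(primitive = TRUE, witness = k))
  }
  list(primitive = FALSE, witness = NA_integer_)
}

#' Stationary distribution of the backward migration matrix
#'
#' The unique left fixed probability vector `q` with `q^T = q^T M`, which
#' exists and attracts for primitive `M`.
#'
#' @param M a `migration_model` or a square stochastic matrix.
#' @return Named numeric vector `q`.
#' @export
stationary_distribution <- function(M) {
  if (inherits(M, "migration_model")) M <- M$backward
  chk <- is_primitive(M)
  if (!chk$primitive)
    stop("backward migration matrix is not primitive ",
         "(no power is entrywise positive up to the Wielandt bound)", call. = FALSE)
  L <- nrow(M)
  A <- rbind(t(M) - diag(L), rep(1, L))
  b <- c(rep(0, L), 1)
  q <- qr.solve(A, b)
  q <- as.vector(q); q <- q / sum(q)
  setNames(q, rownames(M))
}

#' Separability of a recombination distribution
#'
#' Checks that the meet (coarsest common refinement) of all partitions with
#' positive recombination probability is the partition into singletons, so
#' that every pair of sites is eventually separated and the singleton
#' partition is the unique absorbing state of the partitioning process.
#'
#' @param r a `recomb_dist`.
#' @return List with `separable` (logical) and `clusters` (the blocks of the
#'   meet; site clusters never separated when not separable).
#' @export
check_separability <- function(r) {
  stopifnot(inherits(r, "recomb_dist"))
  support <- r$parts[r$probs > 0]
  m <- Reduce(meet, support)
  list(separable = identical(partition_key(m), partition_key(min_partition(r$ground))),
       clusters = m$blocks)
}

#' Collapse never-separated site clusters into super-sites
#'
#' When the recombination distribution does not separate all sites, the
#' blocks of the meet over its support behave as indivisible units; this
#' utility renames those clusters `1..k` and rewrites the recombination
#' distribution on the reduced site set, so the separability assumption
#' holds by construction on the result.
#'
#' @param r a `recomb_dist`.
#' @return List with `r` (the reduced `recomb_dist`) and `clusters` (list of
#'   original-site vectors, cluster `i` becoming site `i`).
#' @export
collapse_clusters <- function(r) {
  cl <- check_separability(r)$clusters
  k <- length(cl)
  owner <- integer(max(r$ground))
  for (i in seq_len(k)) owner[cl[[i]]] <- i
  parts <- lapply(r$parts, function(p) {
    partition(unname(lapply(p$blocks, function(b) sort(unique(owner[b])))), seq_len(k))
  })
  # merge partitions that became identical
  keys <- vapply(parts, partition_key, "")
  uk <- unique(keys)
  probs <- vapply(uk, function(kk) sum(r$probs[keys == kk]), 1)
  list(r = recomb_dist(parts[match(uk, keys)], unname(probs)), clusters = cl)
}

#' Limit of the migration-recombination dynamics
#'
#' For primitive migration and separating recombination, every deme converges
#' (geometrically, uniformly in the initial state) to the same product
#' measure: the tensor product over sites of the q-mixture of the initial
#' one-site marginals.
#'
#' @param mu0 initial `metapopulation`.
#' @param model an `mr_model`.
#' @return The limiting `metapopulation` (identical across demes).
#' @export
limiting_metapopulation <- function(mu0, model) {
  stopifnot(inherits(mu0, "metapopulation"), inherits(model, "mr_model"))
  sep <- check_separability(model$r)
  if (!sep$separable)
    stop("recombination distribution does not separate all sites; ",
         "collapse the clusters first (see collapse_clusters)", call. = FALSE)
  q <- stationary_distribution(model$M)  # errors if not primitive
  site_marg <- lapply(mu0$sites, function(i) {
    tabs <- lapply(mu0$demes, function(b) q[[b]] * marginalise(mu0$measures[[b]], i)$table)
    new_measure(Reduce(`+`, tabs), i)
  })
  lim <- measure_product(site_marg)
  metapopulation(setNames(lapply(mu0$demes, function(a) lim), mu0$demes))
}

#' Fit a geometric decay rate to a positive sequence
#'
#' Log-linear least-squares fit `log x_t ~ t` over the entries above a floor;
#' used to verify the geometric convergence of solver distances.
#'
#' @param x positive numeric sequence (e.g. sup-norm distances per
#'   generation).
#' @param floor entries at or below this are dropped (numerical noise).
#' @return List with `gamma` (`exp(slope)`) and `slope`.
#' @export
fit_geometric_rate <- function(x, floor = 1e-14) {
  t <- seq_along(x)
  keep <- x > floor
  if (sum(keep) < 3) stop("too few positive entries to fit a rate", call. = FALSE)
  fit <- stats::lm(log(x[keep]) ~ t[keep])
  slope <- unname(stats::coef(fit)[2])
  list(gamma = exp(slope), slope = slope)
}

# indices of states reachable from `start` in the positive-entry digraph of
# an unlabelled transition matrix
reachable_indices <- function(Tul, start_idx) {
  n <- length(Tul$states)
  seen <- rep(FALSE, n)
  queue <- start_idx
  seen[start_idx] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nxt <- which(Tul$matrix[i, ] > 0 & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  which(seen)
}

resolve_start <- function(Tul, start) {
  if (inherits(start, "site_partition")) start <- partition_key(start)
  idx <- match(start, Tul$keys)
  if (is.na(idx)) stop("start partition not found in the state space", call. = FALSE)
  idx
}

as_Tul <- function(r, cap = 10L) {
  if (inherits(r, "unlabelled_T")) r else build_T_unlabelled(r, cap = cap)
}

#' Partitions reachable by the unlabelled partitioning process
#'
#' Graph search on the positive-entry digraph of the unlabelled transition
#' matrix from a start partition (the start itself is reachable in zero
#' steps).
#'
#' @param r a `recomb_dist` or a prebuilt `unlabelled_T`.
#' @param start a `site_partition` or its canonical key; defaults to the
#'   one-block partition.
#' @return List with `states` (list of `site_partition`), `keys` and
#'   `indices` (positions in the canonical enumeration).
#' @export
reachable_states <- function(r, start = NULL) {
  Tul <- as_Tul(r)
  if (is.null(start)) start <- max_partition(Tul$states[[1]]$ground)
  idx <- reachable_indices(Tul, resolve_start(Tul, start))
  list(states = Tul$states[idx], keys = Tul$keys[idx], indices = idx)
}

#' Maximal sojourn probability and its attaining states
#'
#' Among the reachable, non-absorbed states of the unlabelled partitioning
#' process, `eta` is the largest diagonal entry of the transition matrix and
#' `F` the set of states attaining it; `eta_prime` is the largest sojourn
#' outside `F` and the absorbing state.  The defining property of `F` (a
#' member can only stay put or absorb in one step) is verified and an error
#' is raised if it fails, which would indicate an inconsistent transition
#' matrix.
#'
#' @param r a `recomb_dist` or `unlabelled_T`.
#' @param start start partition (default: one-block partition).
#' @return List with `eta`, `F_keys`, `F_states`, `eta_prime` (`NA` when no
#'   reachable state lies outside `F` and the absorbing state), and, when
#'   exact arithmetic is available, `eta_exact` (a `rational`).
#' @export
sojourn_eta_F <- function(r, start = NULL) {
  Tul <- as_Tul(r)
  ground <- Tul$states[[1]]$ground
  key0 <- partition_key(min_partition(ground))
  if (is.null(start)) start <- max_partition(ground)
  idx <- reachable_indices(Tul, resolve_start(Tul, start))
  live <- idx[Tul$keys[idx] != key0]
  if (length(live) == 0)
    stop("all recombination mass is on the singleton partition; ",
         "the conditioned process is not defined", call. = FALSE)
  d <- diag(Tul$matrix)[live]
  if (max(d) == 0)
    stop("every reachable state absorbs immediately; ",
         "the conditioned process is not defined", call. = FALSE)
  eta <- max(d)
  Fidx <- live[d == eta]
  # exact tie-breaking when available
  eta_exact <- NULL
  if (!is.null(Tul$exact_num)) {
    dn <- diag(Tul$exact_num)[live]; dd <- diag(Tul$exact_den)[live]
    best <- 1L
    for (i in seq_along(live))
      if (dn[i] * dd[best] > dn[best] * dd[i]) best <- i
    eta_exact <- rational(dn[best], dd[best])
    Fidx <- live[dn * dd[best] == dn[best] * dd]
    eta <- as.numeric(eta_exact)
  }
  # Every maximal-sojourn state may only stay put or absorb in one step.
  i0 <- match(key0, Tul$keys)
  for (i in Fidx) {
    if (abs(Tul$matrix[i, i] + Tul$matrix[i, i0] - 1) > 1e-12)
      stop("internal error: a maximal-sojourn state admits a proper ",
           "non-absorbing refinement", call. = FALSE)
  }
  rest <- setdiff(live, Fidx)
  eta_prime <- if (length(rest)) max(diag(Tul$matrix)[rest]) else NA_real_
  out <- list(eta = eta, F_keys = Tul$keys[Fidx], F_states = Tul$states[Fidx],
              F_indices = Fidx, eta_prime = eta_prime)
  if (!is.null(eta_exact)) out$eta_exact <- eta_exact
  out
}

#' Quasi-limiting law of the unlabelled partitioning process
#'
#' The limit of the conditional law of the state given non-absorption.  It is
#' supported on the reachable states of maximal sojourn probability `eta`,
#' with weights proportional to the exponentially discounted hitting-time
#' transforms `E[eta^(-tau_delta); tau_delta < infinity]`, computed exactly
#' by a linear solve in reverse refinement order (the chain only refines, so
#' the system is triangular along any linear extension of the order).
#'
#' @param r a `recomb_dist` or `unlabelled_T`; the singleton partition must
#'   not carry all the recombination mass.
#' @param start start partition (default: one-block partition).
#' @return Object of class `qlim_law`: fields `eta`, `F_keys`, `law` (named
#'   probability vector over the canonical keys of the support) and
#'   `eta_prime`.
#' @export
qlim_unlabelled <- function(r, start = NULL) {
  Tul <- as_Tul(r)
  ground <- Tul$states[[1]]$ground
  if (is.null(start)) start <- max_partition(ground)
  start_idx <- resolve_start(Tul, start)
  info <- sojourn_eta_F(Tul, start)
  eta <- info$eta
  idx <- reachable_indices(Tul, start_idx)
  key0 <- partition_key(min_partition(ground))
  h_start <- setNames(numeric(length(info$F_indices)), info$F_keys)
  for (fi in seq_along(info$F_indices)) {
    target <- info$F_indices[fi]
    # states that can reach the target, searched on the reversed digraph
    can_reach <- rep(FALSE, length(Tul$states))
    can_reach[target] <- TRUE
    repeat {
      new <- which(!can_reach & (Tul$matrix[, can_reach, drop = FALSE] > 0) %*%
                     rep(1, sum(can_reach)) > 0)
      if (!length(new)) break
      can_reach[new] <- TRUE
    }
    # process in reverse refinement (finer states first): sort by number of
    # blocks, decreasing
    ord <- idx[order(vapply(Tul$states[idx], function(s) length(s$blocks), 1L),
                     decreasing = TRUE)]
    h <- setNames(rep(0, length(Tul$states)), Tul$keys)
    h[target] <- 1
    for (i in ord) {
      if (i == target || !can_reach[i]) next
      num <- sum(Tul$matrix[i, -i] * h[-i]) / eta
      denom <- 1 - Tul$matrix[i, i] / eta
      if (denom <= 0)
        stop("internal error: an intermediate state has sojourn probability ",
             ">= eta; maximal-sojourn bookkeeping is inconsistent", call. = FALSE)
      h[i] <- num / denom
    }
    h_start[fi] <- h[start_idx]
  }
  law <- h_start / sum(h_start)
  structure(list(eta = eta, F_keys = info$F_keys, F_states = info$F_states,
                 law = law, eta_prime = info$eta_prime),
            class = "qlim_law")
}

#' @export
print.qlim_law <- function(x, ...) {
  cat(sprintf("quasi-limiting law (eta = %.6g) on %d maximal-sojourn states\n",
              x$eta, length(x$law)))
  print(x$law)
  invisible(x)
}

#' Exact conditional law of the unlabelled process given non-absorption
#'
#' Computes the distribution of the state at generation `t` conditioned on
#' the base not having fragmented into singletons, by powering the
#' substochastic restriction of the transition matrix to the non-absorbed
#' states and normalising.
#'
#' @param r a `recomb_dist` or `unlabelled_T`.
#' @param start start partition (default: one-block partition).
#' @param t generation (non-negative integer).
#' @return Named probability vector over the canonical keys of the
#'   non-absorbed states.
#' @export
conditional_law_exact <- function(r, start = NULL, t = 0) {
  stopifnot(t >= 0, t == round(t))
  Tul <- as_Tul(r)
  ground <- Tul$states[[1]]$ground
  if (is.null(start)) start <- max_partition(ground)
  start_idx <- resolve_start(Tul, start)
  key0 <- partition_key(min_partition(ground))
  live <- which(Tul$keys != key0)
  if (!(start_idx %in% live))
    stop("start state is already absorbed", call. = FALSE)
  S <- Tul$matrix[live, live, drop = FALSE]
  v <- numeric(length(live)); v[match(start_idx, live)] <- 1
  if (t > 0) for (s in seq_len(t)) v <- as.vector(v %*% S)
  total <- sum(v)
  if (total <= 0)
    stop("probability of non-absorption at this horizon is zero", call. = FALSE)
  setNames(v / total, Tul$keys[live])
}

#' Quasi-limiting law of the labelled partitioning process
#'
#' The conditional law of the labelled state given non-absorption converges
#' to a product: the quasi-limiting law of the base times, independently for
#' each block, the stationary migration distribution of its label.
#'
#' @param model an `mr_model` with primitive migration.
#' @param start_deme deme labelling the one-block start state (the base
#'   quasi-limit does not depend on it; kept for the start-state interface).
#' @return Object of class `qlim_labelled_law`: fields `eta`, `q`,
#'   `unlabelled` (a `qlim_law`), `states` (list of `labelled_partition`s
#'   supported) and `law` (named probability vector).
#' @export
qlim_labelled <- function(model, start_deme = model$demes[1]) {
  stopifnot(inherits(model, "mr_model"), start_deme %in% model$demes)
  q <- stationary_distribution(model$M)
  ul <- qlim_unlabelled(model$r, max_partition(seq_len(model$space$n)))
  states <- list(); probs <- numeric(0)
  for (fi in seq_along(ul$F_states)) {
    base <- ul$F_states[[fi]]
    for (lab in label_tuples(model$demes, length(base$blocks))) {
      states[[length(states) + 1L]] <-
        structure(list(ground = base$ground, blocks = base$blocks, labels = lab),
                  class = "labelled_partition")
      probs <- c(probs, ul$law[[fi]] * prod(q[lab]))
    }
  }
  structure(list(eta = ul$eta, q = q, unlabelled = ul, states = states,
                 law = setNames(probs, vapply(states, labelled_key, ""))),
            class = "qlim_labelled_law")
}

#' @export
print.qlim_labelled_law <- function(x, ...) {
  cat(sprintf("labelled quasi-limiting law on %d states (eta = %.6g)\n",
              length(x$states), x$eta))
  invisible(x)
}
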