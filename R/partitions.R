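# ---------------------------------------------------------------------------
# Set partitions and deme-labelled set partitions of a finite site set.
#
# Canonical form used throughout: sites within a block ascending, blocks
# ordered by their smallest element, ground set ascending.  All state
# indexing (transition matrices, enumeration order) relies on this form.
# ---------------------------------------------------------------------------

check_siteset <- function(sites, allow_empty = FALSE) {
  if (length(sites) == 0) {
    if (allow_empty) return(integer(0))
    stop("site set must be non-empty", call. = FALSE)
  }
  s <- as.integer(sites)
  if (anyNA(s) || any(s < 1L)) stop("sites must be positive integers", call. = FALSE)
  s <- sort(s)
  if (anyDuplicated(s)) stop("sites must be distinct", call. = FALSE)
  s
}

#' Construct a set partition of a site set
#'
#' A partition of a finite set of (1-based) sequence sites into disjoint,
#' non-empty blocks.  Blocks are brought into canonical form: sites ascending
#' within blocks, blocks ordered by smallest element.  Equality of partitions
#' is equality of canonical forms.
#'
#' @param blocks list of integer vectors, the blocks.
#' @param ground optional integer vector of sites; defaults to the union of
#'   the blocks.  If supplied, the blocks must partition exactly this set.
#' @return An object of class `site_partition` with fields `ground` and
#'   `blocks`.
#' @examples
#' partition(list(c(1, 2), c(3, 4)))
#' @export
partition <- function(blocks, ground = NULL) {
  if (!is.list(blocks) || length(blocks) == 0)
    stop("blocks must be a non-empty list", call. = FALSE)
  blocks <- lapply(blocks, check_siteset)
  all_sites <- sort(unlist(blocks, use.names = FALSE))
  if (anyDuplicated(all_sites))
    stop("blocks must be pairwise disjoint", call. = FALSE)
  if (is.null(ground)) {
    ground <- all_sites
  } else {
    ground <- check_siteset(ground)
    if (!identical(all_sites, ground))
      stop("blocks must cover the ground set exactly", call. = FALSE)
  }
  blocks <- blocks[order(vapply(blocks, min, 1L))]
  structure(list(ground = ground, blocks = blocks), class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.site_partition <- function(x, ...) {
  paste0("{", paste(vapply(x$blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
                           ""), collapse = ""), "}")
}

#' Construct a deme-labelled partition
#'
#' A partition of a site set whose blocks each carry a deme label.  The base
#' (labels stripped) must be a valid partition; distinct blocks may carry
#' equal labels.  Canonical block order is that of the base.
#'
#' @param blocks list of integer vectors (the blocks).
#' @param labels character vector of deme names, one per block.
#' @param ground optional ground set, as in [partition()].
#' @return An object of class `labelled_partition` with fields `ground`,
#'   `blocks` and `labels`.
#' @examples
#' labelled_partition(list(c(1, 2), 3), c("a", "b"))
#' @export
labelled_partition <- function(blocks, labels, ground = NULL) {
  if (length(labels) != length(blocks))
    stop("need one label per block", call. = FALSE)
  base <- partition(blocks, ground)
  # reorder labels to follow the canonicalised block order
  mins_in <- vapply(lapply(blocks, check_siteset), min, 1L)
  labels <- as.character(labels)[order(mins_in)]
  structure(list(ground = base$ground, blocks = base$blocks, labels = labels),
            class = "labelled_partition")
}

#' @export
print.labelled_partition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.labelled_partition <- function(x, ...) {
  paste0("{", paste(mapply(function(b, l) paste0("({", paste(b, collapse = ","), "},", l, ")"),
                           x$blocks, x$labels), collapse = ""), "}")
}

#' Base (unlabelled) partition of a labelled partition
#' @param bdelta a `labelled_partition`.
#' @return The underlying `site_partition`.
#' @export
partition_base <- function(bdelta) {
  stopifnot(inherits(bdelta, "labelled_partition"))
  structure(list(ground = bdelta$ground, blocks = bdelta$blocks),
            class = "site_partition")
}

# canonical string keys, used for hashing states into matrix indices
partition_key <- function(delta) {
  paste(vapply(delta$blocks, function(b) paste(b, collapse = ","), ""), collapse = "|")
}

labelled_key <- function(bdelta) {
  paste(mapply(function(b, l) paste0(paste(b, collapse = ","), ":", l),
               bdelta$blocks, bdelta$labels), collapse = "|")
}

#' Finest and coarsest partitions of a ground set
#'
#' @param ground integer vector of sites.
#' @return `min_partition()` returns the partition into singletons;
#'   `max_partition()` the one-block partition.
#' @export
min_partition <- function(ground) {
  ground <- check_siteset(ground)
  partition(as.list(ground), ground)
}

#' @rdname min_partition
#' @export
max_partition <- function(ground) {
  ground <- check_siteset(ground)
  partition(list(ground), ground)
}

#' @rdname min_partition
#' @param label deme name attached to the single block.
#' @export
max_labelled_partition <- function(ground, label) {
  ground <- check_siteset(ground)
  labelled_partition(list(ground), label, ground)
}

#' Enumerate all partitions of a site set
#'
#' Enumerates the full partition lattice of a ground set in restricted-growth
#' string order, which is deterministic and stable; the count is the Bell
#' number of the ground-set size.
#'
#' @param ground integer vector of sites.
#' @param cap maximum allowed ground-set size (guards the exponential state
#'   space); exceeding it is an error, never silent truncation.
#' @return List of `site_partition` objects.
#' @examples
#' length(enumerate_partitions(1:4)) # 15
#' @export
enumerate_partitions <- function(ground, cap = 10L) {
  ground <- check_siteset(ground)
  n <- length(ground)
  if (n > cap)
    stop(sprintf("ground set has %d sites, exceeding the cap of %d", n, cap),
         call. = FALSE)
  rgs <- rgs_enumerate(n)
  lapply(rgs, function(code) {
    blocks <- split(ground, code)
    partition(unname(blocks), ground)
  })
}

# all restricted growth strings of length n, lexicographic order
rgs_enumerate <- function(n) {
  out <- vector("list", 0)
  code <- integer(n)  # a_1 = 0
  repeat {
    out[[length(out) + 1L]] <- code + 1L
    # advance to next RGS in lexicographic order
    i <- n
    while (i > 1L) {
      m <- max(code[seq_len(i - 1L)])
      if (code[i] <= m) break
      i <- i - 1L
    }
    if (i == 1L) break
    code[i] <- code[i] + 1L
    if (i < n) code[(i + 1L):n] <- 0L
  }
  out
}

#' Enumerate all labelled partitions of a site set
#'
#' For each partition of the ground set (in restricted-growth order) all
#' assignments of deme labels to its blocks are produced, label tuples in
#' lexicographic order with respect to the declared deme order (first block
#' most significant).  The count is the sum over partitions of
#' `|demes|^(number of blocks)`.
#'
#' @param ground integer vector of sites.
#' @param demes character vector of deme names, in declaration order.
#' @param cap maximum number of labelled partitions allowed.
#' @return List of `labelled_partition` objects.
#' @export
enumerate_labelled_partitions <- function(ground, demes, cap = 2e5) {
  ground <- check_siteset(ground)
  demes <- as.character(demes)
  if (length(demes) < 1) stop("need at least one deme", call. = FALSE)
  parts <- enumerate_partitions(ground)
  total <- sum(length(demes)^vapply(parts, function(p) length(p$blocks), 1L))
  if (total > cap)
    stop(sprintf("labelled state space has %.0f elements, exceeding the cap of %.0f",
                 total, cap), call. = FALSE)
  out <- vector("list", total)
  k <- 0L
  for (p in parts) {
    nb <- length(p$blocks)
    for (lab in label_tuples(demes, nb)) {
      k <- k + 1L
      out[[k]] <- structure(list(ground = p$ground, blocks = p$blocks, labels = lab),
                            class = "labelled_partition")
    }
  }
  out
}

# all |demes|^k label tuples, lexicographic (first position most significant)
label_tuples <- function(demes, k) {
  if (k == 0L) return(list(character(0)))
  idx <- rev(expand.grid(rev(replicate(k, seq_along(demes), simplify = FALSE))))
  lapply(seq_len(nrow(idx)), function(i) demes[as.integer(idx[i, ])])
}

same_ground <- function(a, b) {
  if (!identical(a$ground, b$ground))
    stop("partitions are defined on different ground sets", call. = FALSE)
  invisible(TRUE)
}

#' Coarsest common refinement (meet) of two partitions
#'
#' The meet in the partition lattice: its blocks are all non-empty pairwise
#' intersections of blocks of the two arguments.
#'
#' @param delta,epsilon `site_partition` objects on the same ground set.
#' @return Their meet, a `site_partition`.
#' @examples
#' meet(partition(list(c(1, 2), c(3, 4))), partition(list(c(1, 3), c(2, 4))))
#' @export
meet <- function(delta, epsilon) {
  stopifnot(inherits(delta, "site_partition"), inherits(epsilon, "site_partition"))
  same_ground(delta, epsilon)
  blocks <- list()
  for (d in delta$blocks) for (e in epsilon$blocks) {
    x <- intersect(d, e)
    if (length(x)) blocks[[length(blocks) + 1L]] <- x
  }
  partition(blocks, delta$ground)
}

#' Refinement order on (labelled) partitions
#'
#' Tests whether `epsilon` is finer than `delta`, i.e. every block of
#' `epsilon` is contained in some block of `delta`.  For labelled partitions
#' only the bases are compared.
#'
#' @param epsilon,delta partitions (labelled or not) on the same ground set.
#' @return Logical scalar.
#' @export
is_finer <- function(epsilon, delta) {
  if (inherits(epsilon, "labelled_partition")) epsilon <- partition_base(epsilon)
  if (inherits(delta, "labelled_partition")) delta <- partition_base(delta)
  stopifnot(inherits(epsilon, "site_partition"), inherits(delta, "site_partition"))
  same_ground(epsilon, delta)
  # map each site to its delta-block id, then check each epsilon block is
  # contained in a single delta block
  owner <- integer(max(delta$ground))
  for (i in seq_along(delta$blocks)) owner[delta$blocks[[i]]] <- i
  for (e in epsilon$blocks) if (length(unique(owner[e])) > 1L) return(FALSE)
  TRUE
}

#' Induced partition on a subset of sites
#'
#' Restricts a (labelled) partition to a non-empty subset `V` of its ground
#' set: the blocks are the non-empty intersections with `V`; in the labelled
#' case each surviving block inherits the label of its originating block.
#'
#' @param delta a `site_partition` or `labelled_partition`.
#' @param V integer vector, non-empty subset of the ground set.
#' @return Partition of `V` of the same kind as the input.
#' @export
restrict_partition <- function(delta, V) {
  V <- check_siteset(V)
  if (!all(V %in% delta$ground))
    stop("V must be a subset of the ground set", call. = FALSE)
  keep_blocks <- list(); keep_labels <- character(0)
  labelled <- inherits(delta, "labelled_partition")
  for (i in seq_along(delta$blocks)) {
    x <- intersect(delta$blocks[[i]], V)
    if (length(x)) {
      keep_blocks[[length(keep_blocks) + 1L]] <- x
      if (labelled) keep_labels <- c(keep_labels, delta$labels[[i]])
    }
  }
  if (labelled) labelled_partition(keep_blocks, keep_labels, V)
  else partition(keep_blocks, V)
}

#' Union of labelled partitions of disjoint site sets
#'
#' Concatenates labelled partitions defined over pairwise disjoint grounds
#' into one labelled partition of the union.  Restricting the result to each
#' input ground recovers that input exactly.
#'
#' @param parts list of `labelled_partition` objects with pairwise disjoint
#'   grounds.
#' @return A `labelled_partition` of the union of the grounds.
#' @export
union_labelled <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1,
            all(vapply(parts, inherits, TRUE, "labelled_partition")))
  grounds <- unlist(lapply(parts, `[[`, "ground"))
  if (anyDuplicated(grounds))
    stop("grounds must be pairwise disjoint", call. = FALSE)
  blocks <- do.call(c, lapply(parts, `[[`, "blocks"))
  labels <- do.call(c, lapply(parts, `[[`, "labels"))
  labelled_partition(blocks, labels)
}

# --- text serialisation -----------------------------------------------------

#' Serialise / deserialise partitions as plain lists
#'
#' The text form of a partition is a list of sorted 1-based integer site
#' lists; a labelled partition is a list of `{block, label}` records.  These
#' are the forms used in model configuration files and JSON output.
#'
#' @param x a `site_partition` or `labelled_partition`.
#' @return `partition_to_list()` returns a plain list; the `from` functions
#'   rebuild the objects.
#' @export
partition_to_list <- function(x) {
  if (inherits(x, "labelled_partition"))
    return(mapply(function(b, l) list(block = as.integer(b), label = l),
                  x$blocks, x$labels, SIMPLIFY = FALSE))
  lapply(x$blocks, as.integer)
}

#' @rdname partition_to_list
#' @param blocks plain-list form, as produced by `partition_to_list()`.
#' @param ground optional ground set.
#' @export
partition_from_list <- function(blocks, ground = NULL) {
  if (length(blocks) && is.list(blocks[[1]]) && !is.null(blocks[[1]]$block))
    return(labelled_partition(lapply(blocks, `[[`, "block"),
                              vapply(blocks, `[[`, "", "label"), ground))
  partition(blocks, ground)
}
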