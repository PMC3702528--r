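#' @import methods
#' @importFrom stats setNames
NULL

#' Partition of traits into unassociated / direct / indirect categories
#'
#' A `Partition` assigns each of `d` phenotypes to exactly one of three
#' categories with respect to a genetic variant: `U` (unassociated), `D`
#' (directly associated) or `I` (indirectly associated, i.e. associated with
#' genotype only through the directly associated phenotypes). Indirect
#' associations require a mediator, so a partition with empty `D` must also
#' have empty `I`; the partition with all traits in `U` is the global null.
#'
#' @slot U integer vector of trait indices (1-based) that are unassociated.
#' @slot D integer vector of directly associated trait indices.
#' @slot I integer vector of indirectly associated trait indices.
#' @slot d single integer, the total number of traits.
#'
#' @seealso [enumeratePartitions()], [partitionPrior()]
#' @export
setClass("Partition",
  representation(U = "integer", D = "integer", I = "integer", d = "integer"),
  validity = function(object) {
    d <- object@d
    if (length(d) != 1L || is.na(d) || d < 1L)
      return("d must be a single positive integer")
    all_idx <- sort(c(object@U, object@D, object@I))
    if (!identical(all_idx, seq_len(d)))
      return("U, D, I must be disjoint and cover 1..d exactly once")
    if (length(object@D) == 0L && length(object@I) > 0L)
      return("indirect associations require a non-empty direct set")
    TRUE
  }
)

#' Create a Partition
#'
#' @param d number of traits.
#' @param D integer vector of directly associated trait indices (may be empty).
#' @param I integer vector of indirectly associated trait indices (may be
#'   empty). All remaining traits are placed in `U`.
#' @return A [Partition-class] object.
#' @examples
#' Partition(4, D = c(1, 3), I = 2)
#' @export
Partition <- function(d, D = integer(0), I = integer(0)) {
  d <- as.integer(d)
  D <- sort(unique(as.integer(D)))
  I <- sort(unique(as.integer(I)))
  if (length(intersect(D, I)))
    stop("D and I overlap: ", paste(intersect(D, I), collapse = ","))
  if (length(c(D, I)) && (min(c(D, I)) < 1L || max(c(D, I)) > d))
    stop("trait indices must lie in 1..d")
  U <- setdiff(seq_len(d), c(D, I))
  new("Partition", U = as.integer(U), D = D, I = I, d = d)
}

#' @describeIn Partition-class number of directly associated traits
#' @param x,object a `Partition`.
#' @export
setGeneric("nDirect", function(x) standardGeneric("nDirect"))
#' @rdname Partition-class
#' @export
setMethod("nDirect", "Partition", function(x) length(x@D))

#' @describeIn Partition-class number of associated traits (direct + indirect)
#' @export
setGeneric("nAssociated", function(x) standardGeneric("nAssociated"))
#' @rdname Partition-class
#' @export
setMethod("nAssociated", "Partition", function(x) length(x@D) + length(x@I))

#' @describeIn Partition-class TRUE for the global-null partition (all traits
#'   unassociated)
#' @export
setGeneric("isGlobalNull", function(x) standardGeneric("isGlobalNull"))
#' @rdname Partition-class
#' @export
setMethod("isGlobalNull", "Partition", function(x) nAssociated(x) == 0L)

#' @describeIn Partition-class character vector of per-trait categories
#'   (`"U"`, `"D"` or `"I"`)
#' @export
setGeneric("traitCategories", function(x) standardGeneric("traitCategories"))
#' @rdname Partition-class
#' @export
setMethod("traitCategories", "Partition", function(x) {
  out <- rep("U", x@d)
  out[x@D] <- "D"
  out[x@I] <- "I"
  out
})

setMethod("show", "Partition", function(object) {
  cat("Partition (d = ", object@d, "): ", formatPartition(object), "\n",
      sep = "")
})

#' Serialize / parse partitions
#'
#' Partitions are written as e.g. `"D:1,3|I:2|U:4"`; empty categories are
#' omitted and the global null is written `"NULL"`. This string form is used
#' in all tabular outputs and prior-weight override files.
#'
#' @param x a [Partition-class].
#' @return `formatPartition` returns a character scalar; `parsePartition`
#'   returns a `Partition`.
#' @examples
#' parsePartition(formatPartition(Partition(3, D = 2, I = 3)), d = 3)
#' @export
formatPartition <- function(x) {
  stopifnot(is(x, "Partition"))
  if (isGlobalNull(x)) return("NULL")
  parts <- character(0)
  if (length(x@D)) parts <- c(parts, paste0("D:", paste(x@D, collapse = ",")))
  if (length(x@I)) parts <- c(parts, paste0("I:", paste(x@I, collapse = ",")))
  if (length(x@U)) parts <- c(parts, paste0("U:", paste(x@U, collapse = ",")))
  paste(parts, collapse = "|")
}

#' @rdname formatPartition
#' @param string partition string such as `"D:1|I:2|U:3"` or `"NULL"`.
#' @param d number of traits.
#' @export
parsePartition <- function(string, d) {
  string <- trimws(string)
  if (identical(toupper(string), "NULL")) return(Partition(d))
  fields <- strsplit(string, "|", fixed = TRUE)[[1]]
  sets <- list(D = integer(0), I = integer(0), U = integer(0))
  for (f in fields) {
    kv <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !kv[1] %in% names(sets))
      stop("malformed partition string: ", string)
    sets[[kv[1]]] <- as.integer(strsplit(kv[2], ",", fixed = TRUE)[[1]])
  }
  p <- Partition(d, D = sets$D, I = sets$I)
  if (!setequal(p@U, sets$U) && length(sets$U))
    stop("U set inconsistent with d in: ", string)
  p
}

.partition_cap <- 15L

#' Enumerate all valid partitions of d traits
#'
#' Produces every assignment of `d` traits to (U, D, I) that satisfies the
#' structural constraint (no indirect associations without a direct one),
#' in a deterministic canonical order: increasing number of associated traits,
#' then increasing number of direct traits, then lexicographically by the
#' direct and indirect member lists. The global null is always first.
#'
#' Exhaustive enumeration is refused for `d > 15`, where the number of
#' partitions (`3^d - 2^d + 1`) makes it impractical.
#'
#' @param d number of traits (1 to 15).
#' @return A list of [Partition-class] objects of length [countPartitions()].
#' @examples
#' length(enumeratePartitions(4)) # 66
#' @export
enumeratePartitions <- function(d) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L || d > .partition_cap)
    stop("d must be an integer in 1..", .partition_cap)
  out <- list(Partition(d))
  traits <- seq_len(d)
  for (p in seq_len(d)) {          # number of associated traits
    assoc_sets <- utils::combn(d, p, simplify = FALSE)
    for (q in seq_len(p)) {        # number of direct traits
      for (A in assoc_sets) {
        d_sets <- utils::combn(p, q, simplify = FALSE)
        for (ds in d_sets) {
          out[[length(out) + 1L]] <- Partition(d, D = A[ds],
                                               I = A[-ds])
        }
      }
    }
  }
  # canonical order: (p, q, lexicographic D then I)
  key <- vapply(out, function(g) {
    sprintf("%02d|%02d|%s|%s", nAssociated(g), nDirect(g),
            paste(sprintf("%02d", g@D), collapse = ","),
            paste(sprintf("%02d", g@I), collapse = ","))
  }, character(1))
  out[order(key)]
}

#' Count valid partitions
#'
#' Closed form `3^d - 2^d + 1`: of the `3^d` assignments of traits to
#' three categories, the `2^d` with empty direct set are invalid except the
#' all-unassociated global null.
#'
#' @inheritParams enumeratePartitions
#' @return integer count, equal to `length(enumeratePartitions(d))`.
#' @export
countPartitions <- function(d) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L || d > .partition_cap)
    stop("d must be an integer in 1..", .partition_cap)
  as.integer(3^d - 2^d + 1)
}

#' Prior distribution over partitions
#'
#' Holds the prior probability `pi0` of the global null together with
#' normalized weights over the non-null partitions.
#'
#' @slot pi0 prior probability of the global null.
#' @slot partitions list of non-null [Partition-class] objects.
#' @slot weights numeric vector of non-negative weights summing to 1,
#'   aligned with `partitions`.
#' @export
setClass("PartitionPrior",
  representation(pi0 = "numeric", partitions = "list", weights = "numeric"),
  validity = function(object) {
    if (length(object@pi0) != 1L || object@pi0 < 0 || object@pi0 > 1)
      return("pi0 must be a probability")
    if (length(object@partitions) != length(object@weights))
      return("weights and partitions must align")
    if (any(object@weights < 0))
      return("weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-8)
      return("weights must sum to 1")
    if (any(vapply(object@partitions, isGlobalNull, logical(1))))
      return("partitions must all be non-null")
    TRUE
  }
)

setMethod("show", "PartitionPrior", function(object) {
  cat("PartitionPrior: pi0 =", object@pi0, "over",
      length(object@partitions), "non-null partitions\n")
  k <- order(object@weights, decreasing = TRUE)[seq_len(min(5, length(object@weights)))]
  for (i in k)
    cat(sprintf("  %-30s %.4g\n", formatPartition(object@partitions[[i]]),
                object@weights[i]))
})

#' Default hierarchical-uniform prior on partitions
#'
#' Conditional on at least one trait being associated, the number of
#' associated traits `p` is uniform on `1..d`; given `p`, the number of
#' directly associated traits `q` is uniform on `1..p`; given `(p, q)` all
#' partitions with those counts are equally likely. The construction is
#' exchangeable in the trait labels, and the implied prior probability that
#' any particular trait is associated (given non-null) is `(d+1)/(2d)`.
#'
#' @param d number of traits.
#' @param pi0 prior probability of the global null. `pi0 = 1` is permitted
#'   (with a warning) for degenerate testing setups.
#' @return A [PartitionPrior-class].
#' @examples
#' partitionPrior(2, pi0 = 0.5)
#' @export
partitionPrior <- function(d, pi0 = 0.5) {
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
  if (pi0 == 1) warning("degenerate prior: all mass on the global null")
  parts <- enumeratePartitions(d)
  parts <- parts[!vapply(parts, isGlobalNull, logical(1))]
  w <- vapply(parts, function(g) {
    p <- nAssociated(g); q <- nDirect(g)
    (1 / d) * (1 / p) / (choose(d, p) * choose(p, q))
  }, numeric(1))
  new("PartitionPrior", pi0 = pi0, partitions = parts, weights = w / sum(w))
}

#' Build a PartitionPrior from explicit weights
#'
#' @param partitions list of non-null [Partition-class] objects.
#' @param weights non-negative weights (normalized internally).
#' @param pi0 prior probability of the global null.
#' @return A [PartitionPrior-class].
#' @export
customPartitionPrior <- function(partitions, weights, pi0 = 0.5) {
  if (sum(weights) <= 0) stop("weights must have positive mass")
  new("PartitionPrior", pi0 = pi0, partitions = partitions,
      weights = weights / sum(weights))
}

#' Distinguished partitions behind the standard tests
#'
#' `gamma_all` (all traits directly associated) underlies the standard
#' multivariate test; the `d` partitions `gamma_uni[[j]]` (trait `j` direct,
#' all others indirect) underlie the standard univariate tests.
#'
#' @param d number of traits.
#' @return list with elements `gamma_all` (a [Partition-class]) and
#'   `gamma_uni` (a list of `d` partitions).
#' @export
specialPartitions <- function(d) {
  list(
    gamma_all = Partition(d, D = seq_len(d)),
    gamma_uni = lapply(seq_len(d), function(j)
      Partition(d, D = j, I = setdiff(seq_len(d), j)))
  )
}
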