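#' Build a table of coalescence records
#'
#' A coalescence record \eqn{(\ell, r, u, (c_1, c_2), t)} states that the
#' child nodes \eqn{c_1 < c_2} coalesce into the parent node \eqn{u} at time
#' \eqn{t} over the half-open genomic interval \eqn{[\ell, r)}.  Sites are
#' discrete integers \code{0..m-1} and times are in units of \eqn{4 N_e}
#' generations.  A set of such records is the fundamental storage unit of a
#' tree sequence: each marginal genealogy along the chromosome is recovered
#' by applying the records whose interval covers the site of interest.
#'
#' @param left,right integer site coordinates, \code{0 <= left < right <= m}.
#' @param node integer parent node label (\code{> n} for a sample of size n).
#' @param child1,child2 integer child node labels with
#'   \code{child1 < child2}.
#' @param time positive numeric coalescence time (units of \eqn{4N_e}
#'   generations).
#' @return a \code{data.frame} with columns \code{left}, \code{right},
#'   \code{node}, \code{child1}, \code{child2}, \code{time}.
#' @examples
#' coalescence_records(0, 1, 3L, 1L, 2L, 0.5)
#' @export
coalescence_records <- function(left, right, node, child1, child2, time) {
  data.frame(
    left = as.integer(left), right = as.integer(right),
    node = as.integer(node), child1 = as.integer(child1),
    child2 = as.integer(child2), time = as.numeric(time)
  )
}

record_columns <- c("left", "right", "node", "child1", "child2", "time")

as_records <- function(records) {
  if (!is.data.frame(records) || !all(record_columns %in% names(records)))
    ts_error(
      paste("records must be a data.frame with columns",
            paste(record_columns, collapse = ", ")),
      "treeseq_structure_error"
    )
  records <- records[record_columns]
  for (col in c("left", "right", "node", "child1", "child2"))
    records[[col]] <- as.integer(records[[col]])
  records$time <- as.numeric(records$time)
  rownames(records) <- NULL
  records
}

#' Validate a set of coalescence records
#'
#' Checks the structural invariants of a record table for a sample of size
#' \code{n} over \code{m} sites: coordinate sanity, child ordering
#' (\code{child1 < child2}), full coverage (every site is intersected by
#' exactly \code{n - 1} records, as marginal trees are binary), and time
#' consistency (every parent is older than its children; a node has a single
#' time).  Each failure mode raises a distinct classed condition:
#' \code{treeseq_child_order_error}, \code{treeseq_coverage_error},
#' \code{treeseq_time_error} or \code{treeseq_structure_error}, all
#' inheriting from \code{treeseq_error}.
#'
#' @param records record table (see [coalescence_records()]).
#' @param n sample size; leaves are labelled \code{1..n}.
#' @param m sequence length in discrete sites.
#' @return the validated records, invisibly.
#' @export
validate_records <- function(records, n, m) {
  records <- as_records(records)
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 2L) ts_error("sample size n must be >= 2", "treeseq_structure_error")
  if (m < 1L) ts_error("sequence length m must be >= 1", "treeseq_structure_error")
  if (nrow(records) == 0L)
    ts_error("empty record set is not a valid tree sequence",
             "treeseq_structure_error")
  with(records, {
    if (any(left < 0L) || any(right > m) || any(left >= right))
      ts_error("record intervals must satisfy 0 <= left < right <= m",
               "treeseq_structure_error")
    if (any(node <= n))
      ts_error("parent node labels must be > n", "treeseq_structure_error")
    if (any(child1 < 1L) || any(child2 < 1L))
      ts_error("child labels must be >= 1", "treeseq_structure_error")
    if (any(time <= 0))
      ts_error("record times must be > 0", "treeseq_structure_error")
    if (any(child1 >= child2))
      ts_error("record children must be ordered child1 < child2",
               "treeseq_child_order_error")
  })

  # coverage: between consecutive distinct coordinates every site must be
  # intersected by exactly n - 1 records (sweep over interval endpoints)
  bp <- sort(unique(c(records$left, records$right, 0L, m)))
  opened <- cumsum(tabulate(match(records$left, bp), nbins = length(bp)))
  closed <- cumsum(tabulate(match(records$right, bp), nbins = length(bp)))
  cover <- (opened - closed)[-length(bp)]  # count on [bp_i, bp_{i+1})
  if (any(cover != n - 1L)) {
    bad <- which(cover != n - 1L)[1]
    ts_error(sprintf(
      "coverage violation: site %d is intersected by %d records, expected %d",
      bp[bad], cover[bad], n - 1L), "treeseq_coverage_error")
  }

  # time consistency
  tt <- tapply(records$time, records$node, function(v) length(unique(v)))
  if (any(tt > 1L))
    ts_error("conflicting times for a single node", "treeseq_time_error")
  times <- node_time_vector(records, n)
  child_labels <- c(records$child1, records$child2)
  undefined <- child_labels[child_labels > n & is.na(times[child_labels])]
  if (length(undefined) > 0L)
    ts_error(sprintf("internal child node %d has no defining record",
                     undefined[1]), "treeseq_time_error")
  ct <- matrix(times[c(records$child1, records$child2)], ncol = 2)
  if (any(records$time <= ct[, 1]) || any(records$time <= ct[, 2]))
    ts_error("record time must strictly exceed the times of its children",
             "treeseq_time_error")
  invisible(records)
}

# times indexed by node label; leaves (and unused labels <= n) at 0,
# internal labels without a record are NA
node_time_vector <- function(records, n) {
  maxu <- max(records$node)
  times <- rep(NA_real_, maxu)
  times[seq_len(min(n, maxu))] <- 0
  times[records$node] <- records$time
  times
}

#' Compute the insertion and removal index vectors
#'
#' The index vectors drive the sequential tree-generation algorithm:
#' \code{I} orders records by nondecreasing left coordinate and increasing
#' time (records are inserted child-before-parent), and \code{O} orders them
#' by nondecreasing right coordinate and decreasing time (records are
#' removed parent-before-child).  Ties in (coordinate, time) -- which arise
#' when disjoint intervals coalesce simultaneously in one common ancestor --
#' are broken by parent node label and then child labels, so the ordering is
#' deterministic across platforms.
#'
#' @inheritParams validate_records
#' @return list with integer permutations \code{I} and \code{O} of
#'   \code{1..M}.
#' @export
index_vectors <- function(records) {
  records <- as_records(records)
  list(
    I = order(records$left, records$time, records$node,
              records$child1, records$child2),
    O = order(records$right, -records$time, records$node,
              records$child1, records$child2)
  )
}

#' Construct a tree sequence from coalescence records
#'
#' A tree sequence is a validated, column-indexed table of coalescence
#' records together with the insertion/removal index vectors \code{I} and
#' \code{O} (see [index_vectors()]).  It is the compressed encoding of all
#' marginal genealogies of a sample of \code{n} haplotypes over \code{m}
#' discrete sites: node assignments shared by adjacent trees are stored
#' exactly once.
#'
#' @inheritParams validate_records
#' @param counts optional named list of simulator event counters, attached
#'   as the \code{counts} element.
#' @return an object of class \code{tree_sequence}: a list with elements
#'   \code{records}, \code{n}, \code{m}, \code{I}, \code{O} and optionally
#'   \code{counts}.
#' @examples
#' ts <- tree_sequence(coalescence_records(0, 1, 3L, 1L, 2L, 0.5), n = 2, m = 1)
#' ts
#' @export
tree_sequence <- function(records, n, m, counts = NULL) {
  records <- as_records(records)
  validate_records(records, n, m)
  iv <- index_vectors(records)
  structure(
    list(records = records, n = as.integer(n), m = as.integer(m),
         I = iv$I, O = iv$O, counts = counts),
    class = "tree_sequence"
  )
}

#' @export
print.tree_sequence <- function(x, ...) {
  cat(sprintf(
    "Tree sequence: n = %d samples, m = %d sites, %d records, %d trees\n",
    x$n, x$m, nrow(x$records), count_trees(x)))
  invisible(x)
}

#' @export
summary.tree_sequence <- function(object, ...) {
  res <- list(
    n = object$n, m = object$m, records = nrow(object$records),
    trees = count_trees(object),
    breakpoints = n_breakpoints(object),
    max_time = max(object$records$time),
    counts = object$counts
  )
  class(res) <- "summary.tree_sequence"
  res
}

#' @export
print.summary.tree_sequence <- function(x, ...) {
  cat(sprintf("Tree sequence of %d samples over %d sites\n", x$n, x$m))
  cat(sprintf("  records:            %d\n", x$records))
  cat(sprintf("  distinct trees:     %d\n", x$trees))
  cat(sprintf("  breakpoints:        %d\n", x$breakpoints))
  cat(sprintf("  oldest node time:   %.4f (4Ne generations)\n", x$max_time))
  if (!is.null(x$counts))
    cat(sprintf(
      "  events: %d recombination (%d within ancestral material), %d common ancestor, %d coalescence\n",
      x$counts$n_recombination, x$counts$n_recomb_ancestral,
      x$counts$n_common_ancestor, x$counts$n_coalescence))
  invisible(x)
}

#' Merge contiguous records describing one node assignment
#'
#' Adjacent records that agree in (node, children, time) and whose intervals
#' touch describe a single assignment of a child pair to a parent over the
#' union interval, and are merged into one record.  Marginal trees are
#' unchanged.  Simulator output is emitted in this squashed form already;
#' the operation is idempotent and useful for normalising records assembled
#' per-tree.
#'
#' @inheritParams validate_records
#' @return the squashed record table, ordered by (time, left, node).
#' @examples
#' squash_records(data.frame(
#'   left = c(0L, 2L), right = c(2L, 7L), node = 7L,
#'   child1 = 1L, child2 = 6L, time = 0.17))
#' @export
squash_records <- function(records) {
  records <- as_records(records)
  ord <- order(records$node, records$child1, records$child2,
               records$time, records$left)
  r <- records[ord, ]
  M <- nrow(r)
  same <- c(FALSE,
            r$node[-1] == r$node[-M] &
              r$child1[-1] == r$child1[-M] &
              r$child2[-1] == r$child2[-M] &
              r$time[-1] == r$time[-M] &
              r$left[-1] == r$right[-M])
  grp <- cumsum(!same)
  out <- data.frame(
    left = unname(as.integer(tapply(r$left, grp, min))),
    right = unname(as.integer(tapply(r$right, grp, max))),
    node = r$node[!same], child1 = r$child1[!same],
    child2 = r$child2[!same], time = r$time[!same]
  )
  out <- out[order(out$time, out$left, out$node), ]
  rownames(out) <- NULL
  out
}

#' Number of distinct marginal trees in a tree sequence
#'
#' Equal to the number of visits made by [iterate_trees()]: one per distinct
#' record left-coordinate (squashed records guarantee each transition changes
#' the tree's records).
#'
#' @param ts a \code{tree_sequence}.
#' @return integer count of distinct marginal trees.
#' @export
count_trees <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  length(unique(ts$records$left))
}

#' Distinct breakpoints appearing in record coordinates
#'
#' The distinct interior coordinates (excluding 0 and m) at which some
#' record starts or ends; equivalently the number of tree transitions.
#' Note that this *undercounts* the recombination events that occurred
#' within ancestral material, since some events leave no trace in the
#' records (e.g. a split followed by the immediate re-merging of the two
#' recombinant lineages).  For the Hudson-Kaplan comparison use the
#' simulator's \code{n_recomb_ancestral} counter (see
#' [mean_breakpoints_experiment()]).
#'
#' @param ts a \code{tree_sequence}.
#' @return integer count of interior record coordinates.
#' @export
n_breakpoints <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  coords <- unique(c(ts$records$left, ts$records$right))
  sum(coords != 0L & coords != ts$m)
}
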