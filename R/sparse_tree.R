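#' Sparse oriented trees
#'
#' An oriented tree is encoded by an integer parent vector \eqn{\pi}:
#' \eqn{\pi_u} is the parent of node \code{u} and \eqn{\pi_u = 0} marks a
#' root (label 0 is reserved).  In a *sparse* tree the leaves are labelled
#' \code{1..n} but internal node labels may be any integers \code{> n}, not
#' necessarily consecutive -- which is what lets adjacent marginal
#' genealogies share node labels without relabelling.
#'
#' @param parent integer parent vector indexed by node label; entry 0 means
#'   root or absent.
#' @param n sample size (leaves are \code{1..n}).
#' @param interval optional half-open genomic interval \code{c(left, right)}
#'   that this marginal tree covers.
#' @return an object of class \code{sparse_tree}: list with elements
#'   \code{parent}, \code{n}, \code{interval}.
#' @examples
#' sparse_tree(c(5L, 4L, 4L, 5L, 0L), n = 3)  # dense encoding
#' sparse_tree(c(6L, 5L, 5L, 0L, 6L, 0L), n = 3)[c("parent", "n")]
#' @export
sparse_tree <- function(parent, n, interval = NULL) {
  parent <- as.integer(parent)
  n <- as.integer(n)
  if (any(parent < 0L, na.rm = TRUE))
    ts_error("parent labels must be non-negative", "treeseq_structure_error")
  if (n < 1L || length(parent) < n)
    ts_error("parent vector must cover the leaf labels 1..n",
             "treeseq_structure_error")
  # no cycles: following parents from any node terminates within max-label
  # steps at a node with parent 0
  for (u in seq_len(n)) {
    v <- u
    for (step in seq_len(length(parent) + 1L)) {
      if (parent[v] == 0L) break
      v <- parent[v]
      if (step > length(parent))
        ts_error("cycle detected in parent vector", "treeseq_structure_error")
    }
  }
  structure(list(parent = parent, n = n, interval = interval),
            class = "sparse_tree")
}

#' @export
print.sparse_tree <- function(x, ...) {
  iv <- if (is.null(x$interval)) "" else
    sprintf(" on [%d, %d)", x$interval[1], x$interval[2])
  cat(sprintf("Sparse tree%s, n = %d: pi = <%s>\n",
              iv, x$n, paste(x$parent, collapse = ", ")))
  invisible(x)
}

# nodes actually present in the tree (appear as a child or as a parent)
tree_nodes <- function(tree) {
  p <- tree$parent
  sort(unique(c(which(p != 0L), p[p != 0L])))
}

#' Root of a sparse tree
#'
#' @param tree a \code{sparse_tree}.
#' @return the label of the root (the unique present node with parent 0);
#'   errors if the tree has several roots.
#' @export
tree_root <- function(tree) {
  nodes <- tree_nodes(tree)
  roots <- nodes[tree$parent[nodes] == 0L]
  if (length(roots) != 1L)
    ts_error(sprintf("tree has %d roots", length(roots)),
             "treeseq_structure_error")
  roots
}

# children adjacency as a list indexed by node label
children_list <- function(tree) {
  p <- tree$parent
  kids <- vector("list", length(p))
  nz <- which(p != 0L)
  for (u in nz) kids[[p[u]]] <- c(kids[[p[u]]], u)
  lapply(kids, sort)
}

#' Leaves below a node
#'
#' Enumerates the leaf labels (\code{1..n}) in the subtree rooted at
#' \code{u}, by explicit-stack descent.
#'
#' @param tree a \code{sparse_tree}.
#' @param u node label.
#' @return sorted integer vector of leaf labels below (or equal to) \code{u}.
#' @export
leaves_below <- function(tree, u) {
  kids <- children_list(tree)
  out <- integer(0)
  stack <- as.integer(u)
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= tree$n) out <- c(out, v)
    else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

#' Marginal tree at a site (point query)
#'
#' Builds the sparse tree covering site \code{x} by applying the
#' \eqn{n - 1} records whose interval contains \code{x}: for every record
#' \eqn{(\ell, r, u, (c_1, c_2), t)} with \eqn{\ell \le x < r}, set
#' \eqn{\pi_{c_1} = \pi_{c_2} = u}; all other entries are 0.
#'
#' @param ts a \code{tree_sequence}.
#' @param x integer site, \code{0 <= x < m}.
#' @return a \code{sparse_tree} whose \code{interval} is the maximal record
#'   interval around \code{x} over which the tree does not change.
#' @examples
#' ts <- tree_sequence(coalescence_records(0, 1, 3L, 1L, 2L, 0.5), n = 2, m = 1)
#' build_tree_at(ts, 0)$parent  # <3, 3, 0>
#' @export
build_tree_at <- function(ts, x) {
  stopifnot(inherits(ts, "tree_sequence"))
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 0L || x >= ts$m)
    ts_error(sprintf("site x must satisfy 0 <= x < m = %d", ts$m),
             "treeseq_structure_error")
  r <- ts$records
  hit <- which(r$left <= x & x < r$right)
  parent <- integer(max(r$node))
  parent[r$child1[hit]] <- r$node[hit]
  parent[r$child2[hit]] <- r$node[hit]
  coords <- sort(unique(c(r$left, r$right)))
  lo <- max(coords[coords <= x])
  hi <- min(coords[coords > x])
  sparse_tree(parent, ts$n, interval = c(lo, hi))
}

#' Node times of a tree sequence
#'
#' Times live on the records: every internal node label is the parent of at
#' least one record and all records sharing a node agree on its time (this
#' is validated).  Leaves are at time 0.
#'
#' @param ts a \code{tree_sequence}.
#' @return numeric vector indexed by node label (length \code{max(node)}),
#'   with leaf entries 0.
#' @examples
#' ts <- tree_sequence(coalescence_records(0, 1, 3L, 1L, 2L, 0.5), n = 2, m = 1)
#' node_times(ts)  # 0.0 0.0 0.5
#' @export
node_times <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  times <- node_time_vector(ts$records, ts$n)
  times[is.na(times)] <- 0
  times
}
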