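#' Sequentially visit every marginal tree (Algorithm T)
#'
#' Generates the marginal genealogies of a tree sequence left-to-right by
#' incremental editing: at each transition the stale records (right
#' coordinate equal to the new left endpoint) are removed in decreasing
#' time order and the incoming records (matching left coordinate) are
#' inserted in increasing time order, so each record is inserted exactly
#' once and removed at most once.  The visited tree over \eqn{[x_k,
#' x_{k+1})} is identical to [build_tree_at()] at any site in the interval.
#'
#' @param ts a \code{tree_sequence}.
#' @param visit function called once per marginal tree with a
#'   \code{sparse_tree} argument (carrying its \code{interval}).  The tree
#'   is reused state: copy it (R's copy-on-write does this implicitly if
#'   you store it) rather than modifying it in place.
#' @return invisibly, a list with counters \code{visits},
#'   \code{inserted}, \code{removed}.
#' @examples
#' ts <- sim_coalescent(4, m = 50, rho = 2, seed = 3)
#' iterate_trees(ts, function(tree) print(tree$interval))
#' @export
iterate_trees <- function(ts, visit) {
  stopifnot(inherits(ts, "tree_sequence"))
  r <- ts$records
  M <- nrow(r)
  I <- ts$I; O <- ts$O
  l <- r$left; rr <- r$right; u <- r$node; c1 <- r$child1; c2 <- r$child2
  parent <- integer(max(u))
  j <- 1L; k <- 1L; x <- 0L
  visits <- 0L; removed <- 0L
  repeat {
    while (j <= M && l[I[j]] == x) {
      h <- I[j]
      parent[c1[h]] <- u[h]
      parent[c2[h]] <- u[h]
      j <- j + 1L
    }
    right <- if (j <= M) l[I[j]] else ts$m
    visits <- visits + 1L
    tree <- structure(list(parent = parent, n = ts$n,
                           interval = c(x, right)), class = "sparse_tree")
    visit(tree)
    if (j > M) break
    x <- l[I[j]]
    while (k <= M && rr[O[k]] == x) {
      h <- O[k]
      parent[c1[h]] <- 0L
      parent[c2[h]] <- 0L
      k <- k + 1L
      removed <- removed + 1L
    }
  }
  invisible(list(visits = visits, inserted = j - 1L, removed = removed))
}

#' All marginal trees as a list
#'
#' Convenience wrapper around [iterate_trees()]; only sensible for small
#' sequences since every tree is materialised.
#'
#' @param ts a \code{tree_sequence}.
#' @return list of \code{sparse_tree} objects in left-to-right order.
#' @export
marginal_trees <- function(ts) {
  out <- vector("list", count_trees(ts))
  i <- 0L
  iterate_trees(ts, function(tree) {
    i <<- i + 1L
    out[[i]] <<- tree
  })
  out
}

#' Visit marginal trees while maintaining leaf counts (Algorithm L)
#'
#' Augments the sequential tree traversal with, for each tracked leaf set
#' \eqn{S}, a vector \eqn{\beta} such that \eqn{\beta_u} is the number of
#' leaves of \eqn{S} in the subtree rooted at \eqn{u} of the current tree.
#' When a record is inserted the combined count of its two children is
#' propagated up to the root; when it is removed the same amount is
#' subtracted.  Removals are processed in decreasing time order, so counts
#' inside temporarily disconnected subtrees remain correct.  Because a
#' mutation is attached to the child node \eqn{u} of the branch it falls
#' on, \eqn{\beta_u/|S|} is directly the frequency of the mutation within
#' \eqn{S}.
#'
#' @param ts a \code{tree_sequence}.
#' @param S tracked leaves: an integer vector of leaf labels, or a list of
#'   such vectors to maintain several counts simultaneously (e.g. cases
#'   and controls).
#' @param visit function called once per marginal tree as
#'   \code{visit(tree, beta)} where \code{beta} is a matrix with one column
#'   per tracked set and one row per node label.
#' @return invisibly, the traversal counters as for [iterate_trees()].
#' @export
iterate_trees_with_counts <- function(ts, S, visit) {
  stopifnot(inherits(ts, "tree_sequence"))
  if (!is.list(S)) S <- list(S)
  for (s in S) {
    s <- as.integer(s)
    if (length(s) > 0 && (any(s < 1L) || any(s > ts$n)))
      ts_error("tracked set S must contain leaf labels in 1..n",
               "treeseq_structure_error")
    if (anyDuplicated(s))
      ts_error("tracked set S must not contain duplicates",
               "treeseq_structure_error")
  }
  r <- ts$records
  M <- nrow(r)
  I <- ts$I; O <- ts$O
  l <- r$left; rr <- r$right; u <- r$node; c1 <- r$child1; c2 <- r$child2
  maxu <- max(u)
  parent <- integer(maxu)
  beta <- matrix(0L, nrow = maxu, ncol = length(S))
  for (si in seq_along(S)) beta[as.integer(S[[si]]), si] <- 1L
  j <- 1L; k <- 1L; x <- 0L
  visits <- 0L; removed <- 0L
  repeat {
    while (j <= M && l[I[j]] == x) {
      h <- I[j]
      parent[c1[h]] <- u[h]
      parent[c2[h]] <- u[h]
      b <- beta[c1[h], ] + beta[c2[h], ]
      v <- u[h]
      while (v != 0L) {
        beta[v, ] <- beta[v, ] + b
        v <- parent[v]
      }
      j <- j + 1L
    }
    right <- if (j <= M) l[I[j]] else ts$m
    visits <- visits + 1L
    tree <- structure(list(parent = parent, n = ts$n,
                           interval = c(x, right)), class = "sparse_tree")
    visit(tree, beta)
    if (j > M) break
    x <- l[I[j]]
    while (k <= M && rr[O[k]] == x) {
      h <- O[k]
      b <- beta[c1[h], ] + beta[c2[h], ]
      v <- u[h]
      while (v != 0L) {
        beta[v, ] <- beta[v, ] - b
        v <- parent[v]
      }
      parent[c1[h]] <- 0L
      parent[c2[h]] <- 0L
      k <- k + 1L
      removed <- removed + 1L
    }
  }
  invisible(list(visits = visits, inserted = j - 1L, removed = removed))
}

#' Record differences between adjacent marginal trees
#'
#' Reports, for each visited tree, the records removed and inserted at the
#' transition into it.  The first element inserts the initial \eqn{n - 1}
#' records with no removals; applying each diff in order to the previous
#' tree reproduces the traversal of [iterate_trees()].  The three classes
#' of subtree-prune-and-regraft transition are visible here: a regraft not
#' involving the root exchanges 3 records, a root-changing regraft 2, and
#' a root-time-only change 1.
#'
#' @param ts a \code{tree_sequence}.
#' @return list of diffs; each has \code{interval}, \code{records_out} and
#'   \code{records_in} (data frames of record rows).
#' @export
tree_diffs <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  r <- ts$records
  M <- nrow(r)
  I <- ts$I; O <- ts$O
  l <- r$left; rr <- r$right
  out <- vector("list", count_trees(ts))
  vi <- 0L
  j <- 1L; k <- 1L; x <- 0L
  repeat {
    removed <- integer(0)
    if (vi > 0L) {
      while (k <= M && rr[O[k]] == x) {
        removed <- c(removed, O[k])
        k <- k + 1L
      }
    }
    inserted <- integer(0)
    while (j <= M && l[I[j]] == x) {
      inserted <- c(inserted, I[j])
      j <- j + 1L
    }
    right <- if (j <= M) l[I[j]] else ts$m
    vi <- vi + 1L
    out[[vi]] <- list(interval = c(x, right),
                      records_out = r[removed, , drop = FALSE],
                      records_in = r[inserted, , drop = FALSE])
    if (j > M) break
    x <- l[I[j]]
  }
  out
}
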