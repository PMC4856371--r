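#' Drop infinite-sites mutations onto a tree sequence
#'
#' Mutations are generated independently on every branch segment of every
#' record: for a record \eqn{(\ell, r, u, (c_1, c_2), t)} and each child
#' \eqn{c}, the branch from \eqn{c} up to \eqn{u} exists over
#' \eqn{[\ell, r)} and carries a Poisson(\eqn{\theta (r - \ell)(t -
#' t_c)}) number of mutations, each placed uniformly on \eqn{[\ell, r)}.
#' Although recombination operates on discrete sites, mutation positions
#' are continuous reals, so every mutation occupies a new position
#' (infinite-sites model).  A mutation is stored as the tuple
#' \code{(node, position)} where \code{node} is the *child* end of the
#' branch it falls on; the carriers of the mutation are exactly the leaves
#' below \code{node} in the marginal tree covering \code{position}.
#'
#' The expected number of segregating sites is \eqn{\theta m H_{n-1}}
#' (\eqn{E}[total branch length] is \eqn{H_{n-1}} in units of \eqn{4 N_e}
#' generations).
#'
#' @param ts a \code{tree_sequence}.
#' @param theta scaled mutation rate per unit of sequence length per
#'   \eqn{4 N_e} generations.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{node} (integer) and
#'   \code{position} (numeric in \eqn{[0, m)}), ordered by position.
#' @examples
#' ts <- sim_coalescent(5, m = 1000, rho = 1, seed = 2)
#' mut <- sim_mutations(ts, theta = 0.005, seed = 2)
#' head(mut)
#' @export
sim_mutations <- function(ts, theta, seed = NULL) {
  stopifnot(inherits(ts, "tree_sequence"))
  if (theta < 0) ts_error("theta must be >= 0", "treeseq_structure_error")
  if (!is.null(seed)) set.seed(seed)
  r <- ts$records
  times <- node_times(ts)
  span <- r$right - r$left
  blen1 <- r$time - times[r$child1]
  blen2 <- r$time - times[r$child2]
  lam <- theta * span * c(blen1, blen2)
  child <- c(r$child1, r$child2)
  left <- c(r$left, r$left)
  counts <- rpois(length(lam), lam)
  tot <- sum(counts)
  if (tot == 0L)
    return(data.frame(node = integer(0), position = numeric(0)))
  node <- rep.int(child, counts)
  pos <- rep.int(left, counts) + runif(tot) * rep.int(c(span, span), counts)
  out <- data.frame(node = node, position = pos)
  out[order(out$position), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Haplotypes induced by a set of mutations
#'
#' Produces the 0/1 genotype matrix of the sample: entry \code{[i, s]} is 1
#' iff sample \code{i} is a leaf of the subtree rooted at the mutation's
#' node in the marginal tree covering the mutation's position.  Computed in
#' one left-to-right tree traversal, resolving each mutation by descending
#' from its node in the covering tree.
#'
#' @param ts a \code{tree_sequence}.
#' @param mutations data.frame as returned by [sim_mutations()].
#' @return integer matrix with \code{n} rows (samples) and one column per
#'   mutation, column names the positions.
#' @export
haplotypes <- function(ts, mutations) {
  stopifnot(inherits(ts, "tree_sequence"))
  mutations <- mutations[order(mutations$position), , drop = FALSE]
  S <- nrow(mutations)
  H <- matrix(0L, nrow = ts$n, ncol = S)
  if (S > 0L)
    colnames(H) <- format(mutations$position, trim = TRUE)
  if (S == 0L) return(H)
  if (any(mutations$position < 0) || any(mutations$position >= ts$m))
    ts_error("mutation positions must lie in [0, m)",
             "treeseq_structure_error")
  iterate_trees(ts, function(tree) {
    sel <- which(mutations$position >= tree$interval[1] &
                   mutations$position < tree$interval[2])
    if (length(sel) == 0L) return(invisible())
    kids <- children_list(tree)
    for (s in sel) {
      u <- mutations$node[s]
      if (u > length(tree$parent) ||
          (tree$parent[u] == 0L && !(u %in% tree$parent)))
        ts_error(sprintf(
          "mutation node %d is not present in the tree covering %.3f",
          u, mutations$position[s]), "treeseq_structure_error")
      stack <- u
      while (length(stack) > 0L) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (v <= ts$n) H[v, s] <<- 1L
        else stack <- c(stack, kids[[v]])
      }
    }
    invisible()
  })
  H
}

#' Allele frequencies within a tracked leaf set
#'
#' For each mutation \code{(u, p)}, the frequency within \eqn{S} is
#' \eqn{\beta_u / |S|}, where \eqn{\beta} is the leaf-count vector of the
#' marginal tree covering \code{p} (Algorithm L); no haplotype matrix is
#' materialised.
#'
#' @param ts a \code{tree_sequence}.
#' @param mutations data.frame from [sim_mutations()].
#' @param S non-empty integer vector of tracked leaf labels.
#' @return numeric vector of frequencies, one per mutation (in position
#'   order).
#' @export
allele_frequencies <- function(ts, mutations, S = seq_len(ts$n)) {
  stopifnot(inherits(ts, "tree_sequence"))
  S <- as.integer(S)
  if (length(S) == 0L)
    ts_error("tracked set S must be non-empty", "treeseq_structure_error")
  mutations <- mutations[order(mutations$position), , drop = FALSE]
  freq <- numeric(nrow(mutations))
  if (nrow(mutations) == 0L) return(freq)
  iterate_trees_with_counts(ts, S, function(tree, beta) {
    sel <- which(mutations$position >= tree$interval[1] &
                   mutations$position < tree$interval[2])
    if (length(sel) > 0L)
      freq[sel] <<- beta[mutations$node[sel], 1L] / length(S)
    invisible()
  })
  freq
}

#' Case/control odds ratios at every mutation
#'
#' The association statistic of a simple genome-wide association scan:
#' carriers are counted simultaneously for the case and control sets with
#' two leaf-count vectors in a single traversal, giving the 2x2 table
#' (carrier/non-carrier x case/control) at each mutation, and the odds
#' ratio \eqn{(a d)/(b c)} with \eqn{a} = case carriers, \eqn{b} = case
#' non-carriers, \eqn{c} = control carriers, \eqn{d} = control
#' non-carriers.  With a zero cell the ratio is reported as \code{Inf}, 0
#' or \code{NaN} as the arithmetic dictates; \code{haldane = TRUE} adds the
#' Haldane-Anscombe 0.5 to every cell instead.
#'
#' @param ts a \code{tree_sequence}.
#' @param mutations data.frame from [sim_mutations()].
#' @param cases,controls disjoint non-empty integer vectors of leaf labels.
#' @param haldane apply the +0.5 continuity correction (default FALSE).
#' @return data.frame with columns \code{position}, \code{node},
#'   \code{case_carrier}, \code{case_noncarrier}, \code{control_carrier},
#'   \code{control_noncarrier}, \code{odds_ratio}.
#' @export
case_control_odds_ratios <- function(ts, mutations, cases, controls,
                                     haldane = FALSE) {
  stopifnot(inherits(ts, "tree_sequence"))
  cases <- as.integer(cases)
  controls <- as.integer(controls)
  if (length(cases) == 0L || length(controls) == 0L)
    ts_error("cases and controls must be non-empty",
             "treeseq_structure_error")
  if (length(intersect(cases, controls)) > 0L)
    ts_error("cases and controls must be disjoint",
             "treeseq_structure_error")
  mutations <- mutations[order(mutations$position), , drop = FALSE]
  S <- nrow(mutations)
  a <- integer(S); cc <- integer(S)
  iterate_trees_with_counts(ts, list(cases, controls), function(tree, beta) {
    sel <- which(mutations$position >= tree$interval[1] &
                   mutations$position < tree$interval[2])
    if (length(sel) > 0L) {
      a[sel] <<- beta[mutations$node[sel], 1L]
      cc[sel] <<- beta[mutations$node[sel], 2L]
    }
    invisible()
  })
  b <- as.numeric(length(cases) - a)
  d <- as.numeric(length(controls) - cc)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (as.numeric(a) * d) / (b * as.numeric(cc))
  data.frame(position = mutations$position, node = mutations$node,
             case_carrier = a, case_noncarrier = b,
             control_carrier = cc, control_noncarrier = d,
             odds_ratio = or)
}
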