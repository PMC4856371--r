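# Fixtures and independent oracles used across the test files.

# A 6-record tree sequence for n = 4 over m = 10 sites with three marginal
# trees on [0,2), [2,7), [7,10).  Built so that the first transition is a
# root-changing prune-and-regraft (2 records out / 2 in) and the second a
# root-time-only change (1 out / 1 in); node 6 coalesces two disjoint
# intervals simultaneously (one event, two records, same time) and the
# assignment (1,6)->7 spans the first two trees as a single record.
three_tree_records <- function() {
  coalescence_records(
    left   = c(2L, 0L, 2L, 0L, 7L, 0L),
    right  = c(10L, 2L, 10L, 7L, 10L, 2L),
    node   = c(5L, 6L, 6L, 7L, 8L, 9L),
    child1 = c(3L, 2L, 2L, 1L, 1L, 3L),
    child2 = c(4L, 4L, 5L, 6L, 6L, 7L),
    time   = c(0.071, 0.090, 0.090, 0.170, 0.202, 0.253)
  )
}

three_tree_ts <- function() tree_sequence(three_tree_records(), n = 4, m = 10)

# n = 5 sequence over m = 2 whose single transition is a subtree
# prune-and-regraft *not* involving the root: subtree at 2 is pruned from
# under 6 and regrafted into the branch joining 5 to 8; the root record
# (7,8)->9 spans both trees.  Exactly 3 records are exchanged.
spr_records <- function() {
  coalescence_records(
    left   = c(0L, 0L, 0L, 0L, 1L, 1L, 1L),
    right  = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
    node   = c(6L, 7L, 8L, 9L, 10L, 8L, 7L),
    child1 = c(1L, 3L, 4L, 7L, 2L, 4L, 1L),
    child2 = c(2L, 6L, 5L, 8L, 5L, 10L, 3L),
    time   = c(0.10, 0.20, 0.15, 0.30, 0.12, 0.15, 0.20)
  )
}

spr_ts <- function() tree_sequence(spr_records(), n = 5, m = 2)

# random simulated tree sequence with moderate parameters
rand_ts <- function(n = NULL, m = NULL, rho = NULL) {
  if (is.null(n)) n <- sample(2:12, 1)
  if (is.null(m)) m <- sample(2:200, 1)
  if (is.null(rho)) rho <- runif(1, 0, 8)
  sim_coalescent(n, m, rho)
}

seg_matrix <- function(...) treeseqsim:::seg_matrix(...)
tree_nodes_helper <- function(tree) treeseqsim:::tree_nodes(tree)
common_ancestor_event <- function(...) treeseqsim:::common_ancestor_event(...)

# --- independent oracles -------------------------------------------------

# marginal tree at site x straight from the record table, written
# independently of build_tree_at / Algorithm T
oracle_tree_at <- function(records, x) {
  parent <- integer(max(records$node))
  for (i in seq_len(nrow(records))) {
    if (records$left[i] <= x && x < records$right[i]) {
      parent[records$child1[i]] <- records$node[i]
      parent[records$child2[i]] <- records$node[i]
    }
  }
  parent
}

# leaf counts by walking up from each tracked leaf (independent of both
# Algorithm L and the children-list DFS)
oracle_beta <- function(parent, S) {
  beta <- integer(length(parent))
  for (s in S) {
    v <- s
    repeat {
      beta[v] <- beta[v] + 1L
      v <- parent[v]
      if (v == 0L) break
    }
  }
  beta
}

# does leaf i carry a mutation above `node`?  walk up from the leaf
oracle_carries <- function(parent, leaf, node) {
  v <- leaf
  repeat {
    if (v == node) return(TRUE)
    v <- parent[v]
    if (v == 0L) return(FALSE)
  }
}

# selection-sort ranking with an explicit lexicographic comparator; an
# independent check of the order()-based index vectors
oracle_sort_records <- function(keys) {
  # keys: list of numeric vectors, priority order; returns permutation
  M <- length(keys[[1]])
  idx <- seq_len(M)
  less <- function(i, j) {
    for (k in keys) {
      if (k[i] < k[j]) return(TRUE)
      if (k[i] > k[j]) return(FALSE)
    }
    FALSE
  }
  for (a in seq_len(M - 1)) {
    best <- a
    for (b in (a + 1):M) if (less(idx[b], idx[best])) best <- b
    tmp <- idx[a]; idx[a] <- idx[best]; idx[best] <- tmp
  }
  idx
}

# distinct record coordinates other than 0 and m
interior_coords <- function(ts) {
  coords <- unique(c(ts$records$left, ts$records$right))
  sort(coords[coords != 0L & coords != ts$m])
}
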