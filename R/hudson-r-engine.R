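# Pure-R reference implementation of Hudson's algorithm.  The step
# functions below are the readable specification of what the compiled core
# does; the two implementations consume the R RNG with an identical draw
# sequence and are required (by the test suite) to produce bit-identical
# output under a shared seed.  Segments are rows (left, right, node) of an
# integer matrix, sorted by coordinate and pairwise disjoint; an ancestor
# is such a matrix.

seg_matrix <- function(left, right, node) {
  matrix(as.integer(c(left, right, node)), ncol = 3,
         dimnames = list(NULL, c("left", "right", "node")))
}

#' Initialise the state of Hudson's algorithm
#'
#' The initial population holds \code{n} ancestors, each carrying the single
#' segment \code{(0, m, u)} for \code{u = 1..n}; time starts at 0 and the
#' next node label at \code{n + 1}.  The state also carries the total link
#' count \eqn{L = \sum_a (\max r - \min \ell - 1)} and a breakpoint ->
#' count map giving, for every genomic position, the number of extant
#' segments covering it (initially \code{n} everywhere).
#'
#' @param n sample size (>= 2).
#' @param m sequence length in sites (>= 1).
#' @param rho scaled recombination rate.
#' @return a state list with elements \code{pop} (list of segment
#'   matrices), \code{links}, \code{L}, \code{t}, \code{w}, the overlap map
#'   (\code{ov_keys}, \code{ov_cnts}), record accumulators and event
#'   counters.
#' @export
initialise_state <- function(n, m, rho = 0) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (is.na(n) || n < 2L)
    ts_error("sample size n must be >= 2", "treeseq_structure_error")
  if (is.na(m) || m < 1L)
    ts_error("sequence length m must be >= 1", "treeseq_structure_error")
  list(
    n = n, m = m, rho = rho,
    pop = lapply(seq_len(n), function(u) seg_matrix(0L, m, u)),
    links = rep(as.numeric(m) - 1, n),
    L = as.numeric(n) * (m - 1),
    t = 0, w = n + 1L,
    ov_keys = c(0L, m), ov_cnts = c(n, 0L),
    rl = integer(0), rr = integer(0), ru = integer(0),
    rc1 = integer(0), rc2 = integer(0), rt = numeric(0),
    n_recombination = 0, n_recomb_ancestral = 0,
    n_common_ancestor = 0, n_coalescence = 0
  )
}

#' Breakable links of one ancestor
#'
#' The number of positions at which a recombination can split the ancestor:
#' its extreme span minus one, \eqn{\max r - \min \ell - 1}.  Gaps of
#' trapped non-ancestral material between segments count as breakable.
#'
#' @param a segment matrix with columns left, right, node.
#' @return integer link count (0 for an unbreakable single-site ancestor).
#' @export
ancestor_links <- function(a) {
  if (is.null(dim(a)) || nrow(a) == 0L)
    ts_error("ancestor has no segments", "treeseq_structure_error")
  as.numeric(a[nrow(a), 2L]) - as.numeric(a[1L, 1L]) - 1
}

#' Draw the waiting time and kind of the next event
#'
#' With \eqn{N = |P|} ancestors and \eqn{L} links, recombination events
#' occur at rate \eqn{\rho L/(m-1)} and common ancestor events at rate
#' \eqn{N(N-1)}; the waiting time is exponential with the summed rate and
#' the kind is chosen with probability proportional to each rate.  Consumes
#' one exponential and one uniform draw.
#'
#' @param state a simulation state (see [initialise_state()]).
#' @return list with \code{waiting_time} and \code{event_kind}
#'   (\code{"recombination"} or \code{"common_ancestor"}).
#' @export
draw_next_event <- function(state) {
  N <- length(state$pop)
  rec_rate <- if (state$m > 1L) state$rho * state$L / (state$m - 1L) else 0
  ca_rate <- N * (N - 1)
  total <- rec_rate + ca_rate
  if (total <= 0)
    ts_error("no event possible: both rates are zero",
             "treeseq_structure_error")
  wait <- rexp(1, total)
  kind <- if (runif(1) < rec_rate / total) "recombination" else
    "common_ancestor"
  list(waiting_time = wait, event_kind = kind)
}

# overlap-map helper: make sure x is a key; counts are piecewise constant
# on [key_i, key_{i+1})
ov_ensure_key <- function(state, x) {
  i <- findInterval(x, state$ov_keys)
  if (state$ov_keys[i] != x) {
    state$ov_keys <- append(state$ov_keys, as.integer(x), after = i)
    state$ov_cnts <- append(state$ov_cnts, state$ov_cnts[i], after = i)
  }
  state
}

# swap-remove of dense population position p; caller handles records
pop_remove_at <- function(state, p) {
  last <- length(state$pop)
  state$L <- state$L - state$links[p]
  if (p != last) {
    state$pop[[p]] <- state$pop[[last]]
    state$links[p] <- state$links[last]
  }
  state$pop[[last]] <- NULL
  state$links <- state$links[-last]
  state
}

#' Apply one recombination event
#'
#' Chooses one of the \eqn{L} available links uniformly (consuming one
#' uniform draw) and splits the owning ancestor at the chosen breakpoint
#' \code{k}: segments with \eqn{r \le k} stay, segments with
#' \eqn{\ell \ge k} move to a new ancestor, and a straddling segment
#' \eqn{(\ell, r, u)} with \eqn{\ell < k < r} is split into
#' \eqn{(\ell, k, u)} and \eqn{(k, r, u)}.  Overlap counts are unchanged:
#' no ancestral material is created or destroyed.
#'
#' @param state a simulation state with \code{L > 0}.
#' @return the updated state.
#' @export
recombination_event <- function(state) {
  if (state$L <= 0)
    ts_error("no breakable links (L = 0)", "treeseq_structure_error")
  h <- floor(runif(1) * state$L) + 1
  if (h > state$L) h <- state$L
  p <- 1L
  while (h > state$links[p]) {
    h <- h - state$links[p]
    p <- p + 1L
  }
  a <- state$pop[[p]]
  k <- as.integer(unname(a[1L, 1L] + h))

  take_left <- a[, 2L] <= k
  take_right <- a[, 1L] >= k
  straddle <- which(!take_left & !take_right)
  inside <- length(straddle) == 1L
  junction <- any(a[-nrow(a), 2L] == k & a[-1L, 1L] == k)
  left <- a[take_left, , drop = FALSE]
  right <- a[take_right, , drop = FALSE]
  if (inside) {
    s <- a[straddle, ]
    left <- rbind(left, c(s[1L], k, s[3L]))
    right <- rbind(c(k, s[2L], s[3L]), right)
  }
  state$n_recombination <- state$n_recombination + 1
  if (inside || junction)
    state$n_recomb_ancestral <- state$n_recomb_ancestral + 1

  ll <- ancestor_links(left)
  state$L <- state$L + (ll - state$links[p])
  state$links[p] <- ll
  state$pop[[p]] <- left
  state$pop[[length(state$pop) + 1L]] <- right
  state$links <- c(state$links, ancestor_links(right))
  state$L <- state$L + ancestor_links(right)
  state
}

#' Defragment an ancestor's segment list
#'
#' Touching segments mapped to the same node, \eqn{(\ell, k, u)} and
#' \eqn{(k, r, u)}, are replaced by the equivalent segment
#' \eqn{(\ell, r, u)}, repeatedly until none remain.  The ancestor's link
#' count is unchanged (its extremes are unchanged).
#'
#' @param a segment matrix.
#' @return the defragmented segment matrix.
#' @export
defragment_segments <- function(a) {
  if (nrow(a) <= 1L) return(a)
  cur <- a[1L, ]
  out <- NULL
  for (i in seq_len(nrow(a))[-1L]) {
    s <- a[i, ]
    if (cur[3L] == s[3L] && cur[2L] == s[1L]) {
      cur[2L] <- s[2L]
    } else {
      out <- rbind(out, cur)
      cur <- s
    }
  }
  out <- rbind(out, cur)
  rownames(out) <- NULL
  colnames(out) <- c("left", "right", "node")
  out
}

#' Merge two ancestors at a common ancestor event
#'
#' Walks the two segment lists in coordinate order.  Non-overlapping
#' segments and overhangs pass through to the merged ancestor unchanged.
#' Every maximal exactly-intersecting interval \eqn{[\ell, r)} with nodes
#' \eqn{u} (from \code{a}) and \eqn{v} (from \code{b}) is a coalescence: a
#' record \eqn{(\ell, r, w, (\min(u,v), \max(u,v)), t)} is emitted, and the
#' merged segment \eqn{(\cdot, w)} is retained only over the parts of
#' \eqn{[\ell, r)} still intersected by other ancestral material (overlap
#' count > 2); parts where the count is exactly 2 have found their MRCA and
#' are dropped.  All coalescing intervals within the one event share the
#' same node label \code{w} and time \code{t}; \code{w} is incremented once
#' at the end if any coalescence occurred.  The merged ancestor is
#' defragmented and re-inserted if non-empty.
#'
#' @param state a simulation state.
#' @param i,j distinct dense population indices of the two ancestors.
#' @return the updated state.
#' @export
merge_ancestors <- function(state, i, j) {
  stopifnot(i != j, i <= length(state$pop), j <= length(state$pop))
  a <- state$pop[[i]]
  b <- state$pop[[j]]
  state <- pop_remove_at(state, max(i, j))
  state <- pop_remove_at(state, min(i, j))
  state$n_common_ancestor <- state$n_common_ancestor + 1

  out_l <- integer(0); out_r <- integer(0); out_u <- integer(0)
  push <- function(l, r, u) {
    out_l[[length(out_l) + 1L]] <<- l
    out_r[[length(out_r) + 1L]] <<- r
    out_u[[length(out_u) + 1L]] <<- u
  }
  coalesced <- FALSE
  ia <- 1L; ib <- 1L
  while (ia <= nrow(a) && ib <= nrow(b)) {
    if (a[ia, 2L] <= b[ib, 1L]) { push(a[ia, 1L], a[ia, 2L], a[ia, 3L]); ia <- ia + 1L; next }
    if (b[ib, 2L] <= a[ia, 1L]) { push(b[ib, 1L], b[ib, 2L], b[ib, 3L]); ib <- ib + 1L; next }
    if (a[ia, 1L] < b[ib, 1L]) { push(a[ia, 1L], b[ib, 1L], a[ia, 3L]); a[ia, 1L] <- b[ib, 1L]; next }
    if (b[ib, 1L] < a[ia, 1L]) { push(b[ib, 1L], a[ia, 1L], b[ib, 3L]); b[ib, 1L] <- a[ia, 1L]; next }
    # exact intersection [l, r): coalescence
    l <- unname(a[ia, 1L])
    r <- unname(min(a[ia, 2L], b[ib, 2L]))
    coalesced <- TRUE
    state$n_coalescence <- state$n_coalescence + 1
    state$rl <- c(state$rl, l); state$rr <- c(state$rr, r)
    state$ru <- c(state$ru, state$w)
    state$rc1 <- c(state$rc1, unname(min(a[ia, 3L], b[ib, 3L])))
    state$rc2 <- c(state$rc2, unname(max(a[ia, 3L], b[ib, 3L])))
    state$rt <- c(state$rt, state$t)
    state <- ov_ensure_key(state, l)
    state <- ov_ensure_key(state, r)
    ki <- match(l, state$ov_keys)
    while (state$ov_keys[ki] < r) {
      if (state$ov_cnts[ki] == 2L) {
        state$ov_cnts[ki] <- 0L
      } else {
        state$ov_cnts[ki] <- state$ov_cnts[ki] - 1L
        push(state$ov_keys[ki], state$ov_keys[ki + 1L], state$w)
      }
      ki <- ki + 1L
    }
    if (a[ia, 2L] == r) ia <- ia + 1L else a[ia, 1L] <- r
    if (b[ib, 2L] == r) ib <- ib + 1L else b[ib, 1L] <- r
  }
  while (ia <= nrow(a)) { push(a[ia, 1L], a[ia, 2L], a[ia, 3L]); ia <- ia + 1L }
  while (ib <= nrow(b)) { push(b[ib, 1L], b[ib, 2L], b[ib, 3L]); ib <- ib + 1L }

  if (coalesced) state$w <- state$w + 1L
  if (length(out_l) > 0L) {
    merged <- defragment_segments(seg_matrix(out_l, out_r, out_u))
    state$pop[[length(state$pop) + 1L]] <- merged
    state$links <- c(state$links, ancestor_links(merged))
    state$L <- state$L + ancestor_links(merged)
  }
  state
}

# one common ancestor event: uniform ordered pair without replacement
common_ancestor_event <- function(state) {
  N <- length(state$pop)
  i <- floor(runif(1) * N) + 1
  if (i > N) i <- N
  j <- floor(runif(1) * (N - 1)) + 1
  if (j > N - 1) j <- N - 1
  if (j >= i) j <- j + 1
  merge_ancestors(state, i, j)
}

run_hudson_r <- function(state, max_events = 1e10) {
  n_events <- 0
  while (length(state$pop) > 0L) {
    if (length(state$pop) < 2L)
      ts_error("internal error: single non-empty ancestor remaining",
               "treeseq_internal_error")
    ev <- draw_next_event(state)
    state$t <- state$t + ev$waiting_time
    n_events <- n_events + 1
    if (n_events > max_events)
      ts_error(sprintf("event cap exceeded (%g events)", max_events),
               "treeseq_internal_error")
    state <- if (ev$event_kind == "recombination")
      recombination_event(state) else common_ancestor_event(state)
  }
  interior <- state$ov_keys < state$m
  if (any(state$ov_cnts[interior] != 0L))
    ts_error("internal error: ancestral material not fully coalesced",
             "treeseq_internal_error")
  state
}

state_output <- function(state) {
  list(left = state$rl, right = state$rr, node = state$ru,
       child1 = state$rc1, child2 = state$rc2, time = state$rt,
       n_recombination = state$n_recombination,
       n_recomb_ancestral = state$n_recomb_ancestral,
       n_common_ancestor = state$n_common_ancestor,
       n_coalescence = state$n_coalescence)
}

# recompute L and the overlap counts from scratch (oracle used in tests)
recompute_links <- function(state) {
  sum(vapply(state$pop, ancestor_links, numeric(1)))
}

overlap_count_at <- function(state, x) {
  sum(vapply(state$pop, function(a)
    sum(a[, 1L] <= x & x < a[, 2L]), numeric(1)))
}
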