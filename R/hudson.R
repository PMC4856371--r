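#' Simulate the exact coalescent with recombination
#'
#' Runs Hudson's algorithm over ancestral segments for a sample of \code{n}
#' haplotypes over \code{m} discrete sites with population-scaled
#' recombination rate \eqn{\rho = 4 N_e r (m - 1)}, and returns the
#' resulting tree sequence.  Time is measured in units of \eqn{4 N_e}
#' generations: with \eqn{k} extant ancestors, common ancestor events occur
#' at rate \eqn{k(k-1)} and recombination events at rate
#' \eqn{\rho L/(m-1)}, where \eqn{L} is the total number of breakable links
#' over all ancestors (each ancestor contributes its extreme span minus
#' one).  The algorithm draws events until all ancestral material has fully
#' coalesced; every contiguous block that coalesces emits one coalescence
#' record.
#'
#' The default \code{engine = "cpp"} runs the compiled core; \code{"r"}
#' runs the pure-R reference implementation built from the exported step
#' functions ([initialise_state()], [recombination_event()],
#' [merge_ancestors()], ...).  Both engines consume the R random number
#' stream with an identical draw sequence, so for a given seed they produce
#' bit-identical output; the R engine is only practical for small
#' instances.
#'
#' @param n sample size (>= 2).
#' @param m sequence length in discrete sites (>= 1).
#' @param rho scaled recombination rate \eqn{4 N_e r (m-1)} (>= 0).
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the run is reproducible.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference).
#' @param max_events safety cap on the number of simulated events; exceeding
#'   it raises an error (termination itself is almost sure).
#' @param validate run full record validation on the output (default TRUE;
#'   skip for large batch experiments where only counters are needed).
#' @return a [tree_sequence()] whose \code{counts} element holds the event
#'   counters: \code{n_recombination} (all recombination events),
#'   \code{n_recomb_ancestral} (those whose breakpoint fell within ancestral
#'   material -- the quantity predicted by \eqn{\rho H_{n-1}}),
#'   \code{n_common_ancestor} and \code{n_coalescence} (records emitted).
#' @examples
#' ts <- sim_coalescent(5, m = 100, rho = 1, seed = 1)
#' summary(ts)
#' @export
sim_coalescent <- function(n, m = 1L, rho = 0, seed = NULL,
                           engine = c("cpp", "r"), max_events = 1e10,
                           validate = TRUE) {
  engine <- match.arg(engine)
  n <- as.integer(n)
  m <- as.integer(m)
  if (is.na(n) || n < 2L)
    ts_error("sample size n must be >= 2", "treeseq_structure_error")
  if (is.na(m) || m < 1L)
    ts_error("sequence length m must be >= 1", "treeseq_structure_error")
  if (rho < 0) ts_error("rho must be >= 0", "treeseq_structure_error")
  if (!is.null(seed)) set.seed(seed)

  raw <- if (engine == "cpp") {
    .hudson_sim_cpp(n, m, rho, max_events)
  } else {
    state <- initialise_state(n, m, rho)
    state <- run_hudson_r(state, max_events)
    state_output(state)
  }
  records <- squash_records(data.frame(
    left = raw$left, right = raw$right, node = raw$node,
    child1 = raw$child1, child2 = raw$child2, time = raw$time))
  counts <- list(
    n_recombination = raw$n_recombination,
    n_recomb_ancestral = raw$n_recomb_ancestral,
    n_common_ancestor = raw$n_common_ancestor,
    n_coalescence = raw$n_coalescence
  )
  if (validate) {
    ts <- tree_sequence(records, n, m, counts = counts)
  } else {
    iv <- index_vectors(records)
    ts <- structure(
      list(records = records, n = n, m = m, I = iv$I, O = iv$O,
           counts = counts),
      class = "tree_sequence")
  }
  ts$params <- list(n = n, m = m, rho = rho, seed = seed, engine = engine)
  ts
}

# counters-only fast path for batch experiments
sim_counters <- function(n, m, rho, max_events = 1e10) {
  raw <- .hudson_sim_cpp(as.integer(n), as.integer(m), rho, max_events)
  list(n_records = length(raw$left),
       n_recombination = raw$n_recombination,
       n_recomb_ancestral = raw$n_recomb_ancestral,
       n_common_ancestor = raw$n_common_ancestor,
       n_coalescence = raw$n_coalescence,
       max_time = max(raw$time))
}
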