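#' Mean recombination breakpoints vs the Hudson-Kaplan expectation
#'
#' Replicates simulations at fixed (n, rho) and summarises the number of
#' recombination events whose breakpoint fell within ancestral material
#' (strictly inside an ancestral segment, or at the junction of two
#' touching segments).  The classical expectation for this count is
#' \eqn{\rho H_{n-1}}.  Note that the number of *distinct breakpoints
#' visible in the records* is systematically smaller, because some
#' recombination events leave no trace (e.g. a split followed by the
#' re-merging of the two recombinant lineages); the visible count is also
#' reported.
#'
#' @param n sample size.
#' @param rho scaled recombination rate.
#' @param reps number of replicate simulations (>= 100 for a stable
#'   standard error).
#' @param seed optional integer seed.
#' @param m sequence length in sites; the default (1e5) makes breakpoint
#'   collisions on the discrete lattice negligible at desk-scale rho.
#' @param csv optional path; when given, the per-replicate summary is also
#'   written as a CSV file with a header row.
#' @return list with \code{mean}, \code{se}, \code{expected}
#'   (\eqn{\rho H_{n-1}}), \code{mean_visible} (distinct record
#'   coordinates), \code{reps}.
#' @examples
#' \donttest{
#' mean_breakpoints_experiment(10, rho = 5, reps = 200, seed = 1)
#' }
#' @export
mean_breakpoints_experiment <- function(n, rho, reps, seed = NULL,
                                        m = 100000L, csv = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- numeric(reps)
  visible <- numeric(reps)
  for (i in seq_len(reps)) {
    raw <- .hudson_sim_cpp(as.integer(n), as.integer(m), rho, 1e10)
    counts[i] <- raw$n_recomb_ancestral
    coords <- unique(c(raw$left, raw$right))
    visible[i] <- sum(coords != 0L & coords != m)
  }
  res <- list(mean = mean(counts),
              se = stats::sd(counts) / sqrt(reps),
              expected = rho * harmonic(n - 1),
              mean_visible = mean(visible),
              reps = reps)
  if (!is.null(csv))
    utils::write.csv(data.frame(n = n, rho = rho, m = m, reps = reps,
                                mean = res$mean, se = res$se,
                                expected = res$expected,
                                mean_visible = res$mean_visible),
                     csv, row.names = FALSE)
  res
}

#' Quadratic growth of the recombination event count
#'
#' Measures the mean number of recombination events generated by Hudson's
#' algorithm over a grid of scaled recombination rates at fixed sample
#' size, and fits a quadratic in \eqn{\rho} by least squares.  The
#' empirical finding is that the event count grows quadratically -- far
#' below the exponential worst case for the full ancestral recombination
#' graph -- with leading coefficient about \eqn{8.4\times 10^{-3}} at
#' \eqn{n = 1000}.
#'
#' @param n sample size.
#' @param rho_grid numeric vector (>= 4 distinct values) of scaled
#'   recombination rates.
#' @param reps replicates per grid point.
#' @param seed optional integer seed.
#' @param sites_per_rho sequence length per unit of rho (default 1000
#'   sites, i.e. a per-site scaled recombination rate of 1e-3).
#' @param csv optional path; when given, the per-cell summary is also
#'   written as a CSV file with a header row.
#' @return list with \code{coefficients} (named a0, a1, a2),
#'   \code{r_squared}, and the per-cell summary data.frame \code{data}
#'   (columns rho, mean, se).
#' @export
fit_event_quadratic <- function(n, rho_grid, reps, seed = NULL,
                                sites_per_rho = 1000, csv = NULL) {
  rho_grid <- sort(rho_grid)
  if (length(rho_grid) < 4L)
    ts_error("need at least 4 grid points", "treeseq_structure_error")
  if (!is.null(seed)) set.seed(seed)
  means <- numeric(length(rho_grid))
  ses <- numeric(length(rho_grid))
  for (g in seq_along(rho_grid)) {
    rho <- rho_grid[g]
    m <- max(2L, as.integer(round(sites_per_rho * rho)))
    cnt <- numeric(reps)
    for (i in seq_len(reps))
      cnt[i] <- .hudson_sim_cpp(as.integer(n), m, rho, 1e10)$n_recombination
    means[g] <- mean(cnt)
    ses[g] <- stats::sd(cnt) / sqrt(reps)
  }
  cells <- data.frame(n = n, rho = rho_grid, reps = reps,
                      mean = means, se = ses)
  if (!is.null(csv)) utils::write.csv(cells, csv, row.names = FALSE)
  if (all(means == 0)) {
    return(list(coefficients = c(a0 = 0, a1 = 0, a2 = 0), r_squared = 1,
                data = data.frame(rho = rho_grid, mean = means, se = ses)))
  }
  if (length(unique(rho_grid)) < 3L)
    ts_error("degenerate rho grid: need >= 3 distinct values",
             "treeseq_structure_error")
  fit <- lm(means ~ rho_grid + I(rho_grid^2))
  cf <- coef(fit)
  names(cf) <- c("a0", "a1", "a2")
  list(coefficients = cf,
       r_squared = summary(fit)$r.squared,
       data = data.frame(rho = rho_grid, mean = means, se = ses))
}

#' Empirical check of the record-count bound
#'
#' The expected number of tree transitions is about \eqn{\rho \log n} and
#' each transition needs at most 3 records, so with the \eqn{n - 1}
#' records of the first tree the expected total record count is bounded by
#' \eqn{n + 3 \rho \ln n - 1}.  This experiment measures the mean record
#' count over replicates and compares it with the bound.
#'
#' @inheritParams mean_breakpoints_experiment
#' @return list with \code{mean_records}, \code{se}, \code{bound},
#'   \code{within_bound} (logical), \code{reps}.
#' @export
record_bound_check <- function(n, rho, reps, seed = NULL, m = 100000L) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- numeric(reps)
  for (i in seq_len(reps))
    cnt[i] <- length(.hudson_sim_cpp(as.integer(n), as.integer(m),
                                     rho, 1e10)$left)
  bound <- n + 3 * rho * log(n) - 1
  list(mean_records = mean(cnt), se = stats::sd(cnt) / sqrt(reps),
       bound = bound, within_bound = mean(cnt) <= bound, reps = reps)
}
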