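---
title: "Coalescent simulation with sparse trees and coalescence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent simulation with sparse trees and coalescence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeseqsim)
```

## The model

The package simulates the exact coalescent with recombination for a sample
of $n$ haploid sequences of $m$ discrete sites, and stores the result as a
*tree sequence*.  Going backwards in time, each extant ancestor carries a
set of non-overlapping *ancestral segments* $(\ell, r, u)$: the statement
that the half-open genomic interval $[\ell, r)$ of tree node $u$ is
ancestral to the sample.  Two kinds of events occur:

* **Recombination**, at total rate $\rho L/(m-1)$ where
  $\rho = 4 N_e r (m-1)$ is the population-scaled recombination rate and
  $L = \sum_a (\max r_a - \min \ell_a - 1)$ is the number of breakable
  links over all ancestors.  A uniformly chosen link is broken and the
  ancestor's segments are divided at the breakpoint.
* **Common ancestor events**, at rate $k(k-1)$ for $k$ extant ancestors.
  Two ancestors merge; wherever their segments intersect, a *coalescence*
  occurs and is stored as the record $(\ell, r, w, (c_1, c_2), t)$ --
  children $c_1 < c_2$ coalesce into the new node $w$ at time $t$ over
  $[\ell, r)$.  Intervals where only one extant segment would remain have
  found their most recent common ancestor and are dropped, so the
  simulation ends when no ancestral material is left.

Time is measured in units of $4 N_e$ generations throughout (the same
convention as the stated event rates: for $n = 2$ the expected pairwise
coalescence time is $1/2$).  All marginal genealogies are binary, so every
site is covered by exactly $n - 1$ records; a record shared by adjacent
trees is stored exactly once, which is what makes the encoding compact
(the expected record count is bounded by $n + 3\rho\ln n - 1$).

The marginal tree at any site is a *sparse oriented tree*: an integer
parent vector $\pi$ with leaves $1..n$, internal labels arbitrary integers
$> n$, and $\pi_u = 0$ marking the root (label 0 is reserved).

```{r}
ts <- sim_coalescent(n = 10, m = 1000, rho = 5, seed = 1)
summary(ts)
build_tree_at(ts, 500)
```

## Sequential algorithms

`iterate_trees()` visits every marginal tree left-to-right by removing and
inserting only the records that change at each transition, driven by two
index vectors: insertion order (nondecreasing left coordinate, increasing
time) and removal order (nondecreasing right coordinate, decreasing time).
Each record is inserted exactly once and removed at most once.  Where the
paper-level orderings leave ties -- simultaneous coalescences of disjoint
intervals within one common ancestor share a time -- we break them by
parent and then child labels; correctness only requires the time ordering,
and the deterministic tie-break makes output platform-independent.

`iterate_trees_with_counts()` additionally maintains, for one or more
tracked leaf sets $S$, the count $\beta_u$ of tracked leaves below every
node, by propagating each inserted/removed record's contribution along the
path to the root.  Because a mutation $(u, p)$ is attached to the *child*
node of the branch it falls on, $\beta_u/|S|$ is directly the allele
frequency in $S$; `case_control_odds_ratios()` runs two count vectors at
once to produce the 2x2 association tables of a simple GWAS scan.

## Mutations

`sim_mutations()` implements the infinite-sites model: for each record and
each child branch segment, the mutation count is Poisson with mean
$\theta \cdot (r - \ell) \cdot (t_{parent} - t_{child})$ and positions are
uniform *continuous* reals on $[\ell, r)$, so every mutation is unique
even though recombination operates on discrete sites.  The expected number
of segregating sites is $\theta m H_{n-1}$.  A node spanning several
records accrues mutations per record interval, which is forced by the fact
that a branch exists only over its record's interval.

## Which breakpoint count matches $\rho H_{n-1}$

The classical Hudson--Kaplan expectation $\rho H_{n-1}$ counts
recombination *events within ancestral material*.  The simulator counts
these directly (`n_recomb_ancestral`: breakpoints strictly inside an
ancestral segment or at the junction of two touching segments; breaks in
trapped non-ancestral gaps are excluded).  The number of *distinct
breakpoints visible in the records* (`n_breakpoints()`) is systematically
smaller -- at $n = 10$, $\rho = 5$ about 11 visible versus 14.1 events --
because an event whose recombinant halves simply re-merge leaves no trace
in the records.  `mean_breakpoints_experiment()` therefore compares the
event count, not the visible count, with $\rho H_{n-1}$; both are
reported.

## Engines, reproducibility, numerics

The simulation core is compiled (Rcpp); a pure-R transliteration of every
step (`initialise_state()`, `draw_next_event()`, `recombination_event()`,
`merge_ancestors()`, `defragment_segments()`) serves as the readable
reference implementation.  Both consume R's RNG with an identical draw
sequence, so for a given seed they produce **bit-identical** records; the
test suite enforces this, which pins the compiled merge/split logic to the
inspectable R code.  Uniform link choice uses a cumulative-sum search
(a Fenwick tree in the compiled engine -- the contract is only
uniformity); overlap bookkeeping uses a sorted breakpoint-to-count map,
chosen because it makes the MRCA-completion rule a logarithmic query and
is directly testable against brute-force recounts.  The common-ancestor
pair is a uniform ordered pair without replacement, matching the rate
$k(k-1)$.  Node times are stored once per node; Newick output (the only
lossy format, branch lengths at a stated precision) is derived from them,
and the text/HDF5 containers round-trip exactly (times are written as
shortest round-trip decimals).

Degenerate inputs: $m = 1$ disables recombination ($L = 0$) and reduces
the simulator to the single-locus (Kingman) coalescent; $\rho = 0$
likewise.  An `max_events` cap guards the (almost surely terminating)
event loop and raises a diagnostic if exceeded.

## The verification experiments and their problem sizes

The package's claims are checked against analytic oracles rather than
external data; the test suite and `scripts/acceptance.R` use these
configurations, chosen to give tight Monte-Carlo bands at desk runtimes:

* **Kingman limit** -- $n = 10$, $m = 1$, $10^4$ replicates: mean
  $T_{MRCA} = 1 - 1/n = 0.9$, always $n - 1 = 9$ records.
* **Hudson--Kaplan** -- $n = 10$, $\rho = 5$, $m = 10^5$ (so lattice
  collisions are negligible), $10^3$ replicates: mean within-ancestral
  events $\approx \rho H_9 = 14.14$.
* **Segregating sites** -- $n = 10$, $\theta m = 10$, $10^3$ replicates:
  mean $\approx \theta m H_9 = 28.29$.  $\rho = 0$ isolates the mutation
  law; mutation-with-recombination agreement is covered by the
  haplotype/frequency oracle tests.
* **Record bound** -- $(n, \rho) \in \{(10, 5), (100, 20)\}$, 200
  replicates: mean record count below $n + 3\rho\ln n - 1$.
* **Quadratic event growth** -- $n = 1000$ over
  $\rho \in \{5000, \dots, 50000\}$ with $m = 1000\rho$ (a per-site scaled
  rate of $10^{-3}$, the 5--50 megabase regime), 10 replicates per point.
  The mean recombination-event count is fitted by a quadratic in $\rho$;
  the grid spans the regime where the quadratic term dominates, giving a
  leading coefficient of about $8 \times 10^{-3}$ with $R^2 > 0.999$.
  At much smaller $\rho$ the apparent local exponent is below 2 and a
  quadratic fit would estimate a larger leading coefficient; the
  asymptotic regime is the meaningful one.
* **Large-simulation pipeline, scaled** -- the flagship configuration
  (per-site scaled recombination and mutation rates of $10^{-3}$) is run
  at $n = 1000$ over $10^6$ sites rather than $10^5$ samples over $10^8$
  sites; the same laws are verified at that scale in seconds:
  $\theta m H_{n-1}$ mutations, $\rho H_{n-1}$ within-ancestral
  recombination events, and a distinct-tree count of about $11/12$ of the
  mutation count (distinct trees undercount events because some
  transitions are invisible; the full-scale configuration shows the same
  ratio).  Nothing in the
  implementation depends on the scale other than runtime; the full-size
  run remains available through the same API.

## What the generator does and does not emulate

Simulated data are the neutral, panmictic, constant-size coalescent with
uniform recombination: no demography, population structure, migration,
growth, recombination maps, gene conversion or selection.  Passing tests
therefore validate the algorithms and the encoding, not the fit of this
model to any real population.  Haplotypes are binary (ancestral/derived)
under infinite sites; finite-sites and recurrent mutation are out of
scope, as are multi-merger coalescents (the record stores an ordered child
pair; the data model would extend to longer child lists, but the simulator
only emits pairs).

## Design choices made where the design was open

* **Half-open intervals on discrete sites** everywhere; coordinates
  $0..m$; node label 0 reserved for "root/absent".
* **Index-vector tie-breaks** by parent then child labels (see above).
* **Odds ratios** are reported raw, with `Inf`/`0`/`NaN` for zero cells,
  and an optional Haldane--Anscombe $+0.5$ flag -- the statistic stays
  transparent rather than silently corrected.
* **Mutation tuples store the child node** of the branch carrying the
  mutation, so carriers are exactly the leaves below the stored node.
* **The container schema** (HDF5 groups `/metadata`, `/records` with a
  $2 \times M$ `children` matrix, `/mutations`) is this package's own
  stable, versioned layout; it is not claimed to interoperate with any
  other tool's container format.
* **CLI**: ms-flavoured but deliberately not a byte-level ms clone; only
  the documented flags are supported.

## Known limitations

* The pure-R engine is a reference, not a performance path; use it only
  at small $n$, $m$.
* `marginal_trees()` materialises every tree; for long sequences use the
  visitor interface.
* Newick export is inherently lossy at the stated precision and is the
  slowest output path, as expected for a per-tree text format.
* The record-count bound $n + 3\rho\ln n - 1$ concerns the expectation;
  individual replicates can exceed it.
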