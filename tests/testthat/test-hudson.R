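test_that("the initial state holds n spanning ancestors", {
  st <- initialise_state(4, 10)
  expect_length(st$pop, 4)
  expect_identical(st$L, 36)
  expect_identical(st$t, 0)
  expect_identical(st$w, 5L)
  expect_identical(st$ov_cnts[1], 4L)
  for (u in 1:4)
    expect_equal(unname(st$pop[[u]][1, ]), c(0, 10, u))
  st2 <- initialise_state(2, 1)
  expect_identical(st2$L, 0)
  expect_error(initialise_state(1, 10), class = "treeseq_structure_error")
  expect_error(initialise_state(3, 0), class = "treeseq_structure_error")
})

test_that("ancestor links span the extreme coordinates, gaps included", {
  expect_equal(ancestor_links(seg_matrix(0, 10, 1)), 9)
  expect_equal(ancestor_links(seg_matrix(c(0, 7), c(2, 10), c(1, 2))), 9)
  expect_equal(ancestor_links(seg_matrix(3, 4, 1)), 0)
  expect_error(ancestor_links(seg_matrix(0, 10, 1)[0, , drop = FALSE]),
               class = "treeseq_structure_error")
})

test_that("event kinds and waiting times follow the stated rates", {
  # rho = 0: only common ancestor events
  st <- initialise_state(4, 10, rho = 0)
  set.seed(1)
  kinds <- replicate(200, draw_next_event(st)$event_kind)
  expect_true(all(kinds == "common_ancestor"))
  # L = 0 with several ancestors: recombination probability 0
  st0 <- initialise_state(5, 1, rho = 3)
  kinds0 <- replicate(200, draw_next_event(st0)$event_kind)
  expect_true(all(kinds0 == "common_ancestor"))
  # n = 2, m = 1: waiting time ~ Exp(2), mean 1/2
  st2 <- initialise_state(2, 1)
  set.seed(2)
  waits <- replicate(10000, draw_next_event(st2)$waiting_time)
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - 0.5), 3 * se)
})

test_that("recombination splits an ancestor at a uniform link", {
  # one breakable ancestor spanning [0,10): split at uniform k in 1..9
  set.seed(31)
  ks <- integer(0)
  for (i in 1:400) {
    st <- initialise_state(2, 10, rho = 1)
    st$pop[[2]] <- seg_matrix(0, 1, 2)  # unbreakable companion
    st$links <- c(9, 0)
    st$L <- 9
    st <- recombination_event(st)
    expect_length(st$pop, 3)
    k <- st$pop[[3]][1, 1]
    ks <- c(ks, k)
    expect_equal(unname(st$pop[[1]]), unname(seg_matrix(0, k, 1)))
    expect_equal(unname(st$pop[[3]]), unname(seg_matrix(k, 10, 1)))
    expect_identical(st$L, 8)  # 9 links become (k-1) + (9-k)
    expect_equal(st$n_recombination, 1)
    expect_equal(st$n_recomb_ancestral, 1)
  }
  # uniform over the 9 interior breakpoints
  expect_setequal(unique(ks), 1:9)
  expect_gt(suppressWarnings(chisq.test(table(ks))$p.value), 1e-4)
})

test_that("a break in a trapped gap separates whole segments", {
  # ancestor [(0,2),(5,8)] has 7 links; k in 3..4 falls in the gap
  # ancestor [(0,2),(5,8)]: breakpoints k in {2,3,4,5} fall in or at the
  # trapped gap and separate the two segments whole; k in {1} splits the
  # first segment, k in {6,7} the second
  set.seed(7)
  seen_gap <- FALSE
  seen_split <- FALSE
  for (i in 1:100) {
    st <- initialise_state(2, 8, rho = 1)
    st$pop[[1]] <- seg_matrix(c(0, 5), c(2, 8), c(1, 1))
    st$pop[[2]] <- seg_matrix(0, 1, 2)  # unbreakable companion
    st$links <- c(ancestor_links(st$pop[[1]]), 0)
    st$L <- treeseqsim:::recompute_links(st)
    st <- recombination_event(st)
    left <- st$pop[[1]]; right <- st$pop[[3]]
    if (nrow(left) == 1 && left[1, 2] == 2 && right[1, 1] == 5) {
      seen_gap <- TRUE
      # segments pass through whole; not within ancestral material
      expect_equal(unname(left), unname(seg_matrix(0, 2, 1)))
      expect_equal(unname(right), unname(seg_matrix(5, 8, 1)))
      expect_equal(st$n_recomb_ancestral, 0)
    } else {
      seen_split <- TRUE
      expect_equal(st$n_recomb_ancestral, 1)
    }
    # material conserved in every case
    expect_equal(sum(left[, 2] - left[, 1]) + sum(right[, 2] - right[, 1]), 5)
  }
  expect_true(seen_gap)
  expect_true(seen_split)
})

test_that("link choice is uniform over ancestors' links", {
  # ancestors with 9 and 3 links: chosen with probability 9/12 and 3/12
  set.seed(99)
  reps <- 4000
  first <- 0
  for (i in 1:reps) {
    st <- initialise_state(2, 14, rho = 1)
    st$pop[[1]] <- seg_matrix(0, 10, 1)
    st$pop[[2]] <- seg_matrix(10, 14, 2)
    st$links <- c(9, 3)
    st$L <- 12
    st <- recombination_event(st)
    # the split ancestor's replacement stays in place; detect by span
    if (st$pop[[1]][nrow(st$pop[[1]]), 2] < 10 ||
        st$pop[[3]][1, 1] < 10) first <- first + 1
  }
  p <- first / reps
  se <- sqrt(0.75 * 0.25 / reps)
  expect_lt(abs(p - 0.75), 3 * se)
})

test_that("merging disjoint ancestors emits no record", {
  st <- initialise_state(3, 10)
  st$pop[[1]] <- seg_matrix(0, 3, 1)
  st$pop[[2]] <- seg_matrix(5, 8, 2)
  st$links <- vapply(st$pop, ancestor_links, numeric(1))
  st$L <- treeseqsim:::recompute_links(st)
  st$ov_keys <- c(0L, 3L, 5L, 8L, 10L)
  st$ov_cnts <- c(2L, 1L, 2L, 1L, 0L)
  st <- merge_ancestors(st, 1, 2)
  expect_length(st$pop, 2)
  merged <- st$pop[[2]]  # swap-remove moves ancestor 3 to slot 1
  expect_equal(unname(merged), unname(seg_matrix(c(0, 5), c(3, 8), c(1, 2))))
  expect_length(st$rl, 0)
  expect_equal(st$w, 4L)  # unchanged: no coalescence
})

test_that("the final pairwise merge empties the population", {
  st <- initialise_state(2, 1)
  st$t <- 0.7
  st <- merge_ancestors(st, 1, 2)
  expect_length(st$pop, 0)
  expect_equal(st$rl, 0L)
  expect_equal(st$rr, 1L)
  expect_equal(st$ru, 3L)
  expect_equal(st$rc1, 1L)
  expect_equal(st$rc2, 2L)
  expect_equal(st$rt, 0.7)
  expect_true(all(st$ov_cnts[st$ov_keys < st$m] == 0))
})

test_that("partial overlap subdivides into overhangs and an intersection", {
  # a = [(0,6,1)], b = [(4,10,2)], third ancestor spans [0,10):
  # record on [4,6), merged ancestor [(0,4,1),(4,6,w),(6,10,2)]
  st <- initialise_state(3, 10)
  st$pop[[1]] <- seg_matrix(0, 6, 1)
  st$pop[[2]] <- seg_matrix(4, 10, 2)
  st$links <- vapply(st$pop, ancestor_links, numeric(1))
  st$L <- treeseqsim:::recompute_links(st)
  st$ov_keys <- c(0L, 4L, 6L, 10L)
  st$ov_cnts <- c(2L, 3L, 2L, 0L)
  st$t <- 0.4
  st <- merge_ancestors(st, 1, 2)
  expect_equal(st$rl, 4L)
  expect_equal(st$rr, 6L)
  expect_equal(st$ru, 4L)
  expect_equal(st$rc1, 1L)
  expect_equal(st$rc2, 2L)
  merged <- st$pop[[2]]
  expect_equal(unname(merged),
               unname(seg_matrix(c(0, 4, 6), c(4, 6, 10), c(1, 4, 2))))
  expect_equal(st$w, 5L)
  # overlap on [4,6) dropped from 3 to 2
  expect_identical(st$ov_cnts[st$ov_keys == 4L], 2L)
})

test_that("defragmentation merges touching same-node segments", {
  expect_equal(unname(defragment_segments(
    seg_matrix(c(0, 3), c(3, 7), c(1, 1)))),
    unname(seg_matrix(0, 7, 1)))
  a <- seg_matrix(c(0, 3), c(3, 7), c(1, 2))
  expect_equal(unname(defragment_segments(a)), unname(a))
  expect_equal(unname(defragment_segments(
    seg_matrix(c(0, 2, 4), c(2, 4, 9), c(1, 1, 1)))),
    unname(seg_matrix(0, 9, 1)))
})

test_that("the compiled and reference engines are bit-identical", {
  params <- list(c(2, 1, 0), c(5, 1, 0), c(4, 30, 2), c(8, 100, 5),
                 c(3, 10, 0.5))
  for (p in params) {
    for (s in 1:4) {
      a <- sim_coalescent(p[1], p[2], p[3], seed = s, engine = "cpp")
      b <- sim_coalescent(p[1], p[2], p[3], seed = s, engine = "r")
      expect_identical(a$records, b$records)
      expect_identical(a$counts, b$counts)
    }
  }
})

test_that("identical seeds give identical simulations", {
  a <- sim_coalescent(7, 80, 4, seed = 123)
  b <- sim_coalescent(7, 80, 4, seed = 123)
  expect_identical(a$records, b$records)
})

test_that("link and overlap bookkeeping match recomputation from scratch", {
  # drive the reference engine event by event and re-derive L and the
  # overlap counts from the population after every event
  set.seed(555)
  for (rep in 1:4) {
    st <- initialise_state(5, 30, rho = 2)
    while (length(st$pop) > 0) {
      ev <- draw_next_event(st)
      st$t <- st$t + ev$waiting_time
      before <- vapply(st$ov_keys[st$ov_keys < st$m],
                       function(x) treeseqsim:::overlap_count_at(st, x),
                       numeric(1))
      st <- if (ev$event_kind == "recombination")
        recombination_event(st) else common_ancestor_event(st)
      expect_identical(st$L, treeseqsim:::recompute_links(st))
      keys <- st$ov_keys[st$ov_keys < st$m]
      actual <- vapply(keys,
                       function(x) treeseqsim:::overlap_count_at(st, x),
                       numeric(1))
      expect_equal(as.numeric(st$ov_cnts[seq_along(keys)]), actual)
      if (ev$event_kind == "recombination") {
        # recombination never changes overlap counts (keys unchanged too)
        expect_equal(actual, before)
      }
    }
  }
})

test_that("with one site the simulator is the Kingman coalescent", {
  set.seed(314)
  reps <- 2000
  nrec <- numeric(reps)
  tmrca <- numeric(reps)
  for (i in seq_len(reps)) {
    out <- treeseqsim:::sim_counters(10, 1, 0)
    nrec[i] <- out$n_records
    tmrca[i] <- out$max_time
  }
  expect_true(all(nrec == 9))
  se <- sd(tmrca) / sqrt(reps)
  expect_lt(abs(mean(tmrca) - 0.9), 3 * se)
})

test_that("simulated outputs validate across a parameter grid", {
  set.seed(777)
  for (p in list(c(2, 1, 0), c(2, 2, 1), c(10, 50, 3), c(6, 500, 10),
                 c(15, 40, 2))) {
    ts <- sim_coalescent(p[1], p[2], p[3])  # validate = TRUE throws on error
    expect_s3_class(ts, "tree_sequence")
    # n - 1 records cover every site; root times positive
    expect_true(all(ts$records$time > 0))
  }
})

test_that("the event cap raises a diagnostic", {
  expect_error(sim_coalescent(20, 100, 5, seed = 1, max_events = 3),
               "event cap")
})
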