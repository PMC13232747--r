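test_that("initialization fills every group to capacity with pool types", {
  cfg <- sim_config(d = 1000, m = 3, n = 10, seed = 1, n_events = 10)
  set.seed(1)
  st <- initialize_population(cfg)
  expect_equal(dim(st$counts), c(1000L, 3L))
  expect_equal(unname(colSums(st$counts)), rep(10L, 3))
  expect_lte(sum(rowSums(st$counts) > 0L), 30L)   # at most m*n distinct types
  cfg1 <- sim_config(d = 1, m = 4, n = 5, seed = 1, n_events = 10)
  st1 <- initialize_population(cfg1)
  expect_equal(unname(st1$counts[1, ]), rep(5L, 4))
})

test_that("initial distinct-type count matches the occupancy formula", {
  cfg <- sim_config(d = 50, m = 6, n = 20, seed = 1, n_events = 10)
  set.seed(99)
  distinct <- replicate(300, sum(rowSums(initialize_population(cfg)$counts) > 0L))
  expected <- 50 * (1 - (1 - 1 / 50)^120)
  expect_equal(mean(distinct), expected, tolerance = 0.01)
})

test_that("splitting conserves composition and respects the size-2 floor", {
  set.seed(5)
  # size-4 parent: only the (2,2) allocation survives the constraint
  off <- split_group(c(2L, 2L))
  expect_equal(sum(off$A), 2L)
  expect_equal(sum(off$B), 2L)
  for (rep in 1:200) {
    d <- sample(2:6, 1)
    grp <- as.integer(rmultinom(1, size = sample(4:15, 1), prob = rep(1, d)))
    while (sum(grp) < 4L) grp[1] <- grp[1] + 1L
    off <- split_group(grp)
    expect_identical(off$A + off$B, grp)          # exact conservation
    expect_gte(sum(off$A), 2L)
    expect_gte(sum(off$B), 2L)
  }
  # homogeneous parent gives homogeneous offspring
  off <- split_group(c(0L, 7L))
  expect_equal(off$A[1] + off$B[1], 0L)
  expect_error(split_group(c(2L, 1L)), "unsplittable")
})

test_that("overflow resolution culls or splits as configured", {
  cfg <- sim_config(d = 3, m = 2, n = 5, q = 0, seed = 1, n_events = 10)
  st <- population_state(matrix(c(3L, 2L, 1L, 2L, 0L, 2L), 3, 2))  # sizes 6, 4
  set.seed(7)
  res <- resolve_overflow(st, 1, cfg)
  expect_equal(res$event, "cull")
  expect_equal(sum(res$state$counts[, 1]), 5L)
  expect_equal(ncol(res$state$counts), 2L)
  expect_error(resolve_overflow(res$state, 1, cfg), "no overflow")

  # single-group populations never split, whatever q says
  cfg1 <- sim_config(d = 3, m = 1, n = 5, q = 1, seed = 1, n_events = 10)
  st1 <- population_state(matrix(c(3L, 2L, 1L), 3, 1))
  set.seed(8)
  res1 <- resolve_overflow(st1, 1, cfg1)
  expect_equal(res1$event, "cull")
  expect_equal(sum(res1$state$counts), 5L)
})

test_that("culling removes a uniformly chosen individual", {
  # counts {1: 6, 2: 1} at n = 6: the lone type-2 individual is removed
  # with probability 1/7
  cfg <- sim_config(d = 2, m = 2, n = 6, q = 0, seed = 1, n_events = 10)
  set.seed(11)
  hits <- replicate(4000, {
    st <- population_state(matrix(c(6L, 1L, 2L, 0L), 2, 2))
    res <- resolve_overflow(st, 1, cfg)
    res$state$counts[2, 1] == 0L
  })
  expect_equal(mean(hits), 1 / 7, tolerance = 0.15)
})

test_that("lambda = 1 gives pure immigration, lambda = 0 closes the pool", {
  A <- generate_matrix(6, seed = 2)
  cfg <- sim_config(d = 6, m = 2, n = 8, lam = 1, q = 0, seed = 3,
                    n_events = 300, sample_every = 50)
  traj <- run_simulation(cfg, A)
  expect_equal(traj$event_log$immigration, 300L)
  expect_equal(traj$event_log$replication, 0L)

  cfg0 <- sim_config(d = 40, m = 2, n = 8, lam = 0, q = 0.01, seed = 4,
                     n_events = 2000, sample_every = 100)
  A0 <- generate_matrix(40, seed = 5)
  traj0 <- run_simulation(cfg0, A0)
  expect_equal(traj0$event_log$immigration, 0L)
  init_types <- which(rowSums(traj0$snapshots[[1]]) > 0L)
  for (s in traj0$snapshots) {
    expect_true(all(which(rowSums(s) > 0L) %in% init_types))
  }
})

test_that("neutral closed single-group dynamics fix types at their initial frequency", {
  # beta = 0, lambda = 0, m = 1, q = 0: a Moran-like neutral birth-death
  # chain whose fixation probability is the initial frequency (martingale).
  A <- matrix(c(2, -1, 1, 0.5), 2, 2)     # irrelevant at beta = 0
  reps <- 2000
  x0 <- integer(reps); fix1 <- logical(reps); absorbed <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(d = 2, m = 1, n = 6, beta = 0, lam = 0, q = 0,
                      seed = 10000 + r, n_events = 400, sample_every = 400)
    traj <- run_simulation(cfg, A)
    x0[r] <- traj$snapshots[[1]][1, 1]
    final <- traj$snapshots[[length(traj$snapshots)]]
    absorbed[r] <- sum(final > 0L) == 1L
    fix1[r] <- final[1, 1] > 0L
  }
  expect_gt(mean(absorbed), 0.95)
  ok <- absorbed
  # martingale: fixation indicator minus initial frequency has mean zero
  expect_lt(abs(mean(fix1[ok] - x0[ok] / 6)), 0.03)
  # conditional on the balanced 3/3 start, each type fixes about half the time
  bal <- ok & x0 == 3L
  expect_gt(sum(bal), 300)
  expect_equal(mean(fix1[bal]), 0.5, tolerance = 0.12)
})

test_that("runs are deterministic and the engines agree bit for bit", {
  A <- generate_matrix(8, seed = 3)
  cfg <- sim_config(d = 8, m = 3, n = 10, beta = 1, lam = 0.2, q = 0.5,
                    seed = 11, n_events = 2500, sample_every = 100)
  t1 <- run_simulation(cfg, A)
  t2 <- run_simulation(cfg, A)
  expect_identical(t1$snapshots, t2$snapshots)
  tr <- run_simulation(cfg, A, engine = "r")
  expect_identical(t1$clocks, tr$clocks)
  expect_identical(t1$snapshots, tr$snapshots)
  expect_identical(t1$event_log, tr$event_log)

  cfg2 <- sim_config(d = 6, m = 4, n = 8, beta = 0.5, lam = 0.3, q = 0.9,
                     seed = 5, n_events = 1500, sample_every = 100,
                     parent_selection = "group-uniform", removal_pool = "all")
  A2 <- generate_matrix(6, seed = 9)
  expect_identical(run_simulation(cfg2, A2)$snapshots,
                   run_simulation(cfg2, A2, engine = "r")$snapshots)
})

test_that("neutral runs are independent of the payoff matrix", {
  cfg <- sim_config(d = 15, m = 3, n = 10, beta = 0, lam = 0.1, q = 0.3,
                    seed = 21, n_events = 4000, sample_every = 200)
  tA <- run_simulation(cfg, generate_matrix(15, seed = 1))
  tB <- run_simulation(cfg, generate_matrix(15, seed = 2))
  expect_identical(tA$snapshots, tB$snapshots)
})

test_that("population invariants hold at every snapshot", {
  A <- generate_matrix(30, seed = 6)
  for (q in c(0.001, 1.0)) {
    cfg <- sim_config(d = 30, m = 4, n = 8, beta = 1, lam = 0.1, q = q,
                      seed = 31, n_events = 8000, sample_every = 200)
    traj <- run_simulation(cfg, A)
    for (s in traj$snapshots) {
      expect_equal(ncol(s), 4L)
      sizes <- colSums(s)
      expect_true(all(sizes >= 2L & sizes <= 8L))
      expect_true(sum(sizes) >= 2L * 4L && sum(sizes) <= 4L * 8L)
    }
    el <- traj$event_log
    expect_equal(el$immigration + el$replication, 8000L)
    expect_equal(el$group_removal, el$split)
  }
})

test_that("immigration frequency concentrates around lambda", {
  cfg <- sim_config(d = 10, m = 2, n = 10, lam = 0.25, q = 0, seed = 41,
                    n_events = 20000, sample_every = 20000)
  traj <- run_simulation(cfg, generate_matrix(10, seed = 1))
  expect_equal(traj$event_log$immigration / 20000, 0.25, tolerance = 0.05)
})

test_that("frequent splitting keeps groups below carrying capacity", {
  A <- generate_matrix(25, seed = 8)
  mean_size <- function(q) {
    cfg <- sim_config(d = 25, m = 5, n = 10, beta = 1, lam = 0.1, q = q,
                      seed = 51, n_events = 10000, sample_every = 250)
    traj <- run_simulation(cfg, A)
    half <- traj$clocks >= 5000
    mean(vapply(traj$snapshots[half], function(s) mean(colSums(s)), numeric(1)))
  }
  m_rare <- mean_size(0.001)
  m_freq <- mean_size(1.0)
  expect_gt(m_rare, 9.5)        # groups sit at capacity when splits are rare
  expect_lt(m_freq, m_rare)     # frequent splitting keeps them below it
})

test_that("run_simulation rejects mismatched dimensions", {
  cfg <- sim_config(d = 10, m = 2, n = 6, seed = 1, n_events = 10)
  expect_error(run_simulation(cfg, generate_matrix(12, seed = 1)),
               "dimension mismatch")
})
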