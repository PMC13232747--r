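snap <- function(...) {
  # build a d x m count matrix column by column
  cols <- list(...)
  do.call(cbind, lapply(cols, as.integer))
}

test_that("richness counts distinct present types", {
  s <- snap(c(4, 0, 0, 0), c(4, 0, 0, 0))
  expect_equal(total_richness(s), 1L)
  s2 <- snap(c(1, 2, 1, 0, 0, 0, 0), c(0, 0, 0, 1, 1, 1, 1))
  expect_equal(total_richness(s2), 7L)                # disjoint sets 3 + 4
  expect_lte(total_richness(s2), min(nrow(s2), sum(s2)))
  gr <- group_richness(snap(c(3, 0, 0), c(1, 1, 2)))
  expect_equal(gr$per_group, c(1L, 3L))
  expect_equal(gr$mean, 2)
})

test_that("Shannon index has its closed-form values and bounds", {
  expect_equal(shannon_index(snap(c(5, 0))), 0)
  s_unif <- snap(c(2, 2, 2, 2))
  expect_equal(shannon_index(s_unif), log(4))
  expect_equal(shannon_index(snap(c(3, 1))),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  set.seed(20)
  for (rep in 1:20) {
    s <- matrix(as.integer(rpois(12, 3)), 4, 3)
    if (sum(s) == 0L) s[1] <- 1L
    H <- shannon_index(s)
    expect_gte(H, 0)
    expect_lte(H, log(total_richness(s)) + 1e-12)
  }
})

test_that("group similarity is mean pairwise Jaccard on presence sets", {
  ident <- snap(c(2, 1, 0), c(1, 3, 0), c(5, 1, 0))
  expect_equal(group_similarity(ident), 1)
  disjoint <- snap(c(2, 0, 0, 0), c(0, 0, 1, 3))
  expect_equal(group_similarity(disjoint), 0)
  # sets {1,2,3} and {2,3,4}: |intersection| 2, |union| 4
  s <- snap(c(1, 1, 1, 0), c(0, 2, 1, 1))
  expect_equal(group_similarity(s), 0.5)
  expect_error(group_similarity(snap(c(1, 2))), "one group")
  # Bray-Curtis option is abundance-weighted
  sb <- snap(c(3, 1), c(1, 3))
  expect_equal(group_similarity(sb, method = "bray"), 1 - 4 / 8)
})

test_that("homogeneous fraction counts single-type groups", {
  expect_equal(homogeneous_fraction(snap(c(4, 0), c(0, 3))), 1)
  expect_equal(homogeneous_fraction(snap(c(2, 1), c(1, 3))), 0)
  s <- snap(c(2, 0), c(1, 1), c(0, 3), c(1, 2), c(2, 1), c(1, 1))
  expect_equal(homogeneous_fraction(s), 1 / 3)
})

test_that("realized interaction frequencies weight co-occurring pairs", {
  # pair (1,2) bistable, pair (3,4) dominance of 3 over 4
  A <- diag(4)
  A[1, 2] <- -1; A[2, 1] <- -1                 # neither invades: bistable
  A[3, 3] <- 1; A[4, 3] <- 0; A[3, 4] <- 1; A[4, 4] <- 0  # 3 dominates 4
  tab <- classify_all(A)
  expect_equal(tab$class[tab$i == 1 & tab$j == 2], "bistability")
  expect_equal(tab$winner[tab$i == 3 & tab$j == 4], 3L)

  # one group {i:2, j:3} on a coexistence pair: all weight on coexistence
  Ac <- matrix(c(0, 1, 2, 0), 2, 2)
  f1 <- realized_interaction_frequencies(list(snap(c(2, 3))),
                                         classify_all(Ac))
  expect_equal(as.vector(f1), c(0, 0, 1))

  # groups {1:1, 2:1} (bistable, weight 1) and {3:1, 4:3} (dominance,
  # weight 3): dominance 3/4, bistability 1/4
  s <- snap(c(1, 1, 0, 0), c(0, 0, 1, 3))
  f2 <- realized_interaction_frequencies(list(s), tab)
  expect_equal(as.vector(f2), c(3 / 4, 1 / 4, 0))

  # presence weighting ignores abundances
  f3 <- realized_interaction_frequencies(list(s), tab, weighting = "presence")
  expect_equal(as.vector(f3), c(1 / 2, 1 / 2, 0))

  # homogeneous groups realize no interactions
  expect_error(realized_interaction_frequencies(list(snap(c(3, 0), c(0, 2))),
                                                classify_all(Ac)),
               "no interactions")
})

test_that("single-group populations collapse population and group measures", {
  set.seed(21)
  s <- matrix(as.integer(rpois(8, 2) + 1L), 8, 1)
  expect_equal(total_richness(s), group_richness(s)$per_group[1])
  expect_equal(group_richness(s)$mean, total_richness(s))
})

test_that("abundance ranking averages the trailing window and ranks both ways", {
  d <- 5
  A <- generate_matrix(d, seed = 22)
  s <- snap(c(6, 3, 1, 0, 0))
  traj <- fake_trajectory(rep(list(s), 20))
  rk <- abundance_ranking(traj, A, last_k = 15)
  expect_equal(unname(rk$abundance), c(0.6, 0.3, 0.1, 0, 0))
  expect_equal(rk$by_abundance$type, c(1L, 2L, 3L))
  expect_equal(rk$by_self_payoff$type,
               intersect(order(-diag(A)), 1:3))
  expect_error(abundance_ranking(fake_trajectory(rep(list(s), 5)), A,
                                 last_k = 15), "fewer than")
})

test_that("turnover summarizes leader run lengths", {
  mk <- function(lead) {
    s <- matrix(1L, 3, 1)
    s[lead, 1] <- 5L
    s
  }
  traj <- fake_trajectory(lapply(c(1, 1, 2, 2, 2, 1), mk))
  ts <- turnover_stats(traj)
  expect_equal(ts$leaders, c(1L, 1L, 2L, 2L, 2L, 1L))
  expect_equal(as.integer(ts$run_lengths), c(2L, 3L, 1L))
  expect_equal(ts$mean_duration, 2)
  const <- fake_trajectory(rep(list(mk(2)), 7))
  expect_equal(turnover_stats(const)$mean_duration, 7)
  # ties break toward the lowest type index
  tie <- fake_trajectory(rep(list(matrix(2L, 3, 1)), 2))
  expect_equal(unique(turnover_stats(tie)$leaders), 1L)
})

test_that("metrics report aggregates a real trajectory coherently", {
  A <- generate_matrix(15, seed = 23)
  cfg <- sim_config(d = 15, m = 3, n = 8, q = 0.01, seed = 24,
                    n_events = 3000, sample_every = 150, burn_in = 1500)
  traj <- run_simulation(cfg, A)
  rep_ <- metrics_report(traj, A = A, table = classify_all(A))
  expect_s3_class(rep_, "metrics_report")
  expect_equal(nrow(rep_$per_snapshot), length(traj$clocks))
  expect_true(all(rep_$per_snapshot$homogeneous_fraction >= 0 &
                  rep_$per_snapshot$homogeneous_fraction <= 1))
  expect_true(all(rep_$per_snapshot$group_similarity >= 0 &
                  rep_$per_snapshot$group_similarity <= 1))
  if (!is.null(rep_$realized_frequencies)) {
    expect_equal(sum(rep_$realized_frequencies), 1)
  }
  expect_gte(rep_$turnover$mean_duration, 1)
})
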