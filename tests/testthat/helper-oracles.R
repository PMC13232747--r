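# Independent oracles used across test files.

# Within-group replication probabilities by explicit enumeration of every
# individual: each individual's payoff is the mean payoff over the other
# group members, fitness is exp(beta * payoff), and a type's replication
# probability is the summed fitness of its individuals over the group total.
brute_force_group_probs <- function(group, A, beta) {
  p <- which(group > 0L)
  types <- rep.int(p, group[p])
  f_ind <- vapply(seq_along(types), function(i) {
    others <- types[-i]
    pi <- if (length(others) == 0L) 0 else mean(A[types[i], others])
    exp(beta * pi)
  }, numeric(1))
  probs <- vapply(p, function(j) sum(f_ind[types == j]), numeric(1)) / sum(f_ind)
  names(probs) <- p
  probs
}

# Endpoint of two-type replicator dynamics dx/dt = x(1-x) * (pi_1 - pi_2),
# integrated numerically: the independent oracle for the pair classifier.
replicator_endpoint <- function(a11, a12, a21, a22, x0, t_end = 20000) {
  deriv <- function(t, y, parms) {
    x <- y[1]
    list(x * (1 - x) * ((a11 - a21) * x + (a12 - a22) * (1 - x)))
  }
  out <- deSolve::ode(c(x = x0), times = c(0, t_end), func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), 2])
}

# Endpoint predicted from the classifier's label plus, for bistable pairs,
# the position of the unstable interior point relative to the start.
predicted_endpoint <- function(a11, a12, a21, a22, x0) {
  A <- matrix(c(a11, a21, a12, a22), 2, 2)
  cls <- classify_pair(A, 1, 2)
  xstar <- (a12 - a22) / ((a12 - a22) + (a21 - a11))
  switch(cls,
         first_dominates = 1,
         second_dominates = 0,
         coexistence = xstar,
         bistability = if (x0 > xstar) 1 else 0,
         degenerate = NA_real_)
}

# Fabricate a sim_trajectory from a list of count matrices (for metric
# tests that need full control over the snapshots).
fake_trajectory <- function(snapshots, sample_every = 1L, ...) {
  d <- nrow(snapshots[[1]])
  m <- ncol(snapshots[[1]])
  cfg <- sim_config(d = d, m = m, n = max(colSums(snapshots[[1]])) + 1L,
                    n_events = length(snapshots), sample_every = sample_every,
                    ...)
  structure(list(config = cfg,
                 clocks = as.integer(seq_along(snapshots) - 1L),
                 snapshots = snapshots,
                 event_log = list(immigration = 0L, replication = 0L,
                                  split = 0L, cull = 0L, group_removal = 0L,
                                  rng_seed = cfg$seed)),
            class = "sim_trajectory")
}
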