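# Stochastic update process: immigration, fitness-proportional replication,
# and overflow resolution by culling or group splitting.
#
# All randomness is drawn from R's global RNG stream in a fixed consumption
# order (event kind -> actor -> placement -> overflow), so that a run is
# fully reproducible from a single seed. The compiled engine in
# src/simulate.cpp consumes the stream in the identical order; the two
# engines produce bit-identical trajectories from the same seed.

#' Initialize a population
#'
#' Each of the `m` groups is filled to its carrying capacity `n` with
#' individuals whose types are drawn independently and uniformly from the
#' `d` types of the environmental pool, so the initial total size is
#' `N = m * n` and every type starts at (stochastically) equal abundance.
#' Consumes `m * n` uniform draws from the current RNG state.
#'
#' @param config A [sim_config()].
#' @return A [population_state()] at event clock 0.
#' @export
initialize_population <- function(config) {
  config <- as_sim_config(config)
  counts <- matrix(0L, config$d, config$m)
  for (g in seq_len(config$m)) {
    for (i in seq_len(config$n)) {
      t <- runif_index(config$d)
      counts[t, g] <- counts[t, g] + 1L
    }
  }
  population_state(counts, 0L)
}

# One uniform draw -> index in 1..k (floor inversion; matched in C++).
runif_index <- function(k) {
  u <- stats::runif(1)
  idx <- 1L + as.integer(floor(u * k))
  if (idx > k) idx <- k
  idx
}

#' Split an overflowing group in two
#'
#' Individuals are allocated independently with equal probability to the
#' two offspring groups; if either offspring would have fewer than two
#' individuals the whole allocation is redrawn (rejection sampling), so the
#' accepted allocation is a fair independent assignment conditioned on both
#' offspring sizes being at least 2. A group of size below 4 cannot satisfy
#' the constraint and is an error.
#'
#' @param group Integer vector of length `d`: type counts of the parent
#'   group (size `>= 4`).
#' @return A list with elements `A` and `B`, the two offspring count
#'   vectors; they sum to the parent's counts exactly.
#' @export
split_group <- function(group) {
  group <- as_group_counts(group)
  d <- length(group)
  Nsz <- sum(group)
  if (Nsz < 4L) stop("unsplittable group (size < 4)", call. = FALSE)
  p <- which(group > 0L)
  types <- rep.int(p, group[p])          # individuals in ascending type order
  repeat {
    toA <- stats::runif(Nsz) < 0.5
    nA <- sum(toA)
    if (nA >= 2L && (Nsz - nA) >= 2L) break
  }
  cA <- tabulate(types[toA], nbins = d)
  list(A = as.integer(cA), B = as.integer(group - cA))
}

#' Resolve a group that exceeded its carrying capacity
#'
#' Called on a group of size exactly `n + 1`. With probability `q` the
#' group splits (see [split_group()]); the two offspring replace the parent
#' and one group drawn uniformly from the remaining groups is removed so
#' the group count stays `m`. With probability `1 - q` one individual
#' chosen uniformly at random from the group is removed. Single-group
#' populations never split (there is no other group to remove), so their
#' overflow is always resolved by removal.
#'
#' @param state A [population_state()].
#' @param g Index of the overflowing group.
#' @param config A [sim_config()].
#' @return A list with elements `state` (the resolved
#'   [population_state()]) and `event` (`"split"` or `"cull"`).
#' @export
resolve_overflow <- function(state, g, config) {
  config <- as_sim_config(config)
  if (!inherits(state, "population_state")) stop("not a population_state", call. = FALSE)
  counts <- state$counts
  m <- ncol(counts)
  g <- as.integer(g)
  if (g < 1L || g > m) stop("group index out of range", call. = FALSE)
  if (sum(counts[, g]) <= config$n) stop("no overflow", call. = FALSE)
  res <- .resolve_overflow_impl(counts, g, config)
  list(state = population_state(res$counts, state$event_clock),
       event = res$event)
}

.resolve_overflow_impl <- function(counts, g, config) {
  m <- ncol(counts)
  u <- stats::runif(1)
  do_split <- (m > 1L) && (u < config$q)
  if (do_split) {
    off <- split_group(counts[, g])
    if (config$removal_pool == "exclude-offspring") {
      cand <- setdiff(seq_len(m), g)      # ascending slots, both offspring kept
      slot <- cand[runif_index(m - 1L)]
      counts[, g] <- off$A
      counts[, slot] <- off$B
    } else {
      # candidates: the m - 1 other groups (ascending), then offspring A, B
      k <- runif_index(m + 1L)
      if (k <= m - 1L) {
        cand <- setdiff(seq_len(m), g)
        counts[, g] <- off$A
        counts[, cand[k]] <- off$B
      } else if (k == m) {
        counts[, g] <- off$B               # offspring A removed
      } else {
        counts[, g] <- off$A               # offspring B removed
      }
    }
    list(counts = counts, event = "split")
  } else {
    grp <- counts[, g]
    Nsz <- sum(grp)
    idx <- runif_index(Nsz)                # uniform individual, ascending type order
    cum <- cumsum(grp)
    t <- which(cum >= idx)[1]
    counts[t, g] <- counts[t, g] - 1L
    list(counts = counts, event = "cull")
  }
}

#' Execute one update event
#'
#' With probability `lam` an immigration occurs: a type drawn uniformly
#' from the `d`-type environmental pool is added to a group drawn uniformly
#' from the `m` groups. Otherwise a replication occurs: a parent is drawn
#' via [replication_weights()] (fitness-proportionally across the whole
#' population under the default `parent_selection = "global"`, or within a
#' uniformly drawn group under `"group-uniform"`) and one offspring of the
#' parent's type is added to the parent's group. If the affected group then
#' exceeds the carrying capacity `n`, the overflow is resolved immediately
#' by [resolve_overflow()] — immigration into a full group can therefore
#' trigger a split. The event clock advances by one.
#'
#' @param state A [population_state()].
#' @param A Payoff matrix with `d` matching the configuration.
#' @param config A [sim_config()].
#' @return The next [population_state()], with attribute `"events"`
#'   naming the event kind(s) that occurred (e.g. `c("replication",
#'   "cull")`).
#' @export
sim_step <- function(state, A, config) {
  config <- as_sim_config(config)
  A <- as_payoff_matrix(A)
  if (!inherits(state, "population_state")) stop("not a population_state", call. = FALSE)
  if (nrow(state$counts) != config$d || nrow(A) != config$d) {
    stop("dimension mismatch between state, matrix and config", call. = FALSE)
  }
  res <- .step_impl(state$counts, A, config)
  out <- population_state(res$counts, state$event_clock + 1L)
  attr(out, "events") <- res$events
  out
}

.step_impl <- function(counts, A, config) {
  m <- ncol(counts)
  events <- character(0)
  u1 <- stats::runif(1)
  if (u1 < config$lam) {
    t <- runif_index(config$d)
    g <- runif_index(m)
    counts[t, g] <- counts[t, g] + 1L
    events <- "immigration"
    g_aff <- g
  } else {
    events <- "replication"
    if (config$parent_selection == "global") {
      wdf <- replication_weights(counts, A, config$beta)
      cw <- cumsum(wdf$weight)
      total <- cw[length(cw)]
      u <- stats::runif(1)
      idx <- which(cw >= u * total)[1]
      g_aff <- wdf$group[idx]
      t <- wdf$type[idx]
    } else {
      g_aff <- runif_index(m)
      grp <- counts[, g_aff]
      pis <- group_payoffs(grp, A)
      p <- as.integer(names(pis))
      w <- as.double(grp[p]) * exp(config$beta * pis)
      cw <- cumsum(w)
      total <- cw[length(cw)]
      u <- stats::runif(1)
      t <- p[which(cw >= u * total)[1]]
    }
    counts[t, g_aff] <- counts[t, g_aff] + 1L
  }
  if (sum(counts[, g_aff]) > config$n) {
    res <- .resolve_overflow_impl(counts, g_aff, config)
    counts <- res$counts
    events <- c(events, res$event)
  }
  list(counts = counts, events = events)
}

#' Run a full simulation
#'
#' Seeds the RNG from `config$seed`, initializes the population (each group
#' filled to capacity with uniformly drawn types), executes
#' `config$n_events` update events and records a snapshot of the group
#' compositions every `config$sample_every` events (plus the initial and
#' final states). Identical `(config, A)`, including the seed, give a
#' bit-identical trajectory; the compiled engine (`engine = "cpp"`, the
#' default) and the pure-R reference engine (`engine = "r"`) consume the
#' RNG stream identically and agree exactly.
#'
#' @param config A [sim_config()].
#' @param A Payoff matrix with `nrow(A) == config$d`.
#' @param engine `"cpp"` (compiled, fast) or `"r"` (reference).
#' @return A `sim_trajectory`: a list with elements `config`, `clocks`
#'   (integer vector of snapshot event clocks), `snapshots` (list of
#'   `d x m` count matrices) and `event_log` (see Details). The event log
#'   counts events by kind (`immigration`, `replication`, `split`, `cull`,
#'   `group_removal`) and records the seed; `immigration + replication`
#'   equals the number of events executed and `group_removal` equals
#'   `split`.
#' @examples
#' cfg <- sim_config(d = 20, m = 3, n = 10, q = 0.01, seed = 1,
#'                   n_events = 2000, sample_every = 200)
#' A <- generate_matrix(20, seed = 2)
#' traj <- run_simulation(cfg, A)
#' total_richness(last_snapshot(traj))
#' @export
run_simulation <- function(config, A, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  config <- as_sim_config(config)
  A <- as_payoff_matrix(A)
  if (nrow(A) != config$d) {
    stop("dimension mismatch: config d = ", config$d,
         " but the payoff matrix has d = ", nrow(A), call. = FALSE)
  }
  set.seed(config$seed)
  state0 <- initialize_population(config)
  if (engine == "cpp") {
    res <- sim_run_cpp(state0$counts, unclass(A), config$beta, config$lam,
                       config$q, config$n, config$n_events,
                       config$sample_every,
                       config$parent_selection == "global",
                       config$removal_pool == "exclude-offspring")
    clocks <- res$clocks
    snapshots <- res$snapshots
    counters <- res$counters
  } else {
    counts <- state0$counts
    clocks <- 0L
    snapshots <- list(counts)
    counters <- c(immigration = 0L, replication = 0L, split = 0L, cull = 0L)
    for (ev in seq_len(config$n_events)) {
      res <- .step_impl(counts, A, config)
      counts <- res$counts
      for (e in res$events) counters[[e]] <- counters[[e]] + 1L
      if (ev %% config$sample_every == 0L) {
        clocks <- c(clocks, ev)
        snapshots <- c(snapshots, list(counts))
      }
    }
    if (clocks[length(clocks)] != config$n_events) {
      clocks <- c(clocks, config$n_events)
      snapshots <- c(snapshots, list(counts))
    }
  }
  event_log <- list(immigration = counters[[1]], replication = counters[[2]],
                    split = counters[[3]], cull = counters[[4]],
                    group_removal = counters[[3]], rng_seed = config$seed)
  structure(list(config = config, clocks = as.integer(clocks),
                 snapshots = snapshots, event_log = event_log),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("Simulation trajectory: %d snapshots over %d events (d = %d, m = %d, n = %d)\n",
              length(x$clocks), x$config$n_events, x$config$d, x$config$m,
              x$config$n))
  el <- x$event_log
  cat(sprintf("  events: %d immigration, %d replication, %d split, %d cull\n",
              el$immigration, el$replication, el$split, el$cull))
  invisible(x)
}

#' Extract a snapshot from a trajectory
#'
#' @param traj A `sim_trajectory` from [run_simulation()].
#' @param i Snapshot index (default: the last snapshot).
#' @return The `d x m` integer count matrix of that snapshot.
#' @export
last_snapshot <- function(traj, i = length(traj$snapshots)) {
  stopifnot(inherits(traj, "sim_trajectory"))
  traj$snapshots[[i]]
}

#' Tidy view of a trajectory
#'
#' @param x A `sim_trajectory`.
#' @param row.names,optional Unused, for S3 compatibility.
#' @param ... Unused.
#' @return A data frame with one row per (snapshot, group, type) with a
#'   nonzero count: columns `event_clock`, `group`, `type`, `count`
#'   (1-based indices; files written by [write_trajectory()] use 0-based
#'   indices).
#' @export
as.data.frame.sim_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  parts <- lapply(seq_along(x$clocks), function(i) {
    s <- x$snapshots[[i]]
    nz <- which(s > 0L, arr.ind = TRUE)
    data.frame(event_clock = x$clocks[i], group = as.integer(nz[, 2]),
               type = as.integer(nz[, 1]), count = s[nz])
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$event_clock, out$group, out$type), ]
  rownames(out) <- NULL
  out
}
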