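#' Simulation configuration
#'
#' Bundles every model and runtime parameter of the group-structured
#' simulation.
#'
#' @param d Number of types in the environmental pool (positive integer).
#' @param m Number of groups, kept constant throughout a run.
#' @param n Group carrying capacity. `n >= 2` is required; `n >= 4` is
#'   recommended so that overflowing groups (size `n + 1 >= 5`) can always
#'   split into two groups of size `>= 2`.
#' @param beta Selection intensity (`>= 0`). `beta = 0` is the neutral
#'   limit where all individuals are equally fit.
#' @param lam Immigration probability in `[0, 1]`: at each event, with
#'   probability `lam` an individual of a uniformly drawn type immigrates
#'   into a uniformly drawn group instead of a replication taking place.
#' @param q Group-splitting probability in `[0, 1]`: when a group exceeds
#'   its carrying capacity it splits with probability `q` (another group is
#'   then removed to keep `m` constant) and otherwise loses one uniformly
#'   chosen individual. Single-group populations (`m = 1`) never split.
#' @param seed Integer seed; all randomness in a run derives from it.
#' @param n_events Total number of update events to execute.
#' @param sample_every Record a snapshot every this many events (the
#'   initial and final states are always recorded).
#' @param burn_in Events discarded before long-run statistics (used as the
#'   default by [realized_interaction_frequencies()] and
#'   [metrics_report()]).
#' @param last_k_snapshots Window, in snapshots, for long-run time-averaged
#'   abundances (default 15).
#' @param parent_selection `"global"` (default): the replicating parent is
#'   drawn fitness-proportionally across all individuals in all groups, so
#'   that groups with fitter individuals grow (and hence split) faster;
#'   restricted to a single group this reduces exactly to the within-group
#'   replication probability `b_j = n_j f_j / sum_k n_k f_k`.
#'   `"group-uniform"`: a group is first drawn uniformly, then the parent
#'   within it by `b_j`.
#' @param removal_pool After a split, the group removed to keep `m`
#'   constant is drawn uniformly from the `m - 1` groups other than the two
#'   offspring (`"exclude-offspring"`, default) or from all `m + 1` groups
#'   including them (`"all"`).
#' @return A list of class `sim_config`.
#' @seealso [run_simulation()]
#' @export
sim_config <- function(d, m, n, beta = 1.0, lam = 0.1, q = 0.001,
                       seed = 1L, n_events = 100000L, sample_every = 1000L,
                       burn_in = 0L, last_k_snapshots = 15L,
                       parent_selection = c("global", "group-uniform"),
                       removal_pool = c("exclude-offspring", "all")) {
  parent_selection <- match.arg(parent_selection)
  removal_pool <- match.arg(removal_pool)
  d <- as.integer(d); m <- as.integer(m); n <- as.integer(n)
  n_events <- as.integer(n_events); sample_every <- as.integer(sample_every)
  burn_in <- as.integer(burn_in)
  last_k_snapshots <- as.integer(last_k_snapshots)
  seed <- as.integer(seed)
  if (is.na(d) || d < 1L) stop("d must be a positive integer", call. = FALSE)
  if (is.na(m) || m < 1L) stop("m must be a positive integer", call. = FALSE)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (!is.finite(lam) || lam < 0 || lam > 1) stop("lam must be in [0, 1]", call. = FALSE)
  if (!is.finite(q) || q < 0 || q > 1) stop("q must be in [0, 1]", call. = FALSE)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  if (is.na(n_events) || n_events < 1L) stop("n_events must be a positive integer", call. = FALSE)
  if (is.na(sample_every) || sample_every < 1L) stop("sample_every must be a positive integer", call. = FALSE)
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  if (is.na(last_k_snapshots) || last_k_snapshots < 1L) {
    stop("last_k_snapshots must be a positive integer", call. = FALSE)
  }
  structure(list(d = d, m = m, n = n, beta = beta, lam = lam, q = q,
                 seed = seed, n_events = n_events,
                 sample_every = sample_every, burn_in = burn_in,
                 last_k_snapshots = last_k_snapshots,
                 parent_selection = parent_selection,
                 removal_pool = removal_pool),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  types d = %d, groups m = %d, carrying capacity n = %d (max N = %d)\n",
              x$d, x$m, x$n, x$m * x$n))
  cat(sprintf("  beta = %g, lambda = %g, q = %g, seed = %d\n",
              x$beta, x$lam, x$q, x$seed))
  cat(sprintf("  %d events, snapshot every %d, burn-in %d, last-%d-snapshot window\n",
              x$n_events, x$sample_every, x$burn_in, x$last_k_snapshots))
  cat(sprintf("  parent selection: %s; removal pool: %s\n",
              x$parent_selection, x$removal_pool))
  invisible(x)
}

as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  if (is.list(x)) return(do.call(sim_config, x))
  stop("not a sim_config", call. = FALSE)
}
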