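# Summary statistics on snapshots and trajectories: diversity indices,
# group similarity, realized interaction frequencies among co-occurring
# individuals, abundance rankings and leader turnover.

# Accept either a d x m count matrix or a population_state.
as_snapshot <- function(x) {
  if (inherits(x, "population_state")) return(x$counts)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (any(is.na(x)) || any(x < 0L)) {
    stop("snapshot counts must be nonnegative integers", call. = FALSE)
  }
  x
}

#' Total richness of a snapshot
#'
#' Number of distinct types with population-wide count at least 1.
#'
#' @param snapshot A `d x m` count matrix (or [population_state()]).
#' @return An integer, at most `min(d, N)`.
#' @export
total_richness <- function(snapshot) {
  x <- as_snapshot(snapshot)
  sum(rowSums(x) > 0L)
}

#' Per-group richness
#'
#' @inheritParams total_richness
#' @return A list with `per_group` (distinct-type count of each group) and
#'   `mean` (their mean over the `m` groups).
#' @export
group_richness <- function(snapshot) {
  x <- as_snapshot(snapshot)
  r <- colSums(x > 0L)
  list(per_group = as.integer(r), mean = mean(r))
}

#' Shannon diversity index of a snapshot
#'
#' `H = -sum_i p_i log(p_i)` over population-wide relative abundances,
#' using the natural logarithm (the ecological convention). `H` ranges
#' from 0 (a single type) to `log(richness)` (all present types equally
#' abundant).
#'
#' @inheritParams total_richness
#' @return A nonnegative number.
#' @export
shannon_index <- function(snapshot) {
  x <- as_snapshot(snapshot)
  tot <- rowSums(x)
  N <- sum(tot)
  if (N < 1L) stop("empty population", call. = FALSE)
  p <- tot[tot > 0L] / N
  -sum(p * log(p))
}

#' Similarity of group compositions
#'
#' Mean pairwise similarity over all unordered group pairs. The default is
#' the Jaccard index on presence sets, `|S_g & S_h| / |S_g | S_h|`,
#' matching a richness-based notion of similarity; `method = "bray"` gives
#' the abundance-weighted Bray-Curtis similarity
#' `1 - sum|x - y| / sum(x + y)` instead.
#'
#' @inheritParams total_richness
#' @param method `"jaccard"` (presence-based, default) or `"bray"`.
#' @return A number in `[0, 1]`.
#' @export
group_similarity <- function(snapshot, method = c("jaccard", "bray")) {
  method <- match.arg(method)
  x <- as_snapshot(snapshot)
  m <- ncol(x)
  if (m < 2L) stop("similarity undefined for one group", call. = FALSE)
  sims <- numeric(0)
  for (g in seq_len(m - 1L)) {
    for (h in seq((g + 1L), m)) {
      if (method == "jaccard") {
        a <- x[, g] > 0L; b <- x[, h] > 0L
        un <- sum(a | b)
        sims <- c(sims, if (un == 0L) 1 else sum(a & b) / un)
      } else {
        tot <- sum(x[, g]) + sum(x[, h])
        sims <- c(sims, if (tot == 0L) 1 else
          1 - sum(abs(x[, g] - x[, h])) / tot)
      }
    }
  }
  mean(sims)
}

#' Fraction of homogeneous groups
#'
#' A group is homogeneous when all its individuals are of a single type
#' (group richness 1).
#'
#' @inheritParams total_richness
#' @return A number in `[0, 1]`.
#' @export
homogeneous_fraction <- function(snapshot) {
  x <- as_snapshot(snapshot)
  mean(colSums(x > 0L) == 1L)
}

#' Realized interaction frequencies among co-occurring individuals
#'
#' Interactions are only realized between individuals that share a group at
#' the same time. For each snapshot and group, every unordered heterotypic
#' pair `{i, j}` present contributes its number of interacting individual
#' pairs, `n_ig * n_jg`, to its stability class (`weighting = "pairs"`,
#' the default) or a single co-occurrence count (`weighting =
#' "presence"`). Weights are summed over groups and snapshots and
#' normalized over the three non-degenerate classes, pooling both
#' dominance orientations.
#'
#' @param traj A `sim_trajectory` (or a plain list of `d x m` count
#'   matrices).
#' @param table Interaction table from [classify_all()] for the same
#'   payoff matrix.
#' @param weighting `"pairs"` (individual-pair counting) or `"presence"`.
#' @param burn_in Discard snapshots with event clock at or below this value
#'   (defaults to the trajectory's configured `burn_in`, or 0 for a plain
#'   snapshot list).
#' @return Named fractions `dominance`, `bistability`, `coexistence`
#'   summing to 1, with the total weight on degenerate pairs attached as
#'   attribute `"degenerate_weight"`.
#' @export
realized_interaction_frequencies <- function(traj, table,
                                             weighting = c("pairs", "presence"),
                                             burn_in = NULL) {
  weighting <- match.arg(weighting)
  table <- as_interaction_table(table)
  if (inherits(traj, "sim_trajectory")) {
    if (is.null(burn_in)) burn_in <- traj$config$burn_in
    snaps <- traj$snapshots[traj$clocks >= burn_in]
  } else {
    snaps <- traj
  }
  if (length(snaps) == 0L) stop("no snapshots", call. = FALSE)
  d <- attr(table, "d")
  cm <- interaction_class_matrix(table)
  acc <- c(dominance = 0, bistability = 0, coexistence = 0, degenerate = 0)
  for (s in snaps) {
    x <- as_snapshot(s)
    if (nrow(x) != d) stop("snapshot and table disagree on d", call. = FALSE)
    for (g in seq_len(ncol(x))) {
      p <- which(x[, g] > 0L)
      if (length(p) < 2L) next
      np <- as.double(x[p, g])
      W <- if (weighting == "pairs") np %o% np else matrix(1, length(p), length(p))
      codes <- cm[p, p, drop = FALSE]
      up <- upper.tri(W)
      for (k in 1:4) acc[k] <- acc[k] + sum(W[up][codes[up] == k])
    }
  }
  tot <- sum(acc[1:3])
  if (tot == 0) stop("no interactions observed (all groups homogeneous)",
                     call. = FALSE)
  out <- acc[1:3] / tot
  attr(out, "degenerate_weight") <- unname(acc[4])
  out
}

#' Long-run abundance ranking and self-payoff correlation
#'
#' Each type's relative abundance is averaged over the last `last_k`
#' snapshots of the trajectory and reported ranked by abundance and by
#' self-payoff `a_ii`, together with the Spearman rank correlation between
#' the two quantities across the types present in the window.
#'
#' @param traj A `sim_trajectory`.
#' @param A The payoff matrix used for the run.
#' @param last_k Number of trailing snapshots to average over (default:
#'   the trajectory's configured `last_k_snapshots`, typically 15).
#' @return A list with `abundance` (mean relative abundance per type),
#'   `by_abundance` and `by_self_payoff` (data frames of the types present,
#'   sorted by descending abundance resp. self-payoff) and `spearman`.
#' @export
abundance_ranking <- function(traj, A, last_k = NULL) {
  stopifnot(inherits(traj, "sim_trajectory"))
  A <- as_payoff_matrix(A)
  if (is.null(last_k)) last_k <- traj$config$last_k_snapshots
  ns <- length(traj$snapshots)
  if (ns < last_k) {
    stop("trajectory has ", ns, " snapshots, fewer than last_k = ", last_k,
         call. = FALSE)
  }
  d <- nrow(A)
  idx <- seq(ns - last_k + 1L, ns)
  p_mat <- vapply(idx, function(i) {
    tot <- rowSums(traj$snapshots[[i]])
    tot / sum(tot)
  }, numeric(d))
  abund <- rowMeans(p_mat)
  present <- which(abund > 0)
  df <- data.frame(type = present, abundance = abund[present],
                   self_payoff = diag(A)[present])
  by_ab <- df[order(-df$abundance, df$type), ]
  by_sp <- df[order(-df$self_payoff, df$type), ]
  rownames(by_ab) <- rownames(by_sp) <- NULL
  rho <- if (nrow(df) >= 3L) {
    stats::cor(df$abundance, df$self_payoff, method = "spearman")
  } else NA_real_
  list(abundance = abund, by_abundance = by_ab, by_self_payoff = by_sp,
       spearman = rho)
}

#' Turnover of the most abundant type
#'
#' Identifies the population-wide most abundant type at each snapshot
#' (ties broken deterministically by lowest type index) and summarizes the
#' lengths of maximal runs during which the leader is unchanged.
#'
#' @param traj A `sim_trajectory` (needs at least 2 snapshots).
#' @return A list with `leaders` (per-snapshot leading type),
#'   `run_lengths` and `mean_duration` (mean run length, in snapshots).
#' @export
turnover_stats <- function(traj) {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (length(traj$snapshots) < 2L) stop("need at least 2 snapshots", call. = FALSE)
  leaders <- vapply(traj$snapshots, function(s) which.max(rowSums(s)),
                    integer(1))
  r <- rle(leaders)
  list(leaders = leaders, run_lengths = r$lengths,
       mean_duration = mean(r$lengths))
}

#' Per-snapshot metric table of a trajectory
#'
#' @param traj A `sim_trajectory`.
#' @return A data frame with one row per snapshot: `event_clock`,
#'   `total_richness`, `mean_group_richness`, `shannon_index`,
#'   `group_similarity` (`NA` for single-group populations),
#'   `homogeneous_fraction`.
#' @export
trajectory_metrics <- function(traj) {
  stopifnot(inherits(traj, "sim_trajectory"))
  m <- ncol(traj$snapshots[[1]])
  rows <- lapply(seq_along(traj$clocks), function(i) {
    s <- traj$snapshots[[i]]
    data.frame(event_clock = traj$clocks[i],
               total_richness = total_richness(s),
               mean_group_richness = group_richness(s)$mean,
               shannon_index = shannon_index(s),
               group_similarity = if (m >= 2L) group_similarity(s) else NA_real_,
               homogeneous_fraction = homogeneous_fraction(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full metrics report for a trajectory
#'
#' Combines the per-snapshot diversity metrics, their long-run averages
#' (over snapshots past the burn-in), the realized interaction frequencies
#' (when an interaction table is supplied) and the abundance ranking and
#' leader-turnover summaries (when the payoff matrix is supplied).
#'
#' @param traj A `sim_trajectory`.
#' @param A Optional payoff matrix (enables abundance ranking).
#' @param table Optional interaction table (enables realized interaction
#'   frequencies).
#' @param burn_in Event-clock cutoff for long-run averages (defaults to
#'   the trajectory's configured value).
#' @param last_k Abundance-averaging window (defaults to the configured
#'   `last_k_snapshots`).
#' @return A list of class `metrics_report` with elements `per_snapshot`,
#'   `long_run` (named means), and optionally `realized_frequencies`,
#'   `ranking`, `turnover`.
#' @export
metrics_report <- function(traj, A = NULL, table = NULL, burn_in = NULL,
                           last_k = NULL) {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (is.null(burn_in)) burn_in <- traj$config$burn_in
  per <- trajectory_metrics(traj)
  keep <- per$event_clock >= burn_in
  if (!any(keep)) keep <- rep(TRUE, nrow(per))
  long_run <- colMeans(per[keep, -1, drop = FALSE], na.rm = TRUE)
  out <- list(per_snapshot = per, long_run = long_run, burn_in = burn_in)
  if (!is.null(table)) {
    out$realized_frequencies <-
      realized_interaction_frequencies(traj, table, burn_in = burn_in)
  }
  if (!is.null(A)) {
    out$ranking <- abundance_ranking(traj, A, last_k = last_k)
    out$turnover <- turnover_stats(traj)
  }
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report (long-run averages, event clock >=", x$burn_in, ")\n")
  print(round(x$long_run, 4))
  if (!is.null(x$realized_frequencies)) {
    cat("Realized interaction frequencies:\n")
    print(round(x$realized_frequencies, 4))
  }
  if (!is.null(x$ranking)) {
    cat(sprintf("Spearman(abundance, self-payoff) = %.3f\n",
                x$ranking$spearman))
  }
  if (!is.null(x$turnover)) {
    cat(sprintf("Mean duration as most abundant type: %.2f snapshots\n",
                x$turnover$mean_duration))
  }
  invisible(x)
}
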