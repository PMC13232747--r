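#' Population state
#'
#' The composition of the `m` groups at one instant, stored as a `d x m`
#' integer matrix of type counts (rows are types, columns are groups),
#' together with the number of update events executed so far.
#'
#' @param counts A `d x m` integer matrix of nonnegative type counts.
#' @param event_clock Nonnegative integer event counter.
#' @return A list of class `population_state` with elements `counts` and
#'   `event_clock`.
#' @export
population_state <- function(counts, event_clock = 0L) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  event_clock <- as.integer(event_clock)
  if (is.na(event_clock) || event_clock < 0L) {
    stop("event_clock must be a nonnegative integer", call. = FALSE)
  }
  structure(list(counts = counts, event_clock = event_clock),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  sizes <- colSums(x$counts)
  cat(sprintf("Population state at event %d: %d groups, %d individuals, richness %d\n",
              x$event_clock, ncol(x$counts), sum(sizes),
              sum(rowSums(x$counts) > 0L)))
  cat("  group sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

# Group counts as a dense integer vector of length d.
as_group_counts <- function(group, d = NULL) {
  group <- as.integer(group)
  if (any(is.na(group)) || any(group < 0L)) {
    stop("group counts must be nonnegative integers", call. = FALSE)
  }
  if (!is.null(d) && length(group) != d) {
    stop("group count vector has length ", length(group),
         " but the payoff matrix has d = ", d, " types", call. = FALSE)
  }
  group
}

#' Payoff of one type in a group
#'
#' The payoff of a focal type-`j` individual in a group is its average
#' payoff over the `N_g - 1` other group members (an individual does not
#' play against itself):
#' `pi_j = (n_j - 1)/(N_g - 1) a_jj + sum_{k != j} n_k/(N_g - 1) a_jk`.
#' In a singleton group there are no interaction partners and the payoff
#' is defined as 0 (neutral fitness 1); singleton groups never arise in the
#' documented dynamics, whose minimum group size is 2.
#'
#' @param group Integer vector of length `d`: type counts in the group.
#' @param type Focal type index (must be present in the group).
#' @param A Payoff matrix.
#' @return The payoff, a single finite number.
#' @examples
#' A <- matrix(c(1, 0, 0, 0), 2, 2)  # a_11 = 1, all else 0
#' type_payoff(c(3, 2), 1, A)        # (2/4)*1 + (2/4)*0 = 0.5
#' @export
type_payoff <- function(group, type, A) {
  A <- as_payoff_matrix(A)
  d <- nrow(A)
  group <- as_group_counts(group, d)
  j <- as.integer(type)
  if (is.na(j) || j < 1L || j > d) stop("type index out of range", call. = FALSE)
  if (group[j] < 1L) stop("type not present in the group", call. = FALSE)
  Ng <- sum(group)
  if (Ng < 2L) return(0)
  p <- which(group > 0L)
  s <- sum(A[j, p] * as.double(group[p]))
  (s - A[j, j]) / (Ng - 1)
}

#' Payoffs of all types present in a group
#'
#' @inheritParams type_payoff
#' @return A named numeric vector of payoffs, one per present type,
#'   in ascending type order.
#' @export
group_payoffs <- function(group, A) {
  A <- as_payoff_matrix(A)
  group <- as_group_counts(group, nrow(A))
  p <- which(group > 0L)
  Ng <- sum(group)
  pis <- vapply(p, function(j) {
    if (Ng < 2L) return(0)
    s <- sum(A[j, p] * as.double(group[p]))
    (s - A[j, j]) / (Ng - 1)
  }, numeric(1))
  names(pis) <- p
  pis
}

#' Exponential payoff-to-fitness mapping
#'
#' `f = exp(beta * pi)`. The exponential mapping keeps fitness strictly
#' positive even for negative payoffs and accommodates both weak
#' (`beta << 1`) and strong selection; `beta = 0` is the neutral limit
#' where every individual has fitness 1.
#'
#' @param pi Payoff value(s); must be finite.
#' @param beta Selection intensity, `>= 0`.
#' @return Fitness value(s), strictly positive.
#' @export
fitness <- function(pi, beta) {
  if (!all(is.finite(pi))) stop("payoff must be finite", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  exp(beta * pi)
}

#' Replication weights of every (group, type) pair
#'
#' For each type `j` present in group `g`, the weight
#' `w_{g,j} = n_{jg} * f_j(g)` with `f_j = exp(beta * pi_j)`. Drawing the
#' parent proportionally to `w` over all groups jointly realizes
#' fitness-proportional selection across the whole population; restricting
#' to a single group and renormalizing recovers the within-group
#' replication probability `b_j = n_j f_j / sum_k n_k f_k` exactly.
#'
#' @param state A [population_state()] (or a bare `d x m` counts matrix).
#' @param A Payoff matrix.
#' @param beta Selection intensity.
#' @return A data frame with columns `group`, `type`, `weight`, rows
#'   ordered by group then ascending type, one row per present
#'   (group, type) pair.
#' @export
replication_weights <- function(state, A, beta) {
  A <- as_payoff_matrix(A)
  counts <- if (inherits(state, "population_state")) state$counts else {
    x <- as.matrix(state); storage.mode(x) <- "integer"; x
  }
  if (nrow(counts) != nrow(A)) {
    stop("state and payoff matrix disagree on d", call. = FALSE)
  }
  m <- ncol(counts)
  out_g <- integer(0); out_t <- integer(0); out_w <- numeric(0)
  for (g in seq_len(m)) {
    grp <- counts[, g]
    if (sum(grp) < 1L) stop("empty group (invariant violation)", call. = FALSE)
    pis <- group_payoffs(grp, A)
    p <- as.integer(names(pis))
    w <- as.double(grp[p]) * exp(beta * pis)
    out_g <- c(out_g, rep.int(g, length(p)))
    out_t <- c(out_t, p)
    out_w <- c(out_w, w)
  }
  data.frame(group = out_g, type = out_t, weight = unname(out_w))
}
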