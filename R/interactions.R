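# Classification of pairwise interactions by their dynamical outcome.
#
# For an unordered pair {i, j} the relevant object is the 2x2 subgame
# (a_ii, a_ij; a_ji, a_jj). Under two-type replicator dynamics the outcome
# is fully determined by two invasion conditions: a rare i invades a
# j-resident population iff a_ij > a_jj, and a rare j invades an i-resident
# population iff a_ji > a_ii.
#   - i dominates j:   i invades, j does not (a_ii > a_ji and a_ij > a_jj)
#   - j dominates i:   j invades, i does not
#   - bistability:     neither invades (a_ii > a_ji and a_jj > a_ij)
#   - coexistence:     both invade (stable interior equilibrium at
#                      x* = (a_ij - a_jj) / (a_ij - a_jj + a_ji - a_ii))
# Any exact tie among the compared entries is classified "degenerate" and
# excluded from frequency denominators: ties have measure zero under the
# Gaussian generator, but silently assigning them a class would corrupt
# baselines computed on hand-crafted integer matrices.

.int_classes <- c("first_dominates", "second_dominates", "bistability",
                  "coexistence", "degenerate")

#' Classify one pair of types by its dynamical outcome
#'
#' @param A Payoff matrix.
#' @param i,j Distinct type indices.
#' @return A single string: `"first_dominates"` (type `i` dominates `j`),
#'   `"second_dominates"`, `"bistability"`, `"coexistence"` or
#'   `"degenerate"` (an exact tie among the compared entries).
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2, 2)
#' classify_pair(A, 1, 2)  # coordination game: bistability
#' @export
classify_pair <- function(A, i, j) {
  A <- as_payoff_matrix(A)
  d <- nrow(A)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > d || j > d) {
    stop("type index out of range", call. = FALSE)
  }
  if (i == j) stop("self-pair: i and j must differ", call. = FALSE)
  aii <- A[i, i]; ajj <- A[j, j]; aij <- A[i, j]; aji <- A[j, i]
  if (aij == ajj || aji == aii) return("degenerate")
  i_invades <- aij > ajj
  j_invades <- aji > aii
  if (i_invades && !j_invades) "first_dominates"
  else if (!i_invades && j_invades) "second_dominates"
  else if (!i_invades && !j_invades) "bistability"
  else "coexistence"
}

#' Classify all unordered type pairs
#'
#' Applies the invasion-condition classification to every unordered pair
#' `{i, j}`, `i < j`, of the payoff matrix.
#'
#' @param A Payoff matrix.
#' @return An `interaction_table`: a data frame with `d(d-1)/2` rows and
#'   columns `i`, `j` (type indices, `i < j`), `class` (`"dominance"`,
#'   `"bistability"`, `"coexistence"` or `"degenerate"`) and `winner` (the
#'   dominating type for dominance pairs, `NA` otherwise). The number of
#'   types is attached as attribute `"d"`.
#' @export
classify_all <- function(A) {
  A <- as_payoff_matrix(A)
  d <- nrow(A)
  ut <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  aii <- diag(A)[i]; ajj <- diag(A)[j]
  aij <- A[cbind(i, j)]; aji <- A[cbind(j, i)]
  degen <- (aij == ajj) | (aji == aii)
  i_inv <- aij > ajj
  j_inv <- aji > aii
  cls <- ifelse(degen, "degenerate",
         ifelse(i_inv & !j_inv, "dominance",
         ifelse(!i_inv & j_inv, "dominance",
         ifelse(!i_inv & !j_inv, "bistability", "coexistence"))))
  winner <- rep(NA_integer_, length(i))
  winner[!degen & i_inv & !j_inv] <- i[!degen & i_inv & !j_inv]
  winner[!degen & !i_inv & j_inv] <- j[!degen & !i_inv & j_inv]
  out <- data.frame(i = as.integer(i), j = as.integer(j), class = cls,
                    winner = winner)
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  attr(out, "d") <- d
  class(out) <- c("interaction_table", "data.frame")
  out
}

as_interaction_table <- function(x) {
  if (!inherits(x, "interaction_table")) {
    stop("not an interaction_table (see classify_all())", call. = FALSE)
  }
  x
}

#' Class fractions of an interaction table
#'
#' The fraction of unordered type pairs in each stability class, with the
#' two dominance orientations pooled. For a payoff matrix with i.i.d.
#' continuous entries the two invasion conditions are independent fair
#' coins, so the expected fractions are 1/2 dominance, 1/4 bistability and
#' 1/4 coexistence. Degenerate (tied) pairs are excluded from the
#' denominator and reported via the `"degenerate"` attribute.
#'
#' @param table An interaction table from [classify_all()].
#' @return A named numeric vector with entries `dominance`, `bistability`
#'   and `coexistence`, summing to 1 over the non-degenerate pairs; the
#'   number of degenerate pairs is attached as attribute `"degenerate"`.
#' @export
baseline_frequencies <- function(table) {
  table <- as_interaction_table(table)
  n_deg <- sum(table$class == "degenerate")
  keep <- table$class != "degenerate"
  n_ok <- sum(keep)
  if (n_ok == 0L) stop("all pairs are degenerate", call. = FALSE)
  out <- c(dominance = sum(table$class == "dominance") / n_ok,
           bistability = sum(table$class == "bistability") / n_ok,
           coexistence = sum(table$class == "coexistence") / n_ok)
  attr(out, "degenerate") <- n_deg
  out
}

#' Per-type interaction profile ranked by self-payoff
#'
#' For each type, counts how many of its `d - 1` pairs fall in each class,
#' splitting dominance by orientation. Types with higher self-payoff
#' `a_ii` tend to dominate more and to be in more bistable pairs (both
#' require `a_ii > a_ji`), while types with lower self-payoff are more
#' often dominated or in coexistence.
#'
#' @param A Payoff matrix.
#' @param table Interaction table from [classify_all()] on the same matrix.
#' @return A data frame ordered by descending self-payoff with columns
#'   `type`, `self_payoff`, `dominates`, `dominated`, `bistable`,
#'   `coexists`, `degenerate`. The counts in each row sum to `d - 1`.
#' @export
ranked_profile <- function(A, table) {
  A <- as_payoff_matrix(A)
  table <- as_interaction_table(table)
  d <- nrow(A)
  if (attr(table, "d") != d) stop("table and matrix disagree on d", call. = FALSE)
  dominates <- dominated <- bistable <- coexists <- degenerate <- integer(d)
  dom <- table$class == "dominance"
  losers <- ifelse(table$winner == table$i, table$j, table$i)
  add_count <- function(v, idx) {
    tb <- tabulate(idx, nbins = d)
    v + tb
  }
  dominates <- add_count(dominates, table$winner[dom])
  dominated <- add_count(dominated, losers[dom])
  bis <- table$class == "bistability"
  bistable <- add_count(add_count(bistable, table$i[bis]), table$j[bis])
  cox <- table$class == "coexistence"
  coexists <- add_count(add_count(coexists, table$i[cox]), table$j[cox])
  deg <- table$class == "degenerate"
  degenerate <- add_count(add_count(degenerate, table$i[deg]), table$j[deg])
  out <- data.frame(type = seq_len(d), self_payoff = diag(A),
                    dominates = dominates, dominated = dominated,
                    bistable = bistable, coexists = coexists,
                    degenerate = degenerate)
  out <- out[order(-out$self_payoff), ]
  rownames(out) <- NULL
  out
}

# d x d symmetric class-code matrix (0 none, 1 dominance, 2 bistability,
# 3 coexistence, 4 degenerate) for fast lookups in metrics.
interaction_class_matrix <- function(table) {
  table <- as_interaction_table(table)
  d <- attr(table, "d")
  code <- match(table$class,
                c("dominance", "bistability", "coexistence", "degenerate"))
  cm <- matrix(0L, d, d)
  cm[cbind(table$i, table$j)] <- code
  cm[cbind(table$j, table$i)] <- code
  cm
}
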