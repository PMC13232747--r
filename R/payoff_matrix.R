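#' Construct a payoff matrix
#'
#' A payoff matrix `A = (a_ij)` is the sole determinant of all interactions
#' in the model: `a_ij` is the payoff a type-`i` individual receives from an
#' interaction with a type-`j` individual. The diagonal `a_ii` is the
#' self-payoff, the payoff received from interacting with an individual of
#' the same type.
#'
#' @param entries A square numeric matrix (`d >= 2`) of finite values.
#' @param gen_meta Optional list recording how the matrix was generated,
#'   with elements `mu`, `sigma2` and `seed` (see [generate_matrix()]).
#' @return A numeric matrix of class `payoff_matrix`.
#' @seealso [generate_matrix()], [classify_all()]
#' @export
payoff_matrix <- function(entries, gen_meta = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) {
    stop("non-square matrix: ", nrow(entries), " rows, ",
         ncol(entries), " columns", call. = FALSE)
  }
  if (!is.numeric(entries)) stop("payoff entries must be numeric", call. = FALSE)
  storage.mode(entries) <- "double"
  if (nrow(entries) < 2L) stop("a payoff matrix needs d >= 2 types", call. = FALSE)
  if (!all(is.finite(entries))) stop("payoff entries must be finite", call. = FALSE)
  dimnames(entries) <- NULL
  structure(entries, class = c("payoff_matrix", "matrix", "array"),
            gen_meta = gen_meta)
}

#' @export
print.payoff_matrix <- function(x, ...) {
  d <- nrow(x)
  meta <- attr(x, "gen_meta")
  cat(sprintf("Payoff matrix with d = %d types\n", d))
  if (!is.null(meta)) {
    cat(sprintf("  generated: Normal(mu = %g, sigma2 = %g), seed = %s\n",
                meta$mu, meta$sigma2, format(meta$seed)))
  }
  k <- min(d, 6L)
  print(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], digits = 3)
  if (d > k) cat(sprintf("  ... (%d x %d entries total)\n", d, d))
  invisible(x)
}

# Coerce + validate; accepts a plain matrix anywhere a payoff matrix is needed.
as_payoff_matrix <- function(A) {
  if (inherits(A, "payoff_matrix")) return(A)
  payoff_matrix(A)
}

#' Generate a random Gaussian payoff matrix
#'
#' Samples the `d x d` entries i.i.d. from a Normal distribution with mean
#' `mu` and variance `sigma2` (the defaults, standard normal entries, give
#' a wide range of interaction structures: on average 50% of type pairs are
#' dominance, 25% bistability and 25% coexistence; see
#' [baseline_frequencies()]).
#'
#' @param d Number of types (`>= 2`).
#' @param mu Mean of the entry distribution.
#' @param sigma2 Variance of the entry distribution (`> 0`).
#' @param seed Optional integer seed; when given the generation is
#'   deterministic and recorded in the matrix metadata.
#' @return A [payoff_matrix()] with `gen_meta` attached.
#' @examples
#' A <- generate_matrix(6, seed = 1)
#' classify_all(A)
#' @export
generate_matrix <- function(d, mu = 0, sigma2 = 1, seed = NULL) {
  d <- as.integer(d)
  if (is.na(d) || d < 2L) stop("d must be an integer >= 2", call. = FALSE)
  if (!is.finite(mu)) stop("mu must be finite", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  A <- matrix(stats::rnorm(d * d, mean = mu, sd = sqrt(sigma2)), d, d)
  payoff_matrix(A, gen_meta = list(mu = mu, sigma2 = sigma2,
                                   seed = if (is.null(seed)) NA_integer_
                                          else as.integer(seed)))
}
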