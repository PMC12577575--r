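#' Priors on the true father count
#'
#' Convenience priors over X = 1..5 contributing fathers for
#' [father_count_posterior()]. `"uniform"` places mass 1/5 on each count and
#' is the default. `"polyandry_decreasing"` is the empirical
#' mating-number distribution for female green sea turtles,
#' (0.463, 0.318, 0.157, 0.034, 0.028), for users who prefer an informative
#' prior.
#'
#' @param prior `"uniform"`, `"polyandry_decreasing"`, or a numeric vector
#'   of 5 non-negative values summing to 1.
#' @return numeric probability vector of length 5.
#' @export
father_count_prior <- function(prior = "uniform") {
  if (is.character(prior)) {
    prior <- match.arg(prior, c("uniform", "polyandry_decreasing"))
    p <- switch(prior,
      uniform = rep(0.2, 5),
      polyandry_decreasing = mating_number_distribution("decreasing"))
  } else {
    p <- as.numeric(prior)
  }
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop("prior must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  p
}

#' Posterior on the number of contributing fathers
#'
#' Inverts an identification matrix by Bayes' theorem:
#' \deqn{P(X \mid Y) = \frac{P(Y \mid X)\, P(X)}{\sum_{X'} P(Y \mid X')\, P(X')}}
#' giving, for each observed count of identified fathers Y = 1..4, the
#' conditional distribution of the true father count X. Observing Y = 5
#' logically implies X = 5 (five is the modeled maximum), so that row is
#' omitted. A row whose marginal P(Y) is zero — the observation never
#' occurred in the simulations — is returned as `NA` with a warning rather
#' than as a silent 0/0.
#'
#' @param M an [identification_matrix()].
#' @param prior prior over X = 1..5; see [father_count_prior()].
#' @return a `posterior_table`: 4 x 5 matrix, rows Y = 1..4, columns
#'   X = 1..5, each defined row summing to 1 with zero mass at X < Y.
#' @examples
#' set.seed(42)
#' M <- identification_matrix("exponential", n = 32, reps = 500)
#' father_count_posterior(M)
#' @export
father_count_posterior <- function(M, prior = "uniform") {
  stopifnot(is.matrix(M), nrow(M) == 5L, ncol(M) == 5L)
  if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-9)) {
    stop("M must be row-stochastic", call. = FALSE)
  }
  p <- father_count_prior(prior)
  Q <- matrix(0, nrow = 4L, ncol = 5L, dimnames = list(Y = 1:4, X = 1:5))
  undefined <- logical(4L)
  for (y in 1:4) {
    joint <- M[, y] * p
    marg <- sum(joint)
    if (marg <= 0) {
      Q[y, ] <- NA_real_
      undefined[y] <- TRUE
    } else {
      Q[y, ] <- joint / marg
    }
  }
  if (any(undefined)) {
    warning("posterior undefined for Y = ",
            paste(which(undefined), collapse = ", "),
            " (identified count never observed); rows set to NA",
            call. = FALSE)
  }
  structure(Q, mode = attr(M, "mode"), sample_size = attr(M, "sample_size"),
            reps = attr(M, "reps"),
            class = c("posterior_table", "matrix", "array"))
}

#' Minimum diagonal of a posterior table
#'
#' The worst case over Y = 1..4 of the posterior probability that the true
#' father count equals the identified count — the headline accuracy figure
#' for a contribution mode and sample size ("the true count matched the
#' identified count in at least this fraction of cases"). Undefined (NA)
#' rows propagate to an NA result.
#'
#' @param Q a `posterior_table` from [father_count_posterior()].
#' @return the minimum of `Q[y, y]` over y = 1..4, or NA.
#' @export
min_diagonal <- function(Q) {
  stopifnot(inherits(Q, "posterior_table"))
  d <- Q[cbind(1:4, 1:4)]
  if (anyNA(d)) return(NA_real_)
  min(d)
}
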