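#' Clutch demography parameters
#'
#' Mean and standard deviation of the per-clutch egg count. Defaults are the
#' field estimates for a green sea turtle nesting population (mean 100.58
#' eggs, SD 22.61).
#'
#' @param mu_eggs mean eggs per clutch (> 0).
#' @param sigma_eggs standard deviation of eggs per clutch (>= 0).
#' @return a `clutch_demography` list.
#' @export
clutch_demography <- function(mu_eggs = 100.58, sigma_eggs = 22.61) {
  stopifnot(is.numeric(mu_eggs), length(mu_eggs) == 1L, mu_eggs > 0,
            is.numeric(sigma_eggs), length(sigma_eggs) == 1L, sigma_eggs >= 0)
  if (sigma_eggs == 0 && round_half_away(mu_eggs) < 1) {
    stop("degenerate demography: mu_eggs rounds below 1 with sigma_eggs = 0",
         call. = FALSE)
  }
  structure(list(mu_eggs = mu_eggs, sigma_eggs = sigma_eggs),
            class = "clutch_demography")
}

# round to nearest integer, ties away from zero (base round() rounds to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# positive integer draws from round(Normal(mu, sigma)); draws < 1 redrawn
draw_positive_count <- function(n, mu, sigma) {
  x <- round_half_away(stats::rnorm(n, mu, sigma))
  while (any(bad <- x < 1)) {
    x[bad] <- round_half_away(stats::rnorm(sum(bad), mu, sigma))
  }
  as.integer(x)
}

#' Draw clutch sizes
#'
#' Egg counts are normal draws rounded to the nearest integer (ties away
#' from zero); draws below one egg are redrawn, so the clutch is never
#' empty. At the default parameters the truncation point sits 4.4 SD below
#' the mean and shifts the realized mean by well under 0.01 egg.
#'
#' @param n number of clutch sizes to draw.
#' @param demog a [clutch_demography()].
#' @return integer vector of length `n`, all values >= 1.
#' @examples
#' set.seed(1)
#' draw_clutch_size(5)
#' @export
draw_clutch_size <- function(n = 1L, demog = clutch_demography()) {
  stopifnot(inherits(demog, "clutch_demography"))
  draw_positive_count(n, demog$mu_eggs, demog$sigma_eggs)
}

#' Assign eggs to fathers
#'
#' Each egg is fertilized independently by one father, drawn with the
#' mode's weighted probabilities (a multinomial over fathers by egg).
#' Because assignment is per egg, a father can sire zero eggs in a clutch —
#' a real feature of skewed modes that caps identification confidence even
#' at whole-clutch sampling.
#'
#' @param clutch_size integer number of eggs (>= 1).
#' @param weights fertilization weights from [contribution_weights()].
#' @return integer vector of father indices (1..F), one per egg.
#' @examples
#' set.seed(1)
#' table(assign_paternity(100, contribution_weights("dominant50", 5)))
#' @export
assign_paternity <- function(clutch_size, weights) {
  stopifnot(length(clutch_size) == 1L, clutch_size >= 1)
  f <- length(weights)
  if (f == 1L) return(rep.int(1L, clutch_size))
  sample.int(f, clutch_size, replace = TRUE, prob = weights)
}

#' Sample offspring from a clutch and identify fathers
#'
#' Draws `min(n, clutch size)` eggs uniformly without replacement (the whole
#' clutch when it is smaller than the requested sample) and returns the
#' distinct father labels observed. Parentage assignment from sampled
#' offspring is assumed error-free, so an observed label is an identified
#' father.
#'
#' @param fathers integer vector of per-egg father labels (a clutch).
#' @param n requested offspring sample size (>= 1).
#' @return sorted integer vector of identified father labels.
#' @export
sample_offspring <- function(fathers, n) {
  stopifnot(length(n) == 1L, n >= 1)
  size <- length(fathers)
  m <- min(as.integer(n), size)
  s <- if (m < size) fathers[sample.int(size, m)] else fathers
  sort(unique.default(s))
}

#' Exact probability of detecting every father in a sample
#'
#' Closed-form companion to the simulation: because eggs are labeled i.i.d.
#' and the offspring sample is drawn uniformly without replacement, the
#' sampled labels are themselves i.i.d. draws from the weight vector. The
#' probability that a sample of `m = min(n, clutch_size)` eggs contains all
#' F labels follows by inclusion-exclusion over the set of missed fathers:
#' \deqn{P = \sum_{S \subseteq \{1..F\}} (-1)^{|S|} (1 - \sum_{i \in S} w_i)^m}
#' Used as an independent oracle for the Monte-Carlo estimates; it is exact
#' at fixed clutch size and must be averaged over the clutch-size
#' distribution to match simulations with demographic stochasticity.
#'
#' @param weights fertilization weight vector.
#' @param n offspring sample size.
#' @param clutch_size total egg count.
#' @return probability that all `length(weights)` fathers appear.
#' @examples
#' analytic_identify_all_probability(c(0.9, 0.1), 32, 100)
#' @export
analytic_identify_all_probability <- function(weights, n, clutch_size) {
  stopifnot(n >= 1, clutch_size >= 1)
  f <- length(weights)
  m <- min(n, clutch_size)
  total <- 0
  for (k in 0:f) {
    if (k == 0L) {
      total <- total + 1
      next
    }
    miss <- utils::combn(f, k)
    missed_mass <- colSums(matrix(weights[miss], nrow = k))
    total <- total + (-1)^k * sum(pmax(1 - missed_mass, 0)^m)
  }
  min(max(total, 0), 1)
}

# Y (number of distinct fathers detected) for one simulated clutch
simulate_identified_count <- function(mode, n_fathers, n, demog) {
  w <- contribution_weights(resolve_mode(mode), n_fathers)
  size <- draw_clutch_size(1L, demog)
  eggs <- assign_paternity(size, w)
  m <- min(as.integer(n), size)
  s <- if (m < size) eggs[sample.int(size, m)] else eggs
  length(unique.default(s))
}

#' Distribution of the number of fathers identified
#'
#' Monte-Carlo estimate of P(Y fathers identified | X = `n_fathers`
#' contributed) for Y = 1..X at a fixed offspring sample size. Each
#' replicate simulates one clutch from scratch: mixed-dominant resolution,
#' clutch size, per-egg paternity, and a without-replacement offspring
#' sample.
#'
#' @param mode contribution mode (meta-modes allowed; resolved per clutch).
#' @param n_fathers true father count X, 1..5.
#' @param n offspring sample size.
#' @param demog a [clutch_demography()].
#' @param reps number of simulated clutches.
#' @return numeric vector `p` of length `n_fathers`; `p[y]` estimates
#'   P(Y = y | X); sums to 1.
#' @export
identification_distribution <- function(mode, n_fathers, n,
                                        demog = clutch_demography(),
                                        reps = 10000L) {
  stopifnot(reps >= 1)
  mode <- normalize_mode(mode)
  if (n_fathers == 1L) {
    p <- 1
    names(p) <- "1"
    return(p)
  }
  ys <- vapply(seq_len(reps), function(i) {
    simulate_identified_count(mode, n_fathers, n, demog)
  }, integer(1))
  p <- tabulate(ys, nbins = n_fathers) / reps
  names(p) <- as.character(seq_len(n_fathers))
  p
}

#' Identification matrix P(Y identified | X contributed)
#'
#' Stacks [identification_distribution()] for true father counts X = 1..5
#' into a row-stochastic 5 x 5 matrix; entries with Y > X are structural
#' zeros (a sample can never reveal more fathers than contributed).
#'
#' @inheritParams identification_distribution
#' @return an `identification_matrix`: 5 x 5 numeric matrix, rows indexed by
#'   X (contributing), columns by Y (identified), with attributes `mode`,
#'   `sample_size` and `reps`.
#' @export
identification_matrix <- function(mode, n, demog = clutch_demography(),
                                  reps = 10000L) {
  mode <- normalize_mode(mode)
  P <- matrix(0, nrow = 5L, ncol = 5L,
              dimnames = list(X = 1:5, Y = 1:5))
  for (x in 1:5) {
    P[x, seq_len(x)] <- identification_distribution(mode, x, n, demog, reps)
  }
  structure(P, mode = mode, sample_size = as.integer(n),
            reps = as.integer(reps), class = c("identification_matrix",
                                               "matrix", "array"))
}

#' Confidence of identifying all fathers versus sample size
#'
#' Estimates P(all X = `n_fathers` fathers identified) for each requested
#' sample size, i.e. the diagonal confidence curve. Within each replicate
#' the same clutch and a single random ordering of its eggs serve every
#' sample size (the size-n sample is the first n eggs of the ordering), so
#' samples are nested and the estimated curve is monotone non-decreasing by
#' construction.
#'
#' @inheritParams identification_distribution
#' @param sample_sizes integer vector of offspring sample sizes (1..96).
#' @return data.frame with columns `mode`, `n_fathers`, `sample_size`,
#'   `reps`, `confidence`, `mc_se`.
#' @export
clutch_confidence_curve <- function(mode, n_fathers, sample_sizes,
                                    demog = clutch_demography(),
                                    reps = 10000L) {
  mode <- normalize_mode(mode)
  stopifnot(all(sample_sizes >= 1), all(sample_sizes <= 96), reps >= 1)
  ns <- as.integer(sample_sizes)
  if (n_fathers == 1L) {
    conf <- rep(1, length(ns))
    se <- rep(0, length(ns))
  } else {
    hits <- integer(length(ns))
    for (r in seq_len(reps)) {
      w <- contribution_weights(resolve_mode(mode), n_fathers)
      size <- draw_clutch_size(1L, demog)
      eggs <- assign_paternity(size, w)
      shuffled <- eggs[sample.int(size)]
      # sample of size n contains all fathers iff every father's first
      # appearance in the shuffled order falls within the first min(n, size)
      first <- match(seq_len(n_fathers), shuffled)
      worst <- if (anyNA(first)) NA_integer_ else max(first)
      if (!is.na(worst)) hits <- hits + (worst <= pmin(ns, size))
    }
    conf <- hits / reps
    se <- sqrt(conf * (1 - conf) / reps)
  }
  data.frame(mode = mode, n_fathers = as.integer(n_fathers),
             sample_size = ns, reps = as.integer(reps),
             confidence = conf, mc_se = se)
}
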