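#' Mating-number distributions
#'
#' Probability of an adult mating with 1 to 5 mates in a season. Three named
#' systems are supported:
#'
#' * `"decreasing"` — (0.463, 0.318, 0.157, 0.034, 0.028), derived from
#'   published multiple-paternity rates for female green sea turtles;
#' * `"uniform"` — (0.2, 0.2, 0.2, 0.2, 0.2);
#' * `"none"` — (1, 0, 0, 0, 0), i.e. every adult of that sex mates exactly
#'   once (used to switch polygyny off).
#'
#' @param system a system name or a numeric vector of 5 probabilities.
#' @return numeric probability vector over 1..5 mates.
#' @export
mating_number_distribution <- function(system = c("decreasing", "uniform",
                                                  "none")) {
  if (is.character(system)) {
    system <- match.arg(system)
    p <- switch(system,
      decreasing = c(0.463, 0.318, 0.157, 0.034, 0.028),
      uniform    = rep(0.2, 5),
      none       = c(1, 0, 0, 0, 0))
  } else {
    p <- as.numeric(system)
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("mating-number distribution must be 5 non-negative ",
           "probabilities summing to 1", call. = FALSE)
    }
  }
  p
}

#' Season configuration
#'
#' Bundles the demographic and mating-system parameters of one simulated
#' breeding/nesting season. Defaults are the green sea turtle study values:
#' clutches per mother ~ Normal(4.95, 2.09) and eggs per clutch ~
#' Normal(100.58, 22.61), both rounded and truncated at 1.
#'
#' @param n_pop operational population size (adults available to breed).
#' @param osr operational sex ratio: proportion of available adults that are
#'   male, strictly between 0 and 1.
#' @param mode paternal contribution mode (see [contribution_modes()]).
#' @param polyandry female mating-number system; see
#'   [mating_number_distribution()].
#' @param polygyny male mating-number system.
#' @param mu_clutch,sigma_clutch clutches-per-mother normal parameters.
#' @param demog a [clutch_demography()].
#' @return a `season_config` list.
#' @export
season_config <- function(n_pop = 100L, osr = 0.5, mode = "random",
                          polyandry = "decreasing", polygyny = "decreasing",
                          mu_clutch = 4.95, sigma_clutch = 2.09,
                          demog = clutch_demography()) {
  stopifnot(n_pop >= 2, osr > 0, osr < 1, mu_clutch > 0, sigma_clutch >= 0)
  split <- split_population(n_pop, osr)
  cfg <- list(
    n_pop = as.integer(n_pop), osr = osr,
    n_males = split[["n_males"]], n_females = split[["n_females"]],
    mode = normalize_mode(mode),
    polyandry = mating_number_distribution(polyandry),
    polygyny = mating_number_distribution(polygyny),
    polyandry_name = if (is.character(polyandry)) polyandry else "custom",
    polygyny_name = if (is.character(polygyny)) polygyny else "custom",
    mu_clutch = mu_clutch, sigma_clutch = sigma_clutch,
    demog = demog)
  structure(cfg, class = "season_config")
}

#' Split the operational population into males and females
#'
#' `n_males = round(osr * n_pop)` (ties away from zero) and the remainder
#' are females. Configurations that leave either sex empty are rejected.
#'
#' @inheritParams season_config
#' @return named integer vector with elements `n_males`, `n_females`.
#' @examples
#' split_population(100, 0.05) # 5 males, 95 females
#' @export
split_population <- function(n_pop, osr) {
  stopifnot(n_pop >= 2, osr > 0, osr < 1)
  n_males <- as.integer(round_half_away(osr * n_pop))
  n_females <- as.integer(n_pop) - n_males
  if (n_males < 1L || n_females < 1L) {
    stop("degenerate population split: ", n_males, " males / ",
         n_females, " females", call. = FALSE)
  }
  c(n_males = n_males, n_females = n_females)
}

#' Build the male breeding pool
#'
#' Each male draws a mating capacity of 1-5 females from the polygyny
#' distribution and contributes that many slots to the breeding pool. With
#' polygyny `"none"` the pool holds exactly one slot per male.
#'
#' @param n_males number of males.
#' @param polygyny mating-number distribution (vector or name).
#' @return integer multiset of male IDs, one entry per mating slot.
#' @export
build_male_pool <- function(n_males, polygyny = "decreasing") {
  stopifnot(n_males >= 1)
  p <- mating_number_distribution(polygyny)
  capacity <- sample.int(5L, n_males, replace = TRUE, prob = p)
  rep.int(seq_len(n_males), capacity)
}

#' Mate females against the male breeding pool
#'
#' Mothers are processed in uniformly random order. Each draws a target mate
#' count of 1-5 from the polyandry distribution, then takes that many slots
#' from the pool belonging to distinct males, drawn uniformly over slots
#' (males with more free slots are proportionally more likely; a repeat male
#' is redrawn). A mother finding fewer distinct males than her target mates
#' with all that remain; once the pool is exhausted, the remaining mothers
#' do not mate and will not nest.
#'
#' @param n_females number of potential mothers.
#' @param pool male-slot multiset from [build_male_pool()].
#' @param polyandry mating-number distribution (vector or name).
#' @return list of length `n_females`; element i is mother i's mates as an
#'   integer vector of male IDs in the order drawn (possibly empty).
#' @export
mate_females <- function(n_females, pool, polyandry = "decreasing") {
  stopifnot(n_females >= 1)
  p <- mating_number_distribution(polyandry)
  slots <- tabulate(pool, nbins = if (length(pool)) max(pool) else 1L)
  mates <- rep(list(integer(0)), n_females)
  remaining <- sum(slots)
  for (i in sample.int(n_females)) {
    if (remaining == 0L) next
    target <- sample.int(5L, 1L, prob = p)
    chosen <- integer(0)
    for (j in seq_len(target)) {
      avail <- which(slots > 0L)
      avail <- avail[!avail %in% chosen]
      if (!length(avail)) break
      male <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = slots[avail])
      chosen <- c(chosen, male)
      slots[male] <- slots[male] - 1L
      remaining <- remaining - 1L
    }
    mates[[i]] <- chosen
  }
  mates
}

#' Simulate one breeding and nesting season
#'
#' Builds the male pool, mates the females, and lays and fertilizes every
#' clutch. Each mated mother lays `round(Normal(mu_clutch, sigma_clutch))`
#' clutches (redrawn to be >= 1); every clutch draws its egg count from the
#' clutch demography and assigns each egg to one of the mother's mates with
#' the contribution-mode weights. The mate drawn first at mating occupies
#' the dominant weight position, fixed across all her clutches; a
#' mixed-dominant mode is re-resolved independently for every clutch.
#'
#' @param config a [season_config()].
#' @return a `season_outcome` list with elements `breeding_fathers` (male
#'   IDs that mated at least once), `mate_lists` (per-mother mates), and
#'   `clutches` (list of lists with `mother` and per-egg `fathers`).
#' @export
simulate_season <- function(config) {
  stopifnot(inherits(config, "season_config"))
  pool <- build_male_pool(config$n_males, config$polygyny)
  mate_lists <- mate_females(config$n_females, pool, config$polyandry)
  clutches <- list()
  k <- 0L
  for (i in seq_along(mate_lists)) {
    mates <- mate_lists[[i]]
    f <- length(mates)
    if (f == 0L) next
    n_clutches <- draw_positive_count(1L, config$mu_clutch,
                                      config$sigma_clutch)
    for (cl in seq_len(n_clutches)) {
      size <- draw_clutch_size(1L, config$demog)
      w <- contribution_weights(resolve_mode(config$mode), f)
      eggs <- mates[assign_paternity(size, w)]
      k <- k + 1L
      clutches[[k]] <- list(mother = i, fathers = eggs)
    }
  }
  breeding <- sort(unique.default(unlist(mate_lists, use.names = FALSE)))
  structure(list(breeding_fathers = breeding, mate_lists = mate_lists,
                 clutches = clutches),
            class = "season_outcome")
}

#' Season sampling design
#'
#' @param clutch_fraction proportion of the season's clutches to sample, in
#'   (0, 1]; the number sampled is rounded up to a whole clutch.
#' @param n_per_clutch offspring sampled per sampled clutch (whole clutch if
#'   smaller); 32 and 96 correspond to a third of a 96-well plate and a full
#'   plate.
#' @param success_threshold minimum fraction of breeding fathers that must
#'   be identified for a replicate to count as a success (1 = all fathers).
#' @return a `sampling_design` list.
#' @export
sampling_design <- function(clutch_fraction = 1, n_per_clutch = 32L,
                            success_threshold = 1) {
  stopifnot(clutch_fraction > 0, clutch_fraction <= 1, n_per_clutch >= 1,
            success_threshold > 0, success_threshold <= 1)
  structure(list(clutch_fraction = clutch_fraction,
                 n_per_clutch = as.integer(n_per_clutch),
                 success_threshold = success_threshold),
            class = "sampling_design")
}

#' Sample a simulated season
#'
#' Chooses `ceiling(clutch_fraction * n_clutches)` clutches uniformly
#' without replacement from all clutches laid in the season, subsamples each
#' with [sample_offspring()], and pools the father labels observed.
#'
#' @param outcome a `season_outcome` from [simulate_season()].
#' @param design a [sampling_design()].
#' @return list with `identified` (male IDs detected) and
#'   `breeding_fathers` (male IDs that actually bred).
#' @export
sample_season <- function(outcome, design) {
  stopifnot(inherits(outcome, "season_outcome"),
            inherits(design, "sampling_design"))
  n_cl <- length(outcome$clutches)
  if (n_cl == 0L) {
    stop("degenerate season: no clutches were laid", call. = FALSE)
  }
  n_sample <- ceiling(design$clutch_fraction * n_cl)
  idx <- if (n_sample < n_cl) sample.int(n_cl, n_sample) else seq_len(n_cl)
  identified <- integer(0)
  for (j in idx) {
    identified <- union(identified,
                        sample_offspring(outcome$clutches[[j]]$fathers,
                                         design$n_per_clutch))
  }
  list(identified = sort(identified),
       breeding_fathers = outcome$breeding_fathers)
}

# successes required to clear a fractional threshold
required_fathers <- function(threshold, n_breeding) {
  as.integer(ceiling(threshold * n_breeding - 1e-9))
}

#' Confidence of identifying the breeding fathers of a season
#'
#' Runs `reps` independent seasons and reports the proportion in which at
#' least `success_threshold` of the breeding fathers were identified
#' (ceiling applied to the required count). The denominator is the set of
#' males that mated, including any that by chance fertilized no surviving
#' egg, so full-census confidence can fall below 1 under skewed contribution
#' modes. Seasons in which no female mated count as failures.
#'
#' @inheritParams sample_season
#' @param config a [season_config()].
#' @param reps number of simulated seasons.
#' @return list with `confidence`, `mc_se`, `mean_breeding_fathers`,
#'   `mean_clutches`, `degenerate` (zero-clutch season count) and `reps`.
#' @export
season_confidence <- function(config, design, reps = 10000L) {
  stopifnot(reps >= 1)
  successes <- 0L
  degenerate <- 0L
  tot_breeding <- 0
  tot_clutches <- 0
  for (r in seq_len(reps)) {
    out <- simulate_season(config)
    tot_breeding <- tot_breeding + length(out$breeding_fathers)
    tot_clutches <- tot_clutches + length(out$clutches)
    if (length(out$clutches) == 0L) {
      degenerate <- degenerate + 1L
      next
    }
    s <- sample_season(out, design)
    need <- required_fathers(design$success_threshold,
                             length(s$breeding_fathers))
    if (length(s$identified) >= need) successes <- successes + 1L
  }
  conf <- successes / reps
  list(confidence = conf, mc_se = sqrt(conf * (1 - conf) / reps),
       mean_breeding_fathers = tot_breeding / reps,
       mean_clutches = tot_clutches / reps,
       degenerate = degenerate, reps = as.integer(reps))
}

#' Confidence across a grid of clutch fractions (common random numbers)
#'
#' Evaluates every clutch fraction on the same `reps` simulated seasons: one
#' random clutch ordering per season supplies nested clutch subsets (the
#' fraction-f sample is the first `ceiling(f * n)` clutches), and each
#' clutch's offspring subsample is drawn once and reused. Marginally each
#' fraction's estimate is identical in distribution to an independent run,
#' and the estimated curve is monotone non-decreasing in the fraction by
#' construction.
#'
#' @inheritParams season_confidence
#' @param n_per_clutch offspring sampled per clutch.
#' @param success_threshold minimum identified fraction for success.
#' @param fractions increasing vector of clutch fractions in (0, 1].
#' @return data.frame with columns `clutch_fraction`, `confidence`, `mc_se`,
#'   plus attributes `mean_breeding_fathers`, `mean_clutches`, `degenerate`.
#' @export
season_fraction_sweep <- function(config, n_per_clutch = 32L,
                                  success_threshold = 1,
                                  fractions = seq(0.05, 1, by = 0.05),
                                  reps = 1000L) {
  stopifnot(inherits(config, "season_config"), reps >= 1,
            all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions))
  hits <- integer(length(fractions))
  degenerate <- 0L
  tot_breeding <- 0
  tot_clutches <- 0
  for (r in seq_len(reps)) {
    out <- simulate_season(config)
    n_cl <- length(out$clutches)
    nb <- length(out$breeding_fathers)
    tot_breeding <- tot_breeding + nb
    tot_clutches <- tot_clutches + n_cl
    if (n_cl == 0L) {
      degenerate <- degenerate + 1L
      next
    }
    perm <- sample.int(n_cl)
    # per-clutch identified sets, drawn once and reused across fractions
    per_clutch <- lapply(out$clutches[perm], function(cl) {
      sample_offspring(cl$fathers, n_per_clutch)
    })
    need <- required_fathers(success_threshold, nb)
    # cumulative distinct fathers after sampling the first k clutches
    seen <- logical(max(out$breeding_fathers))
    count_after <- integer(n_cl)
    n_seen <- 0L
    for (k in seq_len(n_cl)) {
      for (m in per_clutch[[k]]) {
        if (!seen[m]) {
          seen[m] <- TRUE
          n_seen <- n_seen + 1L
        }
      }
      count_after[k] <- n_seen
    }
    k_f <- ceiling(fractions * n_cl)
    hits <- hits + (count_after[k_f] >= need)
  }
  conf <- hits / reps
  res <- data.frame(clutch_fraction = fractions, confidence = conf,
                    mc_se = sqrt(conf * (1 - conf) / reps))
  attr(res, "mean_breeding_fathers") <- tot_breeding / reps
  attr(res, "mean_clutches") <- tot_clutches / reps
  attr(res, "degenerate") <- degenerate
  res
}

#' Minimal clutch fraction reaching a target confidence
#'
#' Sweeps clutch fractions 0.05, 0.10, ..., 1.00 (by default) and returns
#' the smallest fraction whose estimated confidence reaches
#' `target_confidence`, or `NA` if even sampling every clutch falls short.
#'
#' @inheritParams season_fraction_sweep
#' @param target_confidence required confidence, default 0.80.
#' @return the minimal fraction on the grid, or `NA_real_`.
#' @export
minimal_clutch_fraction <- function(config, n_per_clutch = 32L,
                                    success_threshold = 1,
                                    target_confidence = 0.80,
                                    fractions = seq(0.05, 1, by = 0.05),
                                    reps = 1000L) {
  sweep <- season_fraction_sweep(config, n_per_clutch, success_threshold,
                                 fractions, reps)
  ok <- which(sweep$confidence >= target_confidence)
  if (!length(ok)) NA_real_ else sweep$clutch_fraction[min(ok)]
}
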