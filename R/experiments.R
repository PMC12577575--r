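#' @keywords internal
pkg_version_string <- function() {
  paste0("paternitypower ", utils::packageVersion("paternitypower"))
}

#' Within-clutch confidence sweep
#'
#' Confidence of identifying all fathers of a single clutch over a grid of
#' contribution modes, father counts and offspring sample sizes. One row
#' per (mode, father count, sample size) cell; rows carry the full
#' parameter tuple, replicate count, seed and software version so a result
#' file is self-describing. Rerunning with the same arguments and seed
#' reproduces the table exactly.
#'
#' @param modes character vector of contribution modes.
#' @param fathers integer vector of true father counts (1..5).
#' @param sample_sizes integer vector of offspring sample sizes (1..96).
#' @param demog a [clutch_demography()].
#' @param reps simulated clutches per cell (10,000 reproduces the study
#'   scale; smaller values suit exploratory runs).
#' @param seed integer RNG seed for the whole sweep.
#' @return data.frame: `mode`, `n_fathers`, `sample_size`, `reps`,
#'   `confidence`, `mc_se`, `seed`, `version`.
#' @export
run_clutch_sweep <- function(modes, fathers, sample_sizes,
                             demog = clutch_demography(),
                             reps = 10000L, seed = 1L) {
  modes <- vapply(modes, normalize_mode, character(1), USE.NAMES = FALSE)
  stopifnot(all(fathers >= 1), all(fathers <= 5),
            all(sample_sizes >= 1), all(sample_sizes <= 96))
  set.seed(as.integer(seed))
  rows <- list()
  for (mode in modes) {
    for (f in sort(unique(as.integer(fathers)))) {
      rows[[length(rows) + 1L]] <-
        clutch_confidence_curve(mode, f, sample_sizes, demog, reps)
    }
  }
  out <- do.call(rbind, rows)
  out$seed <- as.integer(seed)
  out$version <- pkg_version_string()
  rownames(out) <- NULL
  out
}

#' Identification matrices in long format
#'
#' Estimates P(Y identified | X contributed) for each mode and sample size
#' and returns the stacked matrices as a long table.
#'
#' @inheritParams run_clutch_sweep
#' @return data.frame: `mode`, `sample_size`, `X`, `Y`, `probability`,
#'   `reps`, `seed`, `version`.
#' @export
run_identification_tables <- function(modes, sample_sizes = c(32L, 96L),
                                      demog = clutch_demography(),
                                      reps = 10000L, seed = 1L) {
  modes <- vapply(modes, normalize_mode, character(1), USE.NAMES = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  for (mode in modes) {
    for (n in as.integer(sample_sizes)) {
      M <- identification_matrix(mode, n, demog, reps)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, sample_size = n,
        X = rep(1:5, times = 5L), Y = rep(1:5, each = 5L),
        probability = as.vector(M))
    }
  }
  out <- do.call(rbind, rows)
  out$reps <- as.integer(reps)
  out$seed <- as.integer(seed)
  out$version <- pkg_version_string()
  rownames(out) <- NULL
  out
}

#' Posterior tables over modes and sample sizes
#'
#' Builds identification matrices and inverts them with
#' [father_count_posterior()], emitting each posterior as long-format rows
#' P(X contributed | Y identified) for Y = 1..4.
#'
#' @inheritParams run_clutch_sweep
#' @param prior prior over the true father count; see
#'   [father_count_prior()].
#' @return data.frame: `mode`, `sample_size`, `Y`, `X`, `probability`,
#'   `reps`, `seed`, `version`.
#' @export
run_posterior_tables <- function(modes, sample_sizes = c(32L, 96L),
                                 prior = "uniform",
                                 demog = clutch_demography(),
                                 reps = 10000L, seed = 1L) {
  modes <- vapply(modes, normalize_mode, character(1), USE.NAMES = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  for (mode in modes) {
    for (n in as.integer(sample_sizes)) {
      M <- identification_matrix(mode, n, demog, reps)
      Q <- father_count_posterior(M, prior)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, sample_size = n,
        Y = rep(1:4, times = 5L), X = rep(1:5, each = 4L),
        probability = as.vector(Q))
    }
  }
  out <- do.call(rbind, rows)
  out$reps <- as.integer(reps)
  out$seed <- as.integer(seed)
  out$version <- pkg_version_string()
  rownames(out) <- NULL
  out
}

#' Season-scale confidence grid
#'
#' Confidence of identifying the season's breeding fathers over a grid of
#' operational sex ratios and clutch fractions, for one population size,
#' contribution mode and mating system. Within each sex ratio all clutch
#' fractions share the same simulated seasons (common random numbers), so
#' each row's confidence estimate is unbiased and the fraction profile is
#' monotone.
#'
#' @param n_pop operational population size.
#' @param osr numeric vector of operational sex ratios in (0, 1).
#' @param clutch_fractions increasing vector of clutch fractions in (0, 1].
#' @param n_per_clutch offspring sampled per sampled clutch.
#' @param mode paternal contribution mode.
#' @param polyandry,polygyny mating systems; see
#'   [mating_number_distribution()].
#' @param success_threshold minimum fraction of breeding fathers identified
#'   for success.
#' @param reps simulated seasons per sex ratio.
#' @param seed integer RNG seed.
#' @return data.frame: `pop_size`, `osr`, `clutch_fraction`, `n_per_clutch`,
#'   `mode`, `polyandry`, `polygyny`, `threshold`, `reps`, `confidence`,
#'   `mc_se`, `mean_breeding_fathers`, `mean_clutches`, `seed`, `version`.
#' @export
run_season_grid <- function(n_pop = 100L,
                            osr = seq(0.05, 0.95, by = 0.05),
                            clutch_fractions = seq(0.05, 1, by = 0.05),
                            n_per_clutch = 32L, mode = "random",
                            polyandry = "decreasing",
                            polygyny = "decreasing",
                            success_threshold = 1,
                            reps = 1000L, seed = 1L) {
  mode <- normalize_mode(mode)
  set.seed(as.integer(seed))
  rows <- list()
  for (r in osr) {
    cfg <- season_config(n_pop = n_pop, osr = r, mode = mode,
                         polyandry = polyandry, polygyny = polygyny)
    sw <- season_fraction_sweep(cfg, n_per_clutch, success_threshold,
                                clutch_fractions, reps)
    rows[[length(rows) + 1L]] <- data.frame(
      pop_size = as.integer(n_pop), osr = r,
      clutch_fraction = sw$clutch_fraction,
      n_per_clutch = as.integer(n_per_clutch), mode = mode,
      polyandry = cfg$polyandry_name, polygyny = cfg$polygyny_name,
      threshold = success_threshold, reps = as.integer(reps),
      confidence = sw$confidence, mc_se = sw$mc_se,
      mean_breeding_fathers = attr(sw, "mean_breeding_fathers"),
      mean_clutches = attr(sw, "mean_clutches"))
  }
  out <- do.call(rbind, rows)
  out$seed <- as.integer(seed)
  out$version <- pkg_version_string()
  rownames(out) <- NULL
  out
}
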