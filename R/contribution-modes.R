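#' Paternal contribution modes
#'
#' The six admissible paternal-contribution modes. Each mode determines how a
#' clutch's eggs are apportioned among its `F` fathers (1 <= F <= 5):
#'
#' * `random` — every father fertilizes an equal expected share, 1/F.
#' * `exponential` — a strict hierarchy: 1/2, 1/4, 1/8, ... with the last
#'   father repeating the previous level so the shares sum to one.
#' * `dominant50`, `dominant70`, `dominant90` — one dominant father with
#'   expected share 0.5, 0.7 or 0.9; the remainder split equally among the
#'   other F - 1 fathers.
#' * `mixed_dominant` — a meta-mode: each clutch independently behaves as
#'   one of the three dominant modes, chosen uniformly at random.
#'
#' Mode names are matched case-insensitively, ignoring spaces, dashes and
#' underscores, so `"Dominant 50"`, `"dominant-50"` and `"DOMINANT50"` all
#' name the same mode.
#'
#' @return `contribution_modes()` returns the character vector of the six
#'   canonical mode names.
#' @examples
#' contribution_modes()
#' @export
contribution_modes <- function() {
  c("random", "exponential", "dominant50", "dominant70", "dominant90",
    "mixed_dominant")
}

#' @rdname contribution_modes
#' @param mode a mode name (any accepted spelling).
#' @return `normalize_mode()` returns the canonical name.
#' @export
normalize_mode <- function(mode) {
  stopifnot(is.character(mode), length(mode) == 1L, !is.na(mode))
  key <- gsub("[ _-]", "", tolower(mode))
  canon <- contribution_modes()
  hit <- match(key, gsub("[ _-]", "", canon))
  if (is.na(hit)) {
    stop("unknown contribution mode: '", mode, "' (expected one of ",
         paste(canon, collapse = ", "), ")", call. = FALSE)
  }
  canon[hit]
}

#' Resolve a meta-mode to a concrete contribution mode
#'
#' `mixed_dominant` resolves to `dominant50`, `dominant70` or `dominant90`,
#' each with probability 1/3, using the current RNG state; concrete modes are
#' returned unchanged. Resolution happens independently for every clutch, so
#' a mixed-dominant population contains clutches of all three dominance
#' levels.
#'
#' @param mode a contribution mode name.
#' @return a concrete mode name (never `mixed_dominant`).
#' @examples
#' set.seed(1)
#' resolve_mode("mixed_dominant")
#' resolve_mode("random")
#' @export
resolve_mode <- function(mode) {
  mode <- normalize_mode(mode)
  if (mode == "mixed_dominant") {
    c("dominant50", "dominant70", "dominant90")[sample.int(3L, 1L)]
  } else {
    mode
  }
}

#' Per-father fertilization weights
#'
#' Expected egg shares for the `F` fathers of a clutch under a concrete
#' contribution mode. Position 1 is the dominant (or top-of-hierarchy)
#' father; callers decide which actual male occupies each position. With a
#' single father every mode degenerates to weight 1.
#'
#' @param mode a concrete contribution mode (`mixed_dominant` must be
#'   resolved with [resolve_mode()] first).
#' @param n_fathers integer father count, 1 to 5.
#' @return numeric vector of length `n_fathers`; positive, sums to 1.
#' @examples
#' contribution_weights("dominant50", 5)  # 0.5 0.125 0.125 0.125 0.125
#' contribution_weights("exponential", 3) # 0.5 0.25 0.25
#' @export
contribution_weights <- function(mode, n_fathers) {
  mode <- normalize_mode(mode)
  if (mode == "mixed_dominant") {
    stop("mixed_dominant is a meta-mode; resolve it with resolve_mode() ",
         "before requesting weights", call. = FALSE)
  }
  if (length(n_fathers) != 1L || is.na(n_fathers) ||
      n_fathers != as.integer(n_fathers) || n_fathers < 1 || n_fathers > 5) {
    stop("n_fathers must be a single integer between 1 and 5", call. = FALSE)
  }
  f <- as.integer(n_fathers)
  if (f == 1L) return(1)
  w <- switch(mode,
    random      = rep.int(1 / f, f),
    exponential = c(0.5^seq_len(f - 1L), 0.5^(f - 1L)),
    dominant50  = c(0.5, rep.int(0.5 / (f - 1L), f - 1L)),
    dominant70  = c(0.7, rep.int(0.3 / (f - 1L), f - 1L)),
    dominant90  = c(0.9, rep.int(0.1 / (f - 1L), f - 1L))
  )
  w
}

#' Marginal paternal contribution
#'
#' The smallest expected egg share of any single father — the share of the
#' least dominant male. Identifying all fathers is hardest when this
#' marginal contribution is small. At F = 5 the marginals are: random 0.2,
#' dominant50 0.125, dominant70 0.075, exponential 0.0625, dominant90 0.025.
#'
#' @inheritParams contribution_weights
#' @return the minimum fertilization weight.
#' @examples
#' marginal_contribution("exponential", 5) # 0.0625
#' @export
marginal_contribution <- function(mode, n_fathers) {
  min(contribution_weights(mode, n_fathers))
}
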