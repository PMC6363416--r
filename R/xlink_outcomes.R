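# Combinatorics of bifunctional cross-linking within a trimer carrying one
# reactive cysteine per subunit, and the monomer/dimer/trimer band
# fractions it predicts on a denaturing gel.

#' Cross-linking reaction parameters
#'
#' @param p_link probability that an available adjacent cysteine pair is
#'   bridged when visited.
#' @param p_mono probability that a cysteine left free at the end of the
#'   reaction carries a dead-end mono-adduct. Mono-adducts consume a
#'   cysteine without joining subunits, so they never change which band a
#'   subunit runs in; the parameter is tracked for completeness.
#' @param r_retain probability that a bridged trimer survives SDS treatment
#'   and runs as a trimer band (all three subunits) instead of dimer +
#'   monomer.
#' @return An object of class `reaction_params`.
#' @export
reaction_params <- function(p_link = 1, p_mono = 0, r_retain = 0) {
  v <- c(p_link = p_link, p_mono = p_mono, r_retain = r_retain)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("all reaction probabilities must lie in [0, 1]")
  }
  structure(as.list(v), class = "reaction_params")
}

.band_fractions <- function(monomer, dimer, trimer) {
  s <- monomer + dimer + trimer
  if (abs(s - 1) > 1e-12) stop("band fractions must sum to 1")
  structure(list(monomer = monomer, dimer = dimer, trimer = trimer),
            class = "band_fractions")
}

#' @export
print.band_fractions <- function(x, ...) {
  cat(sprintf("band fractions (subunit signal): monomer %.4f, dimer %.4f, trimer %.4f\n",
              x$monomer, x$dimer, x$trimer))
  invisible(x)
}

#' Dimer-band ceiling at cross-linking saturation
#'
#' With one reactive cysteine per subunit, at most one bridge can form per
#' trimer: the first bridge consumes two of the three cysteines, and every
#' remaining pair shares a consumed cysteine. At saturation (every trimer
#' bridged, no trimer-band retention) each trimer therefore contributes two
#' subunits to the dimer band and one to the monomer band, so the dimer
#' band carries exactly 2/3 of the subunit signal — the benchmark for
#' "efficient cross-linking within a trimer" on a Western blot.
#'
#' @return List with `fraction` (2/3, computed from the saturated reaction
#'   model) and `percent_floor` (whole-percent floor, 66).
#' @export
saturation_dimer_percent <- function() {
  sat <- analytic_band_fractions(reaction_params(p_link = 1, p_mono = 0,
                                                 r_retain = 0))
  list(fraction = sat$dimer, percent_floor = floor(100 * sat$dimer))
}

#' Analytic band fractions under the sequential-pair reaction scheme
#'
#' Per trimer, the three interface cysteine pairs are visited in random
#' order; a visited pair bridges with probability `p_link` if both its
#' cysteines are free. Because a bridge consumes two of the three
#' cysteines, at most one bridge forms, and the probability that a trimer
#' ends up bridged is `q = 1 - (1 - p_link)^3` regardless of visit order.
#' A bridged trimer runs as a trimer band with probability `r_retain`
#' (3 subunits), otherwise as dimer (2 subunits) + monomer (1 subunit).
#'
#' @param params a [reaction_params()].
#' @return A `band_fractions` object (fractions of total subunit signal).
#' @export
analytic_band_fractions <- function(params) {
  stopifnot(inherits(params, "reaction_params"))
  q <- 1 - (1 - params$p_link)^3
  trimer <- q * params$r_retain
  dimer <- q * (1 - params$r_retain) * (2 / 3)
  .band_fractions(1 - trimer - dimer, dimer, trimer)
}

#' Exhaustive enumeration of per-trimer reaction outcomes
#'
#' Walks the full probability tree of the sequential-pair scheme — all 6
#' visit orders of the three pairs, bridge/no-bridge at each available
#' pair, retained/released for bridged trimers — and accumulates
#' probability-weighted subunit counts per band. Independent route to the
#' same quantities as [analytic_band_fractions()].
#'
#' @param params a [reaction_params()].
#' @return A `band_fractions` object.
#' @export
enumerate_band_fractions <- function(params) {
  stopifnot(inherits(params, "reaction_params"))
  orders <- pracma::perms(1:3)          # visit orders of pairs AB, BC, CA
  pair_members <- list(c(1, 2), c(2, 3), c(3, 1))
  acc <- c(monomer = 0, dimer = 0, trimer = 0)
  for (o in seq_len(nrow(orders))) {
    ord <- orders[o, ]
    # recursive walk over bridge outcomes at each visited pair
    walk <- function(step, free, bridged, prob) {
      if (step > 3 || bridged) {
        if (bridged) {
          acc["trimer"] <<- acc["trimer"] + prob * params$r_retain * 3 / 3
          acc["dimer"] <<- acc["dimer"] + prob * (1 - params$r_retain) * 2 / 3
          acc["monomer"] <<- acc["monomer"] + prob * (1 - params$r_retain) * 1 / 3
        } else {
          acc["monomer"] <<- acc["monomer"] + prob * 3 / 3
        }
        return(invisible())
      }
      mem <- pair_members[[ord[step]]]
      if (all(free[mem])) {
        f2 <- free; f2[mem] <- FALSE
        walk(step + 1, f2, TRUE, prob * params$p_link)
        walk(step + 1, free, FALSE, prob * (1 - params$p_link))
      } else {
        walk(step + 1, free, FALSE, prob)
      }
    }
    walk(1, rep(TRUE, 3), FALSE, 1 / nrow(orders))
  }
  .band_fractions(acc[["monomer"]], acc[["dimer"]], acc[["trimer"]])
}

#' Monte-Carlo simulation of cross-linking outcomes
#'
#' Stochastic twin of [analytic_band_fractions()]: simulates `n_trimers`
#' independent trimers through the sequential-pair scheme and tallies
#' subunit signal per band, with binomial standard errors.
#'
#' @param params a [reaction_params()].
#' @param n_trimers number of trimers to simulate (>= 1).
#' @param seed integer seed; the run is reproducible.
#' @return A `band_fractions` object with attribute `"se"` (Monte-Carlo
#'   standard errors of the three fractions) and `"n_trimers"`.
#' @export
simulate_outcomes <- function(params, n_trimers, seed = 1) {
  stopifnot(inherits(params, "reaction_params"))
  if (length(n_trimers) != 1 || n_trimers < 1) stop("`n_trimers` must be >= 1")
  n_trimers <- as.integer(n_trimers)
  withr::with_seed(as.integer(seed), {
    # visit the three pairs in random order; only the first success can
    # bridge (a bridge consumes two of the three cysteines)
    u <- matrix(stats::runif(3L * n_trimers), nrow = 3L)
    bridged <- colSums(u < params$p_link) > 0
    retained <- bridged & (stats::runif(n_trimers) < params$r_retain)
  })
  # per-trimer subunit counts in each band (3/0/0, 1/2/0 or 0/0/3)
  dimered <- bridged & !retained
  mono_i <- ifelse(retained, 0, ifelse(dimered, 1, 3))
  dim_i <- ifelse(dimered, 2, 0)
  tri_i <- ifelse(retained, 3, 0)
  out <- .band_fractions(mean(mono_i) / 3, mean(dim_i) / 3, mean(tri_i) / 3)
  se <- c(monomer = stats::sd(mono_i), dimer = stats::sd(dim_i),
          trimer = stats::sd(tri_i)) / (3 * sqrt(n_trimers))
  attr(out, "se") <- se
  attr(out, "n_trimers") <- n_trimers
  out
}
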