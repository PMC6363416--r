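# The molecular-caliper layer: conversion between backbone Ca-Ca
# separations and the sulphhydryl-to-sulphhydryl span a bifunctional
# cross-linker must bridge, compatibility classification, and the
# inter-trimer placement search that discriminates intra- from
# inter-trimer cross-linking.

#' Built-in bifunctional cross-linker definitions
#'
#' The three cysteine-reactive reagents commonly used as graded calipers on
#' trimeric receptors, with sulphhydryl-to-sulphhydryl spacer lengths:
#' MTS-2-MTS (5.2 A), BMB (10.9 A) and BM(PEG)2 (14.7 A).
#'
#' @return Data frame with columns `name` and `spacer_ss` (Angstrom).
#' @export
builtin_linkers <- function() {
  data.frame(name = c("MTS-2-MTS", "BMB", "BM(PEG)2"),
             spacer_ss = c(5.2, 10.9, 14.7),
             stringsAsFactors = FALSE)
}

#' Cross-linker definition
#' @param name reagent name.
#' @param spacer_ss sulphhydryl-to-sulphhydryl spacer length, Angstrom (> 0).
#' @return An object of class `cross_linker`.
#' @export
cross_linker <- function(name, spacer_ss) {
  if (!is.numeric(spacer_ss) || length(spacer_ss) != 1 || spacer_ss <= 0) {
    stop("`spacer_ss` must be a single positive length in Angstrom")
  }
  structure(list(name = as.character(name), spacer_ss = spacer_ss),
            class = "cross_linker")
}

#' Look up a built-in cross-linker by name
#' @param name one of `"MTS-2-MTS"`, `"BMB"`, `"BM(PEG)2"`.
#' @return A [cross_linker()].
#' @export
get_linker <- function(name) {
  tab <- builtin_linkers()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown linker '", name, "'; built-ins: ",
         paste(tab$name, collapse = ", "))
  }
  cross_linker(tab$name[i], tab$spacer_ss[i])
}

#' Caliper conversion convention
#'
#' The per-cysteine Ca-to-thiol reach used to relate a backbone Ca-Ca
#' separation to the S-to-S span a linker must bridge:
#' `d_xlink = d_ca - 2 * delta_ca_s`. The default 4.3 A is the exact
#' least-squares constant recovered by [calibrate_delta()] from the four
#' standard printed Ca-Ca/cross-link equivalences (residual zero).
#'
#' @param delta_ca_s per-cysteine Ca-to-thiol offset, Angstrom (>= 0).
#' @return An object of class `caliper_convention`.
#' @export
caliper_convention <- function(delta_ca_s = 4.3) {
  if (!is.numeric(delta_ca_s) || length(delta_ca_s) != 1 || delta_ca_s < 0) {
    stop("`delta_ca_s` must be a single non-negative number")
  }
  structure(list(delta_ca_s = delta_ca_s), class = "caliper_convention")
}

#' Convert a Ca-Ca separation to the equivalent cross-link span
#'
#' @param d_ca Ca-Ca distance(s), Angstrom, >= 0.
#' @param conv a [caliper_convention()].
#' @return `pmax(0, d_ca - 2 * delta_ca_s)`: the S-to-S span a bifunctional
#'   linker must bridge; floored at zero when the side-chain reach consumes
#'   the whole backbone separation.
#' @examples
#' ca_to_xlink(20.5)  # 11.9
#' @export
ca_to_xlink <- function(d_ca, conv = caliper_convention()) {
  if (any(d_ca < 0)) stop("`d_ca` must be non-negative")
  pmax(0, d_ca - 2 * conv$delta_ca_s)
}

#' Convert a cross-link span to the equivalent Ca-Ca separation
#'
#' Inverse of [ca_to_xlink()] on its positive range; used to turn a linker
#' spacer length into a backbone distance constraint for modelling.
#'
#' @param d_xl S-to-S span(s), Angstrom, >= 0.
#' @param conv a [caliper_convention()].
#' @return `d_xl + 2 * delta_ca_s`.
#' @examples
#' xlink_to_ca(10.9)  # 19.5
#' @export
xlink_to_ca <- function(d_xl, conv = caliper_convention()) {
  if (any(d_xl < 0)) stop("`d_xl` must be non-negative")
  d_xl + 2 * conv$delta_ca_s
}

#' Recover the per-cysteine offset from paired distances
#'
#' Least-squares fit of the constant-offset model `d_xl = d_ca - 2*delta`
#' to observed (Ca-Ca, cross-link) pairs; the estimate is the mean of the
#' half-differences.
#'
#' @param d_ca numeric vector of Ca-Ca distances, Angstrom.
#' @param d_xl matching cross-link spans, Angstrom.
#' @return A [caliper_convention()] with attributes `max_residual` and
#'   `residuals` (fitted-minus-observed cross-link spans).
#' @export
calibrate_delta <- function(d_ca, d_xl) {
  if (length(d_ca) == 0) stop("no calibration pairs supplied")
  if (length(d_ca) != length(d_xl)) stop("`d_ca` and `d_xl` lengths differ")
  if (any(d_ca < 0) || any(d_xl < 0)) stop("distances must be non-negative")
  delta <- mean((d_ca - d_xl) / 2)
  res <- (d_ca - 2 * delta) - d_xl
  out <- caliper_convention(max(0, delta))
  attr(out, "residuals") <- res
  attr(out, "max_residual") <- max(abs(res))
  out
}

#' Classify a residue position's compatibility with a cross-linker
#'
#' Given per-model minimum inter-chain CA distances for one residue (e.g.
#' from an ab initio ensemble), computes the fraction of models in which
#' the equivalent cross-link span fits within the linker spacer, and calls
#' the position `strong` (fraction >= 0.5, the efficient ~60%-dimer
#' pattern), `absent` (<= 0.1, no dimerisation above background) or
#' `intermediate`.
#'
#' @param distances per-model minimum inter-chain CA distances, Angstrom.
#' @param linker a [cross_linker()].
#' @param conv a [caliper_convention()].
#' @param strong,absent category thresholds on the satisfied fraction.
#' @return An object of class `compatibility_call` with fields `linker`,
#'   `fraction` and `category`.
#' @export
classify_compatibility <- function(distances, linker,
                                   conv = caliper_convention(),
                                   strong = 0.5, absent = 0.1) {
  if (length(distances) == 0) stop("empty distance set")
  frac <- mean(ca_to_xlink(distances, conv) <= linker$spacer_ss)
  category <- if (frac >= strong) "strong"
              else if (frac <= absent) "absent" else "intermediate"
  structure(list(linker = linker$name, fraction = frac, category = category),
            class = "compatibility_call")
}

#' @export
print.compatibility_call <- function(x, ...) {
  cat(sprintf("compatibility with %s: %.3f of models satisfied (%s)\n",
              x$linker, x$fraction, x$category))
  invisible(x)
}

#' Minimum inter-trimer atom distance under a clash constraint
#'
#' Places a second trimer next to a fixed first one — both C3 axes kept
#' parallel to z, the membrane normal — and searches in-plane position and
#' spin of the mobile trimer for the placement minimising the distance
#' between the selected atoms of the two trimers, subject to no atom pair
#' approaching closer than `clash_radius`. This is the geometric test of
#' whether a cross-link could have formed *between* neighbouring trimers
#' rather than within one: surface-exposed residues can approach closely,
#' residues near the central axis cannot.
#'
#' The search is a deterministic polar scan: approach direction and mobile
#' spin on 5-degree grids (one C3 sector each), centre-to-centre separation
#' marched at 1 A and refined to 0.1 A at the best placement; the first
#' minimal placement in scan order wins ties.
#'
#' @param t1,t2 symmetric three-chain `trimer_structure`s, axes along z.
#' @param resno,elety the selected atom (present in all chains of both).
#' @param clash_radius hard-sphere rejection radius, Angstrom (default 3).
#' @param angle_step grid step for approach direction and spin, degrees.
#' @param d_step,refine_step coarse and fine separation steps, Angstrom.
#' @return List with `min_distance` (Angstrom, over all inter-trimer pairs
#'   of the selected atom) and `placement` (`phi`, `spin` in degrees and
#'   centre separation `d`).
#' @export
min_inter_trimer_distance <- function(t1, t2, resno, elety = "CA",
                                      clash_radius = 3.0, angle_step = 5,
                                      d_step = 1.0, refine_step = 0.1) {
  for (s in list(t1, t2)) {
    if (n_chains(s) != 3L) stop("both structures must be trimers")
    if (!any(s$atoms$resno == resno & s$atoms$elety == elety)) {
      stop("selected atom ", elety, "/", resno, " missing from a trimer")
    }
  }
  xyz1 <- as.matrix(t1$atoms[, c("x", "y", "z")])
  xyz2 <- as.matrix(t2$atoms[, c("x", "y", "z")])
  sel1 <- xyz1[t1$atoms$resno == resno & t1$atoms$elety == elety, , drop = FALSE]
  sel2_idx <- t2$atoms$resno == resno & t2$atoms$elety == elety
  c1 <- c(colMeans(xyz1[, 1:2]), 0)
  c2 <- c(colMeans(xyz2[, 1:2]), 0)
  xyz2c <- sweep(xyz2, 2, c2)   # mobile trimer about its own axis at origin
  r1max <- max(sqrt(rowSums(sweep(xyz1, 2, c1)[, 1:2]^2)))
  r2max <- max(sqrt(rowSums(xyz2c[, 1:2]^2)))
  d_hi <- r1max + r2max + clash_radius + d_step
  phis <- seq(0, 120 - angle_step, by = angle_step) * pi / 180
  spins <- seq(0, 120 - angle_step, by = angle_step) * pi / 180

  objective <- function(xyz2p) {
    sel2 <- xyz2p[sel2_idx, , drop = FALSE]
    min_cross_distance(sel1, sel2)
  }
  clash_free <- function(xyz2p) {
    min_cross_distance(xyz1, xyz2p) >= clash_radius
  }
  place <- function(rot2, phi, d) {
    offset <- c1 + d * c(cos(phi), sin(phi), 0)
    sweep(rot2, 2, offset, FUN = "+")
  }

  best <- NULL
  for (spin in spins) {
    rot2 <- rotate_coords(xyz2c, c(0, 0, 1), spin)
    for (phi in phis) {
      # march separation downward; minimal clash-free d is the contact point
      d <- d_hi
      d_free <- NA
      while (d >= 0) {
        if (clash_free(place(rot2, phi, d))) d_free <- d else break
        d <- d - d_step
      }
      if (is.na(d_free)) next
      obj <- objective(place(rot2, phi, d_free))
      if (is.null(best) || obj < best$min_distance) {
        best <- list(min_distance = obj,
                     placement = list(phi = phi * 180 / pi,
                                      spin = spin * 180 / pi, d = d_free))
      }
    }
  }
  if (is.null(best)) stop("no clash-free placement found on the search grid")
  # refine separation at the winning direction/spin
  rot2 <- rotate_coords(xyz2c, c(0, 0, 1), best$placement$spin * pi / 180)
  phi <- best$placement$phi * pi / 180
  d <- best$placement$d
  while (d - refine_step >= 0 &&
         clash_free(place(rot2, phi, d - refine_step))) {
    d <- d - refine_step
  }
  obj <- objective(place(rot2, phi, d))
  if (obj <= best$min_distance) {
    best$min_distance <- obj
    best$placement$d <- d
  }
  best$clash_radius <- clash_radius
  best
}
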