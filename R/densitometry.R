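# Gel lane densitometry: migration calibration against a protein ladder,
# lane profile extraction, baseline removal, band quantification with the
# percent-dimer statistic, and the accompanying ANOVA/Bonferroni group
# comparison.

#' Lane intensity profile
#'
#' @param position strictly increasing migration coordinates (arbitrary
#'   units, typically pixel rows).
#' @param intensity non-negative-going signal values, same length.
#' @param provenance free-text origin note (image lane bounds or CSV path).
#' @return An object of class `lane_profile`.
#' @export
lane_profile <- function(position, intensity, provenance = "") {
  if (length(position) != length(intensity)) stop("length mismatch")
  if (any(diff(position) <= 0)) stop("`position` must be strictly increasing")
  if (any(!is.finite(intensity))) stop("non-finite intensities")
  structure(list(position = as.numeric(position),
                 intensity = as.numeric(intensity),
                 provenance = provenance),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat("lane_profile:", length(x$position), "samples, total signal",
      sprintf("%.4g\n", pracma::trapz(x$position, x$intensity)))
  invisible(x)
}

#' Log-linear migration calibration from a ladder
#'
#' Least-squares fit of `log10(MW kD) = a + b * position` to ladder band
#' positions, the standard molecular-weight mapping for SDS-PAGE.
#'
#' @param position ladder band migration positions (>= 2, distinct).
#' @param mw matching molecular weights, kD; must vary monotonically with
#'   position.
#' @return An object of class `ladder_calibration` with coefficients `a`,
#'   `b`, fit `r_squared`, and mapping functions `mw_at(position)` /
#'   `position_at(mw)`.
#' @export
calibrate_migration <- function(position, mw) {
  if (length(position) < 2) stop("need at least two ladder bands")
  if (length(position) != length(mw)) stop("length mismatch")
  if (anyDuplicated(position)) stop("duplicate ladder positions")
  ord <- order(position)
  m <- mw[ord]
  if (any(diff(m) >= 0) && any(diff(m) <= 0)) {
    stop("ladder is not monotone in migration position")
  }
  fit <- stats::lm(log10(mw) ~ position)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  r2 <- if (length(position) == 2) 1 else
    suppressWarnings(summary(fit)$r.squared)   # warns on noise-free ladders
  structure(list(a = a, b = b, r_squared = r2,
                 mw_at = function(p) 10^(a + b * p),
                 position_at = function(w) (log10(w) - a) / b),
            class = "ladder_calibration")
}

#' Extract a lane profile from a grayscale image
#'
#' Sums pixel intensity across the lane's columns, row by row, giving one
#' intensity value per migration position. Chemiluminescence images are
#' signal-bright; for stained gels (dark bands on light background) set
#' `invert = TRUE` to flip the polarity.
#'
#' @param image numeric matrix, rows = migration direction.
#' @param cols integer column range of the lane.
#' @param invert flip polarity (`max(image) - image`) before summing.
#' @return A [lane_profile()] with positions = row indices.
#' @export
extract_lane_profile <- function(image, cols, invert = FALSE) {
  image <- as.matrix(image)
  if (length(cols) == 0) stop("empty lane bounds")
  if (min(cols) < 1 || max(cols) > ncol(image)) {
    stop("lane bounds outside the image")
  }
  if (invert) image <- max(image) - image
  lane_profile(seq_len(nrow(image)),
               rowSums(image[, cols, drop = FALSE]),
               provenance = sprintf("image columns %d-%d", min(cols), max(cols)))
}

#' Remove a slowly varying baseline from a lane profile
#'
#' Morphological opening: a rolling minimum followed by a rolling maximum
#' over the same window. The opening passes broad trends (it reproduces a
#' linear drift exactly) while removing features narrower than the window,
#' so subtracting it leaves the bands on a flat floor. Output is clipped
#' at zero.
#'
#' The profile is first smoothed with a short rolling mean (`smooth`
#' samples, area-preserving) so that pixel noise does not drag the
#' rolling minimum below the true baseline; the smoothed trace is what is
#' quantified downstream.
#'
#' @param profile a [lane_profile()].
#' @param window baseline window in samples (odd; default 25% of the lane
#'   length). Must be narrower than the profile and wider than the bands.
#' @param smooth rolling-mean denoising window in samples (odd; default
#'   2% of the lane length, minimum 1 = no smoothing). Keep well below
#'   the band width.
#' @return A baseline-subtracted [lane_profile()] of the smoothed trace;
#'   the removed baseline is attached as attribute `"baseline"`.
#' @export
subtract_baseline <- function(profile, window = NULL, smooth = NULL) {
  n <- length(profile$intensity)
  if (is.null(window)) window <- max(3L, round(0.25 * n))
  window <- as.integer(window)
  if (window %% 2 == 0) window <- window + 1L
  if (window < 3) stop("`window` must cover at least 3 samples")
  if (window > n) stop("`window` larger than the profile")
  if (is.null(smooth)) smooth <- max(1L, round(0.02 * n))
  smooth <- as.integer(smooth)
  if (smooth %% 2 == 0) smooth <- smooth + 1L
  x <- if (smooth > 1) {
    zoo::rollapply(profile$intensity, smooth, mean,
                   partial = TRUE, align = "center")
  } else profile$intensity
  eroded <- zoo::rollapply(x, window, min, partial = TRUE, align = "center")
  baseline <- zoo::rollapply(eroded, window, max,
                             partial = TRUE, align = "center")
  out <- pmax(0, x - baseline)
  res <- lane_profile(profile$position, out, profile$provenance)
  attr(res, "baseline") <- baseline
  res
}

#' Default molecular-weight windows for receptor bands
#'
#' Monomer ~55 kD, dimer ~100-120 kD (the window defining the
#' percent-dimer statistic), trimer ~160-170 kD.
#'
#' @return Named list of `c(lo, hi)` kD ranges.
#' @export
default_band_windows <- function() {
  list(monomer = c(45, 65), dimer = c(100, 120), trimer = c(150, 180))
}

#' Quantify bands and the percent-dimer statistic
#'
#' Integrates the (baseline-subtracted) lane intensity over each
#' molecular-weight window mapped to migration positions by the ladder
#' calibration (trapezoidal rule, no peak fitting), plus the whole-lane
#' total. `percent_dimer` is 100 times the dimer-window integral divided
#' by the whole-lane total — the fraction of subunit signal that has
#' dimerised.
#'
#' @param profile a [lane_profile()].
#' @param calibration a [calibrate_migration()] result.
#' @param windows named list of kD ranges (default
#'   [default_band_windows()]).
#' @return An object of class `band_quantification`: `bands` (named
#'   integrals), `total`, `percent_dimer`.
#' @export
quantify_bands <- function(profile, calibration,
                           windows = default_band_windows()) {
  pos <- profile$position
  dens <- profile$intensity
  band_integral <- function(w, name) {
    p <- sort(calibration$position_at(w))
    if (p[1] < min(pos) || p[2] > max(pos)) {
      stop("window '", name, "' maps outside the calibrated lane")
    }
    keep <- pos >= p[1] & pos <= p[2]
    if (sum(keep) < 2) return(0)
    pracma::trapz(pos[keep], dens[keep])
  }
  bands <- vapply(names(windows),
                  function(nm) band_integral(windows[[nm]], nm), numeric(1))
  total <- pracma::trapz(pos, dens)
  pd <- if (total > 0) 100 * bands[["dimer"]] / total else 0
  structure(list(bands = bands, total = total, percent_dimer = pd),
            class = "band_quantification")
}

#' @export
print.band_quantification <- function(x, ...) {
  cat(sprintf("bands: %s; total %.4g; percent dimer %.1f%%\n",
              paste(sprintf("%s %.4g", names(x$bands), x$bands),
                    collapse = ", "),
              x$total, x$percent_dimer))
  invisible(x)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post-tests
#'
#' Standard one-way ANOVA across groups of percent-dimer replicates,
#' followed by all-pairs pooled-variance t-tests whose p-values are
#' multiplied by the number of comparisons `k*(k-1)/2` (capped at 1) —
#' the Bonferroni post-test family used for per-figure mutant/linker
#' comparisons.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return List with `F`, `p`, `df` (between/within), and `pairwise`
#'   (data frame: group1, group2, t, p_raw, p_adj).
#' @export
anova_bonferroni <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs n >= 2 replicates")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                  levels = names(groups))
  fit <- stats::aov(value ~ group)
  tab <- summary(fit)[[1]]
  Fval <- tab[["F value"]][1]
  pval <- tab[["Pr(>F)"]][1]
  if (is.nan(Fval)) { Fval <- 0; pval <- 1 }      # all observations identical
  if (is.infinite(Fval)) pval <- 0                # zero within-group variance
  mse <- tab[["Mean Sq"]][2]
  df_w <- tab[["Df"]][2]
  k <- length(groups)
  cmb <- utils::combn(names(groups), 2)
  m <- ncol(cmb)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    g1 <- groups[[cmb[1, i]]]; g2 <- groups[[cmb[2, i]]]
    tstat <- (mean(g1) - mean(g2)) /
      sqrt(mse * (1 / length(g1) + 1 / length(g2)))
    p_raw <- 2 * stats::pt(-abs(tstat), df_w)
    data.frame(group1 = cmb[1, i], group2 = cmb[2, i], t = tstat,
               p_raw = p_raw, p_adj = min(1, p_raw * m),
               stringsAsFactors = FALSE)
  }))
  list(F = Fval, p = pval, df = c(between = k - 1, within = df_w),
       pairwise = pw)
}

#' Published percent-dimer reference values
#'
#' Experimentally measured percent-dimer values for receptor cysteine
#' mutants and cross-linkers, shipped as a fixture for annotating reports.
#' These are wet-lab quantities: they contextualise computed results but
#' are never themselves computed by this package.
#'
#' @return Data frame with columns `construct`, `condition`,
#'   `percent_dimer`, `sem`, `n`.
#' @export
experimental_percent_dimer <- function() {
  path <- system.file("extdata", "experimental_percent_dimer.csv",
                      package = "xlcaliper", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
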