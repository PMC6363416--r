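# Anisotropic elastic-network normal-mode analysis over CA positions, and
# the residue-pair distance changes carried by low-frequency modes.

#' Elastic network model over CA positions
#'
#' @param coords `N x 3` CA coordinate matrix, Angstrom, `N >= 2`.
#' @param cutoff interaction radius, Angstrom (default 15).
#' @param gamma uniform spring constant, arbitrary units (default 1).
#' @return An object of class `enm_model`.
#' @export
enm_model <- function(coords, cutoff = 15, gamma = 1) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) < 2) {
    stop("`coords` must be an N x 3 matrix with N >= 2")
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  if (cutoff <= 0 || gamma <= 0) stop("`cutoff` and `gamma` must be positive")
  structure(list(coords = coords, cutoff = cutoff, gamma = gamma),
            class = "enm_model")
}

#' Anisotropic-network Hessian
#'
#' Assembles the `3N x 3N` Hessian of the uniform-spring anisotropic
#' network model: for each atom pair within the cutoff, the off-diagonal
#' 3x3 superelement is `-gamma * r_hat %*% t(r_hat)`; diagonal
#' superelements enforce zero row sums (translation invariance).
#'
#' @param model an [enm_model()].
#' @return Symmetric `3N x 3N` matrix. Warns (attribute
#'   `"disconnected" = TRUE`) if some atom has no neighbour within the
#'   cutoff; coincident atom pairs are an error.
#' @export
build_hessian <- function(model) {
  stopifnot(inherits(model, "enm_model"))
  X <- model$coords
  N <- nrow(X)
  D <- as.matrix(stats::dist(X))
  if (any(D[upper.tri(D)] < 1e-8)) stop("coincident atoms in the network")
  H <- matrix(0, 3 * N, 3 * N)
  connected <- rep(FALSE, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (D[i, j] > model$cutoff) next
      connected[c(i, j)] <- TRUE
      r <- (X[j, ] - X[i, ]) / D[i, j]
      block <- -model$gamma * tcrossprod(r)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] + block
      H[jj, ii] <- H[jj, ii] + block
      H[ii, ii] <- H[ii, ii] - block
      H[jj, jj] <- H[jj, jj] - block
    }
  }
  if (!all(connected)) {
    warning("network is disconnected: some atoms have no neighbour within the cutoff")
    attr(H, "disconnected") <- TRUE
  }
  H
}

#' Diagonalise an elastic-network Hessian
#'
#' @param hessian symmetric `3N x 3N` matrix from [build_hessian()].
#' @param zero_tol_factor modes with eigenvalue below
#'   `zero_tol_factor * max(eigenvalue)` are flagged rigid-body (3
#'   translations + 3 rotations for a connected, non-collinear network).
#' @return An object of class `mode_set`: `values` (ascending, clipped at
#'   0 within tolerance), `vectors` (orthonormal columns, sign convention:
#'   first non-negligible component positive), `n_zero`. "Mode 1" of the
#'   analysis is the first non-rigid column, `vectors[, n_zero + 1]`.
#' @export
solve_modes <- function(hessian, zero_tol_factor = 1e-8) {
  if (max(abs(hessian - t(hessian))) > 1e-8) stop("hessian must be symmetric")
  e <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  tol <- zero_tol_factor * max(abs(values))
  values[abs(values) < tol] <- 0
  if (min(values) < -1e-8 * max(abs(values))) {
    stop("hessian is not positive semi-definite")
  }
  for (k in seq_len(ncol(vectors))) {  # deterministic sign convention
    i <- which(abs(vectors[, k]) > 1e-8)[1]
    if (!is.na(i) && vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  structure(list(values = values, vectors = vectors,
                 n_zero = sum(values == 0)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  nr <- length(x$values) - x$n_zero
  cat("mode_set:", x$n_zero, "rigid-body modes,", nr, "internal modes;",
      "lowest internal eigenvalue",
      if (nr > 0) sprintf("%.4g\n", x$values[x$n_zero + 1]) else "NA\n")
  invisible(x)
}

.mode_vector <- function(modeset, mode, allow_rigid = FALSE) {
  idx <- if (allow_rigid) mode else modeset$n_zero + mode
  if (mode < 1 || idx > length(modeset$values)) stop("invalid mode index")
  if (!allow_rigid && modeset$n_zero + mode <= modeset$n_zero) {
    stop("rigid-body mode requested without allow_rigid")
  }
  modeset$vectors[, idx]
}

#' Displace coordinates along a normal mode
#'
#' @param model an [enm_model()].
#' @param modeset a [solve_modes()] result for the model.
#' @param mode internal-mode index (1 = lowest non-rigid mode).
#' @param amplitude displacement amplitude, Angstrom times the unit-norm
#'   mode vector.
#' @param allow_rigid interpret `mode` as an absolute column index,
#'   permitting rigid-body modes.
#' @return `N x 3` displaced coordinate matrix.
#' @export
displace_along_mode <- function(model, modeset, mode, amplitude,
                                allow_rigid = FALSE) {
  v <- .mode_vector(modeset, mode, allow_rigid)
  model$coords + amplitude * matrix(v, ncol = 3, byrow = TRUE)
}

#' Largest pair-distance reduction along a mode
#'
#' Sweeps the mode amplitude over a symmetric grid and reports the largest
#' reduction of the distance between two atoms relative to the undisplaced
#' structure — the computation behind asking whether a low-frequency
#' collective motion can transiently bring two inter-subunit cysteines
#' within cross-linking range.
#'
#' @param model an [enm_model()].
#' @param modeset a [solve_modes()] result.
#' @param mode internal-mode index (1 = lowest non-rigid).
#' @param pair length-2 atom indices into the model coordinates.
#' @param amplitude_max sweep bound (> 0); grid is `n_grid` uniform points
#'   on `[-amplitude_max, amplitude_max]`.
#' @param n_grid odd number of sweep points (default 201).
#' @return List with `max_reduction` (Angstrom, >= 0), `amplitude_at_max`,
#'   and `d0` (undisplaced pair distance).
#' @export
pair_distance_delta_along_mode <- function(model, modeset, mode, pair,
                                           amplitude_max, n_grid = 201) {
  if (amplitude_max <= 0) stop("`amplitude_max` must be positive")
  if (length(pair) != 2 || any(pair < 1) || any(pair > nrow(model$coords))) {
    stop("`pair` must index two atoms of the model")
  }
  v <- matrix(.mode_vector(modeset, mode), ncol = 3, byrow = TRUE)
  x0 <- model$coords[pair[1], ]; y0 <- model$coords[pair[2], ]
  dx <- v[pair[1], ]; dy <- v[pair[2], ]
  d0 <- vec_dist(x0, y0)
  amps <- seq(-amplitude_max, amplitude_max, length.out = n_grid)
  d <- vapply(amps, function(a) vec_dist(x0 + a * dx, y0 + a * dy),
              numeric(1))
  i <- which.min(d)
  list(max_reduction = max(0, d0 - d[i]), amplitude_at_max = amps[i], d0 = d0)
}

#' Default amplitude cap for mode sweeps
#'
#' The amplitude at which the most-displaced atom of a unit-norm mode
#' moves `max_disp` Angstrom (default 5), a sensible sweep bound for
#' low-frequency collective modes.
#'
#' @param modeset a [solve_modes()] result.
#' @param mode internal-mode index.
#' @param max_disp largest allowed single-atom displacement, Angstrom.
#' @return Positive amplitude.
#' @export
amplitude_cap <- function(modeset, mode, max_disp = 5) {
  v <- matrix(.mode_vector(modeset, mode), ncol = 3, byrow = TRUE)
  max_disp / max(sqrt(rowSums(v^2)))
}
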