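# Analysis layer for scored structural-model ensembles of the flexible
# intracellular region: score filtering, Kabsch superposition, pairwise
# RMSD, hierarchical clustering, per-residue inter-subunit distance
# distributions and cross-link constraint satisfaction.

#' Scored model ensemble container
#'
#' Holds CA coordinates of a fixed residue selection (across the three
#' chains) for every model of an ensemble, together with Rosetta-like
#' scalar scores (lower = better).
#'
#' @param coords numeric array `n_atoms x 3 x n_models`, Angstrom.
#' @param ids character model identifiers (unique).
#' @param scores numeric scores, one per model.
#' @param selection data frame with columns `chain` and `resno`, one row
#'   per atom of the selection, shared by every model.
#' @return An object of class `model_ensemble`.
#' @export
model_ensemble <- function(coords, ids, scores, selection) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("`coords` must be an n_atoms x 3 x n_models array")
  }
  n_models <- dim(coords)[3]
  if (n_models < 1) stop("ensemble must contain at least one model")
  if (length(ids) != n_models || length(scores) != n_models) {
    stop("`ids`/`scores` length must equal the number of models")
  }
  if (anyDuplicated(ids)) stop("model ids must be unique")
  if (!all(c("chain", "resno") %in% names(selection)) ||
      nrow(selection) != dim(coords)[1]) {
    stop("`selection` must have columns chain, resno with one row per atom")
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  structure(list(coords = coords, ids = as.character(ids),
                 scores = as.numeric(scores), selection = selection),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("model_ensemble:", n_models(x), "models,", dim(x$coords)[1],
      "selected atoms; score range",
      sprintf("[%.2f, %.2f]\n", min(x$scores), max(x$scores)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param x a `model_ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(x) dim(x$coords)[3]

#' Keep the top-scoring fraction of an ensemble
#'
#' Retains the `floor(frac * N)` lowest-score models (at least one),
#' ordered by score with stable ties broken by model id — the "top 10%"
#' filter applied before clustering a 20,000-model run keeps 2,000 models.
#'
#' @param ensemble a [model_ensemble()].
#' @param frac fraction in (0, 1].
#' @return A `model_ensemble` of the retained models, best score first.
#' @export
top_fraction <- function(ensemble, frac) {
  if (length(frac) != 1 || frac <= 0 || frac > 1) {
    stop("`frac` must lie in (0, 1]")
  }
  n <- n_models(ensemble)
  k <- max(1L, floor(frac * n))
  ord <- order(ensemble$scores, ensemble$ids)[seq_len(k)]
  model_ensemble(ensemble$coords[, , ord, drop = FALSE],
                 ensemble$ids[ord], ensemble$scores[ord], ensemble$selection)
}

#' Least-RMSD rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of the
#' rows of `B` onto the rows of `A`.
#'
#' @param A,B `n x 3` coordinate matrices, `n >= 3`, matching rows.
#' @return List with `rotation` (3x3, determinant +1), `translation`
#'   (length 3) and `rmsd`; the fit of B onto A is
#'   `B %*% rotation + rep(translation, each = n)`.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3) {
    stop("`A` and `B` must be matching n x 3 matrices")
  }
  if (nrow(A) < 3) stop("need at least 3 atoms for superposition")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  H <- crossprod(Bc, Ac)                 # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  Rcol <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # column-vector rotation
  rotation <- t(Rcol)                    # row-vector convention
  fit <- Bc %*% rotation
  rmsd <- sqrt(mean(rowSums((fit - Ac)^2)))
  list(rotation = rotation, translation = cA - cB %*% rotation, rmsd = rmsd)
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Entry (i, j) is the Kabsch RMSD of model j superposed onto model i over
#' the full stored selection (no mass weighting).
#'
#' @param ensemble a [model_ensemble()] with at least two models.
#' @return Symmetric matrix (Angstrom) with zero diagonal, dimnames = ids.
#' @export
pairwise_rmsd_matrix <- function(ensemble) {
  n <- n_models(ensemble)
  if (n < 2) stop("need at least two models")
  M <- matrix(0, n, n, dimnames = list(ensemble$ids, ensemble$ids))
  # precentre once; RMSD needs only the centred coordinates
  centred <- lapply(seq_len(n), function(i) {
    x <- ensemble$coords[, , i]
    sweep(x, 2, colMeans(x))
  })
  for (i in seq_len(n - 1)) {
    Ac <- centred[[i]]
    for (j in (i + 1):n) {
      Bc <- centred[[j]]
      s <- svd(crossprod(Bc, Ac))
      dsign <- sign(det(s$v %*% t(s$u)))
      # rmsd via trace identity: ||A||^2 + ||B||^2 - 2*sum(singular values)
      sv <- s$d; sv[3] <- sv[3] * dsign
      msd <- (sum(Ac^2) + sum(Bc^2) - 2 * sum(sv)) / nrow(Ac)
      M[i, j] <- M[j, i] <- sqrt(max(0, msd))
    }
  }
  M
}

#' Deterministic agglomerative clustering of an RMSD matrix
#'
#' Hierarchical clustering (via [stats::hclust()]) of a pairwise RMSD
#' matrix, cut either to `k` clusters or at dendrogram height `h`.
#'
#' @param mat symmetric distance matrix with zero diagonal.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @param k number of clusters, or
#' @param h height cutoff (exactly one of `k`, `h` must be given).
#' @return Integer cluster labels (1-based, in order of first appearance),
#'   with the `hclust` tree attached as attribute `"tree"`.
#' @export
hier_cluster <- function(mat, linkage = c("average", "complete", "single"),
                         k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || max(abs(mat - t(mat))) > 1e-8) {
    stop("`mat` must be square and symmetric")
  }
  if (is.null(k) == is.null(h)) stop("give exactly one of `k` or `h`")
  if (!is.null(k) && k > nrow(mat)) stop("`k` exceeds the number of models")
  tree <- stats::hclust(stats::as.dist(mat), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(tree, k = k)
            else stats::cutree(tree, h = h)
  structure(as.integer(labels), names = rownames(mat), tree = tree)
}

#' Best-scoring representatives of the largest clusters
#'
#' Sorts clusters by size (ties: the cluster containing the lower minimum
#' score first) and returns, for each of the `k_largest` largest, the id
#' of its lowest-score member — the models one would visualise from a
#' clustered ensemble.
#'
#' @param labels cluster labels aligned with `scores`/`ids`.
#' @param scores model scores (lower = better).
#' @param ids model identifiers.
#' @param k_largest how many clusters to report (> 0); fewer are returned
#'   if fewer clusters exist.
#' @return Character vector of representative model ids, largest cluster
#'   first.
#' @export
cluster_representatives <- function(labels, scores, ids, k_largest = 10) {
  if (k_largest <= 0) stop("`k_largest` must be positive")
  if (length(labels) != length(scores) || length(labels) != length(ids)) {
    stop("`labels`, `scores` and `ids` must be aligned")
  }
  cl <- unique(labels)
  size <- vapply(cl, function(c) sum(labels == c), integer(1))
  minsc <- vapply(cl, function(c) min(scores[labels == c]), numeric(1))
  ord <- order(-size, minsc)
  take <- cl[ord][seq_len(min(k_largest, length(cl)))]
  vapply(take, function(c) {
    members <- which(labels == c)
    best <- members[order(scores[members], ids[members])][1]
    ids[best]
  }, character(1))
}

# Per-model minimum over the three chain-pair CA distances for one residue.
.min_interchain_per_model <- function(ensemble, resno) {
  sel <- ensemble$selection
  chains <- unique(sel$chain)
  if (length(chains) != 3) stop("ensemble selection must span three chains")
  idx <- vapply(chains, function(ch) {
    i <- which(sel$chain == ch & sel$resno == resno)
    if (!length(i)) stop("residue ", resno, " outside the ensemble selection")
    i[1]
  }, integer(1))
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3))
  atom_xyz <- function(i) {   # 3 x n_models matrix for one atom
    matrix(ensemble$coords[i, , , drop = FALSE], nrow = 3)
  }
  d <- sapply(seq_len(nrow(pairs)), function(p) {
    sqrt(colSums((atom_xyz(idx[pairs[p, 1]]) - atom_xyz(idx[pairs[p, 2]]))^2))
  })
  d <- matrix(d, ncol = 3)
  apply(d, 1, min)
}

#' Inter-subunit distance distribution for one residue
#'
#' For each model, takes the minimum over the three chain-pair CA
#' distances of the selected residue, and summarises the ensemble of
#' minima: overall minimum, 5/50/95 percentiles (linear interpolation) and
#' a fixed-width histogram.
#'
#' @param ensemble a [model_ensemble()].
#' @param resno residue number within the selection.
#' @param bin_width histogram bin width, Angstrom (default 0.5).
#' @return An object of class `distance_distribution` with fields `resno`,
#'   `values`, `min`, `percentiles` (p5/p50/p95), `breaks`, `counts`.
#' @export
pair_distance_distribution <- function(ensemble, resno, bin_width = 0.5) {
  values <- .min_interchain_per_model(ensemble, resno)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  structure(list(resno = resno, values = values, min = min(values),
                 percentiles = stats::quantile(values, c(0.05, 0.5, 0.95),
                                               names = FALSE),
                 breaks = breaks, counts = counts),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "residue %d inter-subunit CA distance over %d models: min %.2f A, p5/p50/p95 = %.2f/%.2f/%.2f A\n",
    x$resno, length(x$values), x$min, x$percentiles[1], x$percentiles[2],
    x$percentiles[3]))
  invisible(x)
}

#' Fraction of models satisfying a distance constraint
#'
#' The satisfaction analogue of a harmonic CA-CA modelling restraint: the
#' fraction of models whose minimum inter-chain CA distance at `resno` is
#' at most `d_ca_max`.
#'
#' @param ensemble a [model_ensemble()].
#' @param resno residue number within the selection.
#' @param d_ca_max distance ceiling, Angstrom.
#' @return Fraction in \[0, 1\].
#' @export
constraint_satisfaction <- function(ensemble, resno, d_ca_max) {
  mean(.min_interchain_per_model(ensemble, resno) <= d_ca_max)
}

#' Write an ensemble as packed coordinate + score tables
#'
#' Per-file formats do not scale to 20,000-model runs; the on-disk form is
#' a long coordinate CSV (`model`, `chain`, `resno`, `x`, `y`, `z`) plus a
#' score CSV (`model`, `score`).
#'
#' @param ensemble a [model_ensemble()].
#' @param coords_csv,scores_csv output paths.
#' @return `coords_csv`, invisibly.
#' @export
write_ensemble <- function(ensemble, coords_csv, scores_csv) {
  n <- n_models(ensemble)
  na <- dim(ensemble$coords)[1]
  tab <- data.frame(
    model = rep(ensemble$ids, each = na),
    chain = rep(ensemble$selection$chain, times = n),
    resno = rep(ensemble$selection$resno, times = n),
    x = as.vector(ensemble$coords[, 1, ]),
    y = as.vector(ensemble$coords[, 2, ]),
    z = as.vector(ensemble$coords[, 3, ]))
  utils::write.csv(tab, coords_csv, row.names = FALSE)
  utils::write.csv(data.frame(model = ensemble$ids, score = ensemble$scores),
                   scores_csv, row.names = FALSE)
  invisible(coords_csv)
}

#' Read an ensemble from packed coordinate + score tables
#'
#' @param coords_csv,scores_csv paths written by [write_ensemble()].
#' @return A [model_ensemble()]; model order follows the score table.
#' @export
read_ensemble <- function(coords_csv, scores_csv) {
  tab <- utils::read.csv(coords_csv, stringsAsFactors = FALSE)
  sc <- utils::read.csv(scores_csv, stringsAsFactors = FALSE)
  ids <- as.character(sc$model)
  first <- tab[tab$model == ids[1], ]
  selection <- data.frame(chain = first$chain, resno = first$resno,
                          stringsAsFactors = FALSE)
  na <- nrow(selection)
  coords <- array(NA_real_, c(na, 3, length(ids)))
  tab <- tab[order(match(as.character(tab$model), ids)), ]
  if (nrow(tab) != na * length(ids)) stop("coordinate table is ragged")
  coords[, 1, ] <- tab$x; coords[, 2, ] <- tab$y; coords[, 3, ] <- tab$z
  model_ensemble(coords, ids, sc$score, selection)
}
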