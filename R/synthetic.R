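# Seeded generators for every input the pipeline consumes, with ground
# truth recorded alongside: C3 helix bundles with known inter-chain
# distances, scored model ensembles with planted cluster structure and
# planted pair-distance distributions, and rendered gel images with
# planted band fractions. Each generator is a pure function of its
# arguments plus the seed.

#' Synthetic C3 transmembrane-like helix bundle
#'
#' Builds one ideal alpha-helix (optionally with a flexible intracellular
#' tail) whose own axis runs parallel to z at distance `ring_radius` from
#' the origin, then C3-symmetrises it about z. For an atom at distance `r`
#' from the C3 axis, the three inter-chain copies sit on an equilateral
#' triangle, so the inter-chain distance is exactly `sqrt(3)` times `r` — the
#' analytic truth recorded per residue.
#'
#' @param n_res helical residues per chain (>= 5).
#' @param ring_radius distance of the helix axis from the C3 axis, Angstrom.
#' @param helix_radius radius of the CA helix about its own axis (default
#'   2.3 A; set 0 for a straight rod at exactly `ring_radius`).
#' @param rise helical rise per residue, Angstrom (default 1.5).
#' @param twist helical twist per residue, degrees (default 100).
#' @param tail_len residues of flexible tail appended below the helix,
#'   drifting toward the C3 axis.
#' @param tail_spread isotropic positional noise on tail atoms, Angstrom.
#' @param seed integer seed (used only for the tail noise).
#' @return List with `structure` (a symmetric [trimer_structure()], CA
#'   atoms only, chains A/B/C) and `truth` (data frame: `resno`,
#'   `ring_radius`, `interchain_distance = ring_radius * sqrt(3)`).
#' @export
make_c3_bundle <- function(n_res = 20, ring_radius = 10, helix_radius = 2.3,
                           rise = 1.5, twist = 100, tail_len = 0,
                           tail_spread = 1.0, seed = 1) {
  if (n_res < 5) stop("`n_res` must be >= 5")
  if (ring_radius <= 0) stop("`ring_radius` must be positive")
  i <- seq_len(n_res)
  ang <- (i - 1) * twist * pi / 180
  xyz <- cbind(ring_radius + helix_radius * cos(ang),
               helix_radius * sin(ang),
               (i - 1) * rise)
  if (tail_len > 0) {
    withr::with_seed(as.integer(seed), {
      # tail drifts from the helix base toward the C3 axis, with spread
      frac <- seq_len(tail_len) / (tail_len + 1)
      base <- xyz[1, ]
      tail <- cbind(base[1] * (1 - frac), base[2] * (1 - frac),
                    base[3] - 1.5 * seq_len(tail_len))
      tail <- tail + matrix(stats::rnorm(3 * tail_len, sd = tail_spread),
                            ncol = 3)
    })
    xyz <- rbind(tail[rev(seq_len(tail_len)), , drop = FALSE], xyz)
  }
  n_tot <- nrow(xyz)
  atoms <- data.frame(chain = "A", resno = seq_len(n_tot), resid = "GLY",
                      elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  protomer <- trimer_structure(atoms)
  tri <- symmetrize_c3(protomer)
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  list(structure = tri,
       truth = data.frame(resno = seq_len(n_tot), ring_radius = r,
                          interchain_distance = r * sqrt(3)))
}

#' Synthetic scored model ensemble with planted structure
#'
#' Emulates the post-hoc analysis substrate of an ab initio modelling run:
#' `n_models` models of a three-chain CA selection, drawn around
#' `n_clusters` well-separated reference conformations (cluster labels are
#' the ground truth), with scores equal to each model's deviation from its
#' cluster centre plus noise (so score correlates with model quality), and
#' optionally one residue whose minimum inter-chain distance is planted
#' per model by drawing from a Gamma distribution and placing the three
#' chain copies on an exact C3 ring of circumradius `d / sqrt(3)`.
#'
#' @param n_models models to generate (default 2000, the scale of a
#'   filtered 20,000-model run).
#' @param resnos residue numbers of the per-chain selection.
#' @param n_clusters planted conformations (>= 1).
#' @param cluster_scale spatial extent of each cluster-centre conformation,
#'   Angstrom (controls between-cluster RMSD).
#' @param spread within-cluster isotropic noise, Angstrom.
#' @param planted_resno residue receiving a planted inter-chain distance
#'   distribution, or `NULL`.
#' @param planted_shape,planted_scale Gamma parameters of the planted
#'   minimum inter-chain distance (defaults mean 20 A).
#' @param score_noise_sd score noise on top of the quality term.
#' @param seed integer seed.
#' @return List with `ensemble` (a [model_ensemble()]) and `truth` (list:
#'   `labels`, `planted_distances`, `centers`, `best_ids` — lowest-score
#'   model id per cluster).
#' @export
make_ensemble <- function(n_models = 2000, resnos = 10:26, n_clusters = 2,
                          cluster_scale = 8, spread = 0.5,
                          planted_resno = NULL, planted_shape = 40,
                          planted_scale = 0.5, score_noise_sd = 0.5,
                          seed = 1) {
  if (n_models < 1 || n_clusters < 1) stop("counts must be >= 1")
  if (spread <= 0) stop("`spread` must be positive")
  n_res <- length(resnos)
  chains <- c("A", "B", "C")
  selection <- data.frame(chain = rep(chains, each = n_res),
                          resno = rep(resnos, 3), stringsAsFactors = FALSE)
  na <- nrow(selection)
  planted_idx <- if (!is.null(planted_resno)) {
    if (!planted_resno %in% resnos) stop("`planted_resno` not in selection")
    which(selection$resno == planted_resno)   # one atom per chain
  } else integer(0)
  withr::with_seed(as.integer(seed), {
    # cluster centres: independent random protomer conformations,
    # C3-replicated so each model keeps a symmetric three-chain layout
    centers <- lapply(seq_len(n_clusters), function(c) {
      prot <- matrix(stats::rnorm(3 * n_res, sd = cluster_scale), ncol = 3)
      prot[, 1] <- prot[, 1] + 3 * cluster_scale   # keep off the C3 axis
      do.call(rbind, lapply(0:2, function(k) {
        rotate_coords(prot, c(0, 0, 1), k * 2 * pi / 3)
      }))
    })
    labels <- rep_len(seq_len(n_clusters), n_models)
    coords <- array(NA_real_, c(na, 3, n_models))
    for (m in seq_len(n_models)) {
      coords[, , m] <- centers[[labels[m]]] +
        matrix(stats::rnorm(3 * na, sd = spread), ncol = 3)
    }
    # planted draws consumed after the coordinate noise, so two runs that
    # share a seed but change the planted family keep identical
    # conformational noise everywhere else
    planted <- if (length(planted_idx)) {
      stats::rgamma(n_models, shape = planted_shape, scale = planted_scale)
    } else numeric(0)
    quality <- numeric(n_models)
    for (m in seq_len(n_models)) {
      if (length(planted_idx)) {
        # exact C3 ring of circumradius d/sqrt(3): all three pair
        # distances equal the planted minimum d
        rr <- planted[m] / sqrt(3)
        zh <- mean(centers[[labels[m]]][planted_idx, 3])
        ang <- 2 * pi * (0:2) / 3
        coords[planted_idx, , m] <- cbind(rr * cos(ang), rr * sin(ang), zh)
      }
      quality[m] <- sqrt(mean((coords[, , m] - centers[[labels[m]]])^2))
    }
    scores <- quality + stats::rnorm(n_models, sd = score_noise_sd)
  })
  ids <- sprintf("model_%05d", seq_len(n_models))
  ens <- model_ensemble(coords, ids, scores, selection)
  best_ids <- vapply(seq_len(n_clusters), function(c) {
    members <- which(labels == c)
    ids[members[which.min(scores[members])]]
  }, character(1))
  list(ensemble = ens,
       truth = list(labels = labels, planted_distances = planted,
                    centers = centers, best_ids = best_ids))
}

#' Default gel migration mapping
#'
#' `log10(MW kD) = a + b * row` spanning ~320 kD at the top of the lane to
#' ~30 kD at the bottom over `n_rows` rows.
#'
#' @param n_rows lane length in rows.
#' @return Named numeric `c(a, b)`.
#' @export
default_gel_mapping <- function(n_rows = 1000) {
  c(a = log10(320), b = (log10(30) - log10(320)) / n_rows)
}

#' Synthetic Western-blot style gel image with known band fractions
#'
#' Renders one lane per element of `fractions`: Gaussian bands at the
#' monomer/dimer/trimer molecular weights (55/110/165 kD) positioned by
#' the inverse log-linear migration mapping, with band areas proportional
#' to the planted subunit-signal fractions, plus optional linear baseline
#' drift and white pixel noise. A ladder table (band position vs kD) is
#' produced from the same mapping.
#'
#' @param fractions list of per-lane named vectors
#'   `c(monomer=, dimer=, trimer=)` summing to 1 (e.g. a `band_fractions`
#'   object via `unlist`).
#' @param total_signal integrated subunit signal per lane (profile units).
#' @param band_sigma_kd band width as a molecular-weight sigma, kD
#'   (default 2.5).
#' @param drift_amp linear baseline drift at the bottom of the lane, as a
#'   fraction of the tallest band peak (default 0).
#' @param noise_sd pixel noise sigma as a fraction of the tallest band
#'   peak (default 0).
#' @param n_rows lane length in rows (default 1000).
#' @param lane_width,gap lane width and inter-lane gap in columns.
#' @param ladder_mw ladder molecular weights, kD.
#' @param mapping migration mapping `c(a, b)` (default
#'   [default_gel_mapping()]).
#' @param band_mw band centre molecular weights, kD.
#' @param seed integer seed.
#' @return List with `image` (rows x columns matrix), `lane_bounds` (list
#'   of column ranges), `profiles` (noise-free per-lane [lane_profile()]s),
#'   `ladder` (data frame `position`, `mw`), `mapping`, and `truth` (the
#'   planted fractions).
#' @export
make_gel <- function(fractions, total_signal = 1e4, band_sigma_kd = 2.5,
                     drift_amp = 0, noise_sd = 0, n_rows = 1000,
                     lane_width = 20, gap = 5,
                     ladder_mw = c(250, 150, 100, 70, 55, 40),
                     mapping = default_gel_mapping(n_rows),
                     band_mw = c(monomer = 55, dimer = 110, trimer = 165),
                     seed = 1) {
  if (!is.list(fractions)) fractions <- list(fractions)
  for (f in fractions) {
    if (abs(sum(f) - 1) > 1e-9) stop("lane fractions must sum to 1")
  }
  a <- mapping[["a"]]; b <- mapping[["b"]]
  position_at <- function(w) (log10(w) - a) / b
  rows <- seq_len(n_rows)
  render_lane <- function(frac) {
    dens <- numeric(n_rows)
    for (nm in names(band_mw)) {
      amount <- total_signal * unname(frac[[nm]])
      if (amount <= 0) next
      centre <- position_at(band_mw[[nm]])
      # convert the kD sigma to rows via the local slope of the mapping
      sigma_rows <- band_sigma_kd / abs(band_mw[[nm]] * log(10) * b)
      dens <- dens + amount * stats::dnorm(rows, centre, sigma_rows)
    }
    dens
  }
  clean <- lapply(fractions, render_lane)
  peak <- max(1e-12, max(vapply(clean, max, numeric(1))))
  n_lanes <- length(fractions)
  ncols <- n_lanes * lane_width + (n_lanes + 1) * gap
  image <- matrix(0, n_rows, ncols)
  lane_bounds <- vector("list", n_lanes)
  for (l in seq_len(n_lanes)) {
    c0 <- gap + (l - 1) * (lane_width + gap) + 1
    lane_bounds[[l]] <- c0:(c0 + lane_width - 1)
    image[, lane_bounds[[l]]] <-
      matrix(clean[[l]] / lane_width, n_rows, lane_width)
  }
  if (drift_amp > 0) {
    image <- image + drift_amp * peak * (rows / n_rows) / lane_width
  }
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      image <- image +
        matrix(stats::rnorm(length(image),
                            sd = noise_sd * peak / lane_width),
               n_rows, ncols)
    })
  }
  image <- pmax(image, 0)
  profiles <- lapply(seq_len(n_lanes), function(l) {
    lane_profile(rows, clean[[l]], provenance = sprintf("synthetic lane %d", l))
  })
  list(image = image,
       lane_bounds = lane_bounds,
       profiles = profiles,
       ladder = data.frame(position = position_at(ladder_mw), mw = ladder_mw),
       mapping = c(a = a, b = b),
       truth = fractions)
}
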