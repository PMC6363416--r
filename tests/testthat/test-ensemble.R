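test_that("top_fraction keeps the floor(frac*N) best-scoring models", {
  me <- make_ensemble(n_models = 10, resnos = 10:12, n_clusters = 1, seed = 7)
  ens <- me$ensemble
  top3 <- top_fraction(ens, 0.3)
  expect_equal(n_models(top3), 3L)
  # sort oracle: the three smallest scores
  expect_equal(sort(top3$scores), sort(ens$scores)[1:3])
  # frac = 1 keeps everything, reordered by score; idempotent thereafter
  all_m <- top_fraction(ens, 1)
  expect_equal(n_models(all_m), 10L)
  expect_equal(all_m$scores, sort(ens$scores))
  expect_identical(top_fraction(all_m, 1)$ids, all_m$ids)
  # retained scores never exceed discarded scores
  expect_lte(max(top3$scores), min(setdiff(ens$scores, top3$scores)))
  expect_error(top_fraction(ens, 0), "\\(0, 1\\]")
  expect_error(top_fraction(ens, 1.1), "\\(0, 1\\]")
})

test_that("ties in top_fraction break stably by model id", {
  coords <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  ens <- model_ensemble(coords, c("m_d", "m_a", "m_c", "m_b"),
                        c(5, 5, 1, 5),
                        data.frame(chain = "A", resno = 1:3))
  expect_equal(top_fraction(ens, 0.5)$ids, c("m_c", "m_a"))
})

test_that("Kabsch superposition recovers constructed rigid transforms", {
  A <- random_coords(25, seed = 2)
  self <- kabsch_superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  R <- xlcaliper:::rotation_about_axis(c(0, 0, 1), 37 * pi / 180)
  B <- sweep(A %*% t(R), 2, c(4, -2, 7), FUN = "+")
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  refit <- sweep(B %*% fit$rotation, 2, as.numeric(fit$translation), FUN = "+")
  expect_equal(refit, A, tolerance = 1e-8)
  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD of noisy copies sits in the expected band", {
  A <- random_coords(50, seed = 5)
  # isotropic displacement noise of magnitude sigma = 0.5 A per atom
  rmsds <- vapply(1:20, function(s) {
    noise <- withr::with_seed(s, matrix(rnorm(150, sd = 0.5 / sqrt(3)),
                                        ncol = 3))
    kabsch_superpose(A, A + noise)$rmsd
  }, numeric(1))
  expect_true(all(rmsds > 0.3 & rmsds < 0.7))
})

test_that("pairwise RMSD matrix matches per-pair recomputation", {
  me <- make_ensemble(n_models = 5, resnos = 10:14, n_clusters = 1, seed = 9)
  ens <- me$ensemble
  M <- pairwise_rmsd_matrix(ens)
  expect_equal(M, t(M))
  expect_equal(unname(diag(M)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(M[i, j],
                 kabsch_superpose(ens$coords[, , i], ens$coords[, , j])$rmsd,
                 tolerance = 1e-8)
  }
  # duplicated model has zero off-diagonal distance
  dup <- model_ensemble(ens$coords[, , c(1, 1, 2)], c("a", "b", "c"),
                        c(1, 2, 3), ens$selection)
  expect_equal(pairwise_rmsd_matrix(dup)["a", "b"], 0, tolerance = 1e-8)
  single <- model_ensemble(ens$coords[, , 1, drop = FALSE], "a", 1,
                           ens$selection)
  expect_error(pairwise_rmsd_matrix(single), "at least two")
})

test_that("hierarchical clustering recovers planted conformations exactly", {
  me <- make_ensemble(n_models = 120, resnos = 10:17, n_clusters = 2,
                      cluster_scale = 8, spread = 0.4, seed = 13)
  M <- pairwise_rmsd_matrix(me$ensemble)
  labels <- hier_cluster(M, k = 2)
  expect_equal(mclust::adjustedRandIndex(labels, me$truth$labels), 1.0)
  # k = N puts every model in its own cluster
  expect_equal(length(unique(hier_cluster(M, k = 120))), 120L)
  expect_error(hier_cluster(M, k = 121), "exceeds")
  expect_error(hier_cluster(M, k = 2, h = 1), "exactly one")
})

test_that("average-linkage merges match a hand-computed dendrogram", {
  # 6 points on a line, two triplets, all merge heights distinct
  x <- c(0, 1, 2.5, 10, 11.5, 13.5)
  D <- as.matrix(dist(x))
  labels <- hier_cluster(D, linkage = "average", k = 2)
  expect_equal(unname(labels), c(1, 1, 1, 2, 2, 2), ignore_attr = TRUE)
  tree <- attr(labels, "tree")
  # hand agglomeration: {1,2} at 1; {4,5} at 1.5; {3} joins {1,2} at
  # average(2.5, 1.5) = 2; {6} joins {4,5} at average(3.5, 2) = 2.75;
  # final merge at the mean of the 9 cross distances
  expect_equal(tree$height,
               c(1, 1.5, 2, 2.75,
                 mean(outer(c(0, 1, 2.5), c(10, 11.5, 13.5),
                            function(a, b) abs(a - b)))),
               tolerance = 1e-12)
})

test_that("cluster representatives are the best-scoring members of the largest clusters", {
  labels <- c(1, 1, 1, 1, 1, 2, 2, 2, 3, 3)
  scores <- c(5, 3, 9, 4, 8, 2, 6, 7, 1, 10)
  ids <- sprintf("m%02d", 1:10)
  reps <- cluster_representatives(labels, scores, ids, k_largest = 10)
  # sizes 5/3/2; fewer clusters than requested is allowed
  expect_equal(reps, c("m02", "m06", "m09"))
  expect_equal(cluster_representatives(rep(1, 10), scores, ids, 4), "m09")
  expect_error(cluster_representatives(labels, scores, ids, 0), "positive")
  # planted ensemble: representative ids equal generator truth
  me <- make_ensemble(n_models = 80, resnos = 10:14, n_clusters = 2,
                      spread = 0.4, seed = 19)
  M <- pairwise_rmsd_matrix(me$ensemble)
  lab <- hier_cluster(M, k = 2)
  reps <- cluster_representatives(lab, me$ensemble$scores, me$ensemble$ids, 2)
  expect_setequal(reps, me$truth$best_ids)
})

test_that("pair distance distributions report per-model interchain minima", {
  # identical symmetric models at a fixed pair distance -> degenerate
  b <- make_c3_bundle(n_res = 6, ring_radius = 11.258, helix_radius = 0)
  ca <- as.matrix(b$structure$atoms[, c("x", "y", "z")])
  sel <- b$structure$atoms[, c("chain", "resno")]
  coords <- array(rep(ca, 3), c(nrow(ca), 3, 3))
  ens <- model_ensemble(coords, c("a", "b", "c"), 1:3, sel)
  dd <- pair_distance_distribution(ens, 3)
  expect_equal(dd$min, 11.258 * sqrt(3), tolerance = 1e-6)
  expect_lt(diff(range(dd$values)), 1e-9)
  expect_equal(sum(dd$counts), 3)
  expect_error(pair_distance_distribution(ens, 99), "outside")
  # reported minimum equals a brute-force scan over models and chain pairs
  me <- make_ensemble(n_models = 40, resnos = 10:14, n_clusters = 2,
                      seed = 23)
  dd2 <- pair_distance_distribution(me$ensemble, 12)
  brute <- min(vapply(seq_len(40), function(m) {
    xyz <- me$ensemble$coords[, , m]
    idx <- lapply(c("A", "B", "C"), function(ch) {
      which(me$ensemble$selection$chain == ch &
              me$ensemble$selection$resno == 12)
    })
    min(sqrt(sum((xyz[idx[[1]], ] - xyz[idx[[2]], ])^2)),
        sqrt(sum((xyz[idx[[2]], ] - xyz[idx[[3]], ])^2)),
        sqrt(sum((xyz[idx[[1]], ] - xyz[idx[[3]], ])^2)))
  }, numeric(1)))
  expect_equal(dd2$min, brute, tolerance = 1e-10)
  expect_equal(sum(dd2$counts), 40)
})

test_that("planted Gamma pair distances are recovered at the quantile level", {
  me <- make_ensemble(n_models = 2000, resnos = 10:14, n_clusters = 1,
                      planted_resno = 12, planted_shape = 40,
                      planted_scale = 0.5, seed = 29)
  dd <- pair_distance_distribution(me$ensemble, 12)
  planted_q <- quantile(me$truth$planted_distances, c(0.05, 0.5, 0.95),
                        names = FALSE)
  expect_equal(dd$percentiles, planted_q, tolerance = 1e-8)
  theo_q <- qgamma(c(0.05, 0.5, 0.95), shape = 40, scale = 0.5)
  expect_true(all(abs(dd$percentiles - theo_q) / theo_q < 0.05))
  expect_equal(dd$min, min(me$truth$planted_distances), tolerance = 1e-8)
})

test_that("constraint satisfaction matches the counting oracle", {
  me <- make_ensemble(n_models = 200, resnos = 10:14, n_clusters = 1,
                      planted_resno = 12, seed = 31)
  dmin <- me$truth$planted_distances
  # exact counting at a data-defined threshold: 25% of models satisfy
  thr <- quantile(dmin, 0.25, type = 1)
  frac <- constraint_satisfaction(me$ensemble, 12, thr)
  expect_equal(frac, mean(dmin <= thr))
  expect_equal(constraint_satisfaction(me$ensemble, 12, Inf), 1)
  expect_equal(constraint_satisfaction(me$ensemble, 12, min(dmin) - 1), 0)
})

test_that("tightening one planted pair leaves other residues untouched", {
  loose <- make_ensemble(n_models = 300, resnos = 10:14, n_clusters = 1,
                         planted_resno = 12, planted_shape = 100,
                         planted_scale = 0.25, seed = 37)   # mean 25 A
  tight <- make_ensemble(n_models = 300, resnos = 10:14, n_clusters = 1,
                         planted_resno = 12, planted_shape = 72,
                         planted_scale = 0.25, seed = 37)   # mean 18 A
  sat_loose <- constraint_satisfaction(loose$ensemble, 12, 19.5)
  sat_tight <- constraint_satisfaction(tight$ensemble, 12, 19.5)
  expect_gt(sat_tight, sat_loose)
  # an unplanted residue keeps its distribution across the two runs
  d_loose <- pair_distance_distribution(loose$ensemble, 10)
  d_tight <- pair_distance_distribution(tight$ensemble, 10)
  expect_equal(d_loose$percentiles, d_tight$percentiles, tolerance = 1e-6)
})

test_that("ensembles round-trip through the packed table format", {
  me <- make_ensemble(n_models = 6, resnos = 10:12, n_clusters = 1, seed = 41)
  cf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(me$ensemble, cf, sf)
  back <- read_ensemble(cf, sf)
  expect_equal(back$ids, me$ensemble$ids)
  expect_equal(back$scores, me$ensemble$scores, tolerance = 1e-12)
  expect_equal(back$coords, me$ensemble$coords, tolerance = 1e-12)
})
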