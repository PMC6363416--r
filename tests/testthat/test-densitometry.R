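test_that("migration calibration recovers the generating log-linear map", {
  # two bands: exact fit
  cal2 <- calibrate_migration(c(100, 700), c(150, 55))
  expect_equal(cal2$r_squared, 1)
  expect_equal(cal2$mw_at(100), 150, tolerance = 1e-9)
  expect_equal(cal2$position_at(55), 700, tolerance = 1e-9)
  # noiseless synthetic ladder from known coefficients
  a <- 2.45; b <- -0.0011
  pos <- seq(50, 950, by = 150)
  mw <- 10^(a + b * pos)
  cal <- calibrate_migration(pos, mw)
  expect_equal(cal$a, a, tolerance = 1e-10)
  expect_equal(cal$b, b, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  expect_error(calibrate_migration(c(1, 1, 2), c(3, 2, 1)), "duplicate")
  expect_error(calibrate_migration(c(1, 2, 3), c(10, 30, 20)),
               "not monotone")
  expect_error(calibrate_migration(5, 10), "at least two")
})

test_that("lane profiles are column sums with optional polarity inversion", {
  img <- matrix(2, nrow = 6, ncol = 10)
  prof <- extract_lane_profile(img, 3:5)
  expect_equal(prof$intensity, rep(6, 6))
  expect_equal(diff(range(prof$intensity)), 0)
  inv <- extract_lane_profile(img, 3:5, invert = TRUE)
  expect_equal(inv$intensity, rep(0, 6))
  expect_error(extract_lane_profile(img, integer(0)), "empty")
  expect_error(extract_lane_profile(img, 9:12), "outside")
  # Gaussian band of known integral survives extraction within 1%
  g <- make_gel(list(c(monomer = 1, dimer = 0, trimer = 0)),
                total_signal = 5000)
  p <- extract_lane_profile(g$image, g$lane_bounds[[1]])
  expect_equal(pracma::trapz(p$position, p$intensity), 5000,
               tolerance = 0.01)
  # two lanes recover their own per-lane generation
  g2 <- make_gel(list(c(monomer = 1, dimer = 0, trimer = 0),
                      c(monomer = 0, dimer = 1, trimer = 0)))
  for (l in 1:2) {
    pl <- extract_lane_profile(g2$image, g2$lane_bounds[[l]])
    expect_equal(pl$intensity, g2$profiles[[l]]$intensity, tolerance = 1e-9)
  }
})

test_that("baseline subtraction removes drift without eating band signal", {
  flat <- lane_profile(1:200, rep(7, 200))
  out <- subtract_baseline(flat, window = 51)
  expect_equal(out$intensity, rep(0, 200))
  # planted linear drift + band: band integral recovered within 2%
  pos <- 1:1000
  band <- 800 * dnorm(pos, 400, 20)
  drift <- 0.5 * pos / 1000
  prof <- lane_profile(pos, band + drift)
  corr <- subtract_baseline(prof, smooth = 1)
  got <- pracma::trapz(pos, corr$intensity)
  expect_lt(abs(got - 800) / 800, 0.02)
  # subtracting a non-negative baseline never increases the signal
  expect_true(all(corr$intensity <= prof$intensity + 1e-9))
  expect_error(subtract_baseline(flat, window = 300), "larger")
  expect_error(subtract_baseline(flat, window = 1), "at least 3")
})

test_that("band quantification reproduces planted percent dimer", {
  g <- make_gel(list(c(monomer = 0.6, dimer = 0.4, trimer = 0)))
  cal <- calibrate_migration(g$ladder$position, g$ladder$mw)
  q <- quantify_bands(subtract_baseline(
    extract_lane_profile(g$image, g$lane_bounds[[1]])), cal)
  expect_lt(abs(q$percent_dimer - 40), 0.5)
  expect_lte(sum(q$bands), q$total + 1e-9)
  # gain invariance of the percent statistic
  g10 <- make_gel(list(c(monomer = 0.6, dimer = 0.4, trimer = 0)),
                  total_signal = 1e5)
  q10 <- quantify_bands(subtract_baseline(
    extract_lane_profile(g10$image, g10$lane_bounds[[1]])), cal)
  expect_equal(q10$percent_dimer, q$percent_dimer, tolerance = 1e-6)
  # a lane with no dimer signal scores zero
  g0 <- make_gel(list(c(monomer = 1, dimer = 0, trimer = 0)))
  q0 <- quantify_bands(subtract_baseline(
    extract_lane_profile(g0$image, g0$lane_bounds[[1]])), cal)
  expect_equal(q0$percent_dimer, 0, tolerance = 1e-6)
  expect_error(quantify_bands(g$profiles[[1]], cal,
                              windows = list(dimer = c(1, 5))),
               "dimer")
})

test_that("ANOVA with Bonferroni post-tests matches long-hand arithmetic", {
  # identical groups: no between-group variance
  same <- anova_bonferroni(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # extreme separation with zero within-group variance
  sep <- anova_bonferroni(list(a = c(0, 0, 0), b = c(10, 10, 10)))
  expect_lt(sep$p, 1e-6)
  expect_error(anova_bonferroni(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(anova_bonferroni(list(a = c(1, 2))), "two groups")
})

test_that("ANOVA and adjusted p-values match brute-force formulas on random draws", {
  withr::with_seed(55, {
    for (rep in 1:100) {
      k <- sample(2:4, 1)
      groups <- lapply(seq_len(k), function(i) rnorm(sample(3:6, 1),
                                                     mean = runif(1, 0, 5)))
      names(groups) <- paste0("g", seq_len(k))
      res <- anova_bonferroni(groups)
      # brute-force sums of squares
      all_v <- unlist(groups)
      gm <- mean(all_v)
      ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                         numeric(1)))
      ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                         numeric(1)))
      df_b <- k - 1; df_w <- length(all_v) - k
      F_hand <- (ss_b / df_b) / (ss_w / df_w)
      expect_equal(res$F, F_hand, tolerance = 1e-10)
      expect_equal(res$p, pf(F_hand, df_b, df_w, lower.tail = FALSE),
                   tolerance = 1e-10)
      # Bonferroni multiplication by k(k-1)/2, capped at 1
      m <- k * (k - 1) / 2
      expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p_raw * m),
                   tolerance = 1e-12)
      expect_equal(nrow(res$pairwise), m)
    }
  })
})

test_that("the published percent-dimer fixture ships with expected entries", {
  tab <- experimental_percent_dimer()
  expect_true(all(c("construct", "condition", "percent_dimer") %in%
                    names(tab)))
  g30_mts <- tab[tab$construct == "G30C C349A" &
                   tab$condition == "MTS-2-MTS", ]
  expect_equal(g30_mts$percent_dimer, 31.2)
})
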