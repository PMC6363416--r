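# Shared in-code fixtures for the test suite.

# The four published Ca-Ca / cross-link span equivalences (Angstrom).
conversion_pairs <- data.frame(
  d_ca = c(20.5, 19.5, 23.3, 40.5),
  d_xl = c(11.9, 10.9, 14.7, 31.9))

# A dense flat ring trimer: one-third arc of a circle of radius `R` in the
# z = 0 plane as the protomer (n_arc atoms), plus one atom at the ring
# centre, C3-symmetrised. The full trimer is a closed ring whose wall a
# second copy cannot penetrate in-plane, giving clean geometric bounds for
# the inter-trimer placement search. Residue 999 sits at the centre.
ring_trimer <- function(R = 5, n_arc = 15) {
  ang <- seq(0, 2 * pi / 3, length.out = n_arc + 1)[-(n_arc + 1)]
  atoms <- data.frame(chain = "A",
                      resno = c(seq_len(n_arc), 999L),
                      resid = "GLY", elety = "CA",
                      x = c(R * cos(ang), 0), y = c(R * sin(ang), 0),
                      z = 0, stringsAsFactors = FALSE)
  symmetrize_c3(trimer_structure(atoms))
}

# Small random protomer coordinates for Kabsch tests.
random_coords <- function(n, sd = 5, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = sd), ncol = 3))
}

# Brute-force minimum over all interchain atom pairs for one selector.
brute_min_interchain <- function(struct, resno, elety = "CA") {
  a <- struct$atoms[struct$atoms$resno == resno & struct$atoms$elety == elety, ]
  chains <- unique(a$chain)
  best <- Inf
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i >= j) next
    p <- as.numeric(a[a$chain == chains[i], c("x", "y", "z")])
    q <- as.numeric(a[a$chain == chains[j], c("x", "y", "z")])
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}
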