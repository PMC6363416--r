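# xlcaliper

Cysteine cross-linking "molecular caliper" analysis for C3-symmetric
trimeric membrane receptors.

Bifunctional cysteine-reactive reagents — MTS-2-MTS (5.2 Å), BMB (10.9 Å)
and BM(PEG)₂ (14.7 Å spacers, sulphhydryl to sulphhydryl) — bridge pairs of
engineered cysteines only when the two thiols can come within the spacer
length. Applied to a homotrimeric receptor carrying one introduced cysteine
per subunit, the pattern of dimer formation across linker lengths brackets
inter-subunit distances in the intracellular juxta-membrane regions, where
crystallography sees nothing. `xlcaliper` implements the complete
computational side of that experiment for structural biologists and channel
physiologists:

- **caliper conversion** between backbone separations and cross-linkable
  spans: `d_SS = d_CαCα − 2δ` with a per-cysteine Cα→thiol reach δ = 4.3 Å
  (recoverable by least squares from published distance equivalences via
  `calibrate_delta()`), plus compatibility classification of residue
  positions against each linker;
- **cross-linking combinatorics**: with one reactive Cys per subunit a
  trimer can form at most one bridge, so at saturation the dimer band
  carries exactly 2/3 (66%) of the subunit signal — closed form, exhaustive
  enumeration and seeded Monte-Carlo simulation of the
  monomer/dimer/trimer band fractions;
- **structure handling**: PDB I/O, C3 symmetrisation of a protomer,
  in-silico cysteine substitution with idealised SG placement, inter-chain
  distance queries, and a clash-constrained placement search that tests
  whether a cross-link could instead have formed *between* neighbouring
  trimers;
- **ensemble analysis** for scored structural model sets: top-fraction
  score filtering, Kabsch superposition, pairwise RMSD, deterministic
  hierarchical clustering, best-scoring cluster representatives,
  inter-subunit residue-pair distance distributions and constraint
  satisfaction fractions;
- **elastic-network normal modes** (anisotropic network model over Cα
  atoms): Hessian assembly, spectral decomposition with rigid-body mode
  detection, and amplitude sweeps reporting how much a low-frequency mode
  can transiently shorten an inter-subunit pair distance;
- **gel densitometry**: lane profile extraction from grayscale images,
  log-linear ladder calibration, baseline removal, band integration, the
  percent-dimer statistic (100 × dimer-band density / whole-lane density),
  and one-way ANOVA with Bonferroni post-tests;
- **seeded synthetic-data generators** with analytic ground truth for every
  input: C3 helix bundles, planted-structure model ensembles, rendered gel
  images.

## Worked example

Bracket an inter-subunit distance with the caliper, then follow the signal
through to a quantified blot:

```r
library(xlcaliper)

# a backbone separation of 19.5 A is the ceiling BMB can bridge
xlink_to_ca(get_linker("BMB")$spacer_ss)
#> [1] 19.5

# synthetic C3 bundle whose residue ring sits at that separation
b <- make_c3_bundle(n_res = 12, ring_radius = 11.258, helix_radius = 0)
interchain_distances(b$structure, 6)$min
#> [1] 19.49943

classify_compatibility(rep(19.49943, 100), get_linker("BMB"))
#> compatibility with BMB: 1.000 of models satisfied (strong)
classify_compatibility(rep(19.49943, 100), get_linker("MTS-2-MTS"))
#> compatibility with MTS-2-MTS: 0.000 of models satisfied (absent)
```

The residue is within reach of BMB in every model but never within reach of
the short MTS-2-MTS spacer — the graded-linker pattern that localises a
residue pair between 5.2 + 8.6 and 10.9 + 8.6 Å of backbone separation.
Predict the blot a cross-linking reaction would produce and recover the
statistic from a rendered gel:

```r
ana <- analytic_band_fractions(reaction_params(p_link = 0.8))
ana
#> band fractions (subunit signal): monomer 0.3387, dimer 0.6613, trimer 0.0000

g   <- make_gel(list(unlist(ana)), noise_sd = 0.02, seed = 1)
cal <- calibrate_migration(g$ladder$position, g$ladder$mw)
q   <- quantify_bands(subtract_baseline(
         extract_lane_profile(g$image, g$lane_bounds[[1]])), cal)
q
#> bands: monomer 3202, dimer 6498, trimer 16.52; total 9879; percent dimer 65.8%
```

The densitometry recovers the planted 66.1% dimer signal to within a
percentage point. `experimental_percent_dimer()` ships published wet-lab
percent-dimer measurements for annotating such reports (they are reference
values, never computed targets).

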