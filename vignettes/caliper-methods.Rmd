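---
title: "Cross-linking calipers on trimeric receptors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-linking calipers on trimeric receptors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlcaliper)
```

## The problem

Trimeric ATP-gated channels carry their amino- and carboxy-terminal tails
on the intracellular side of the membrane, where they assemble into a
cytoplasmic cap in the open state. In the apo and desensitized states these
regions are invisible to crystallography, so their organisation must be
probed indirectly. One such probe treats bifunctional cysteine-reactive
reagents as molecular calipers: a linker with a sulphhydryl-to-sulphhydryl
spacer of length $s$ can bridge two engineered cysteines only if their
thiols can approach within $s$, and a bridge between two subunits of a
trimer shows up on a denaturing Western blot as a dimer band. Scanning a
run of residues with linkers of graded length (5.2, 10.9, 14.7 Å) yields a
position-specific cross-linking pattern that brackets inter-subunit
distances. This package implements every computational step of that
analysis; it does not generate structural models ab initio (that is the job
of a dedicated modelling suite), and it does not attempt any wet-lab
quantity.

## The caliper conversion

A linker bridges thiols, but models and structures are interrogated at
backbone Cα positions. The two scales are related by a fixed per-cysteine
Cα→thiol reach $\delta$:

$$d_{SS} = d_{C\alpha C\alpha} - 2\delta, \qquad \delta = 4.3\ \text{Å}.$$

The value of $\delta$ is not arbitrary: `calibrate_delta()` recovers it by
least squares (the mean of half-differences) from the four standard
published Cα–Cα ↔ cross-link equivalences (20.5 ↔ 11.9, 19.5 ↔ 10.9,
23.3 ↔ 14.7, 40.5 ↔ 31.9 Å), which are *exactly* consistent with a single
constant — the maximum residual of the fit is zero to machine precision.
We therefore adopt the constant-offset model and deliberately avoid any
rotamer-aware conversion; 4.3 Å is physically sensible for a cysteine
side chain (Cα–Cβ ≈ 1.5 Å plus Cβ–S ≈ 1.8 Å plus geometry). The
conversion floors at zero when the side-chain reach consumes the whole
backbone separation. Whether the offset silently includes linker
flexibility cannot be decided from the calibration pairs alone; we make no
allowance for it, and conversions should be read as nominal reach, not a
hard geometric cutoff.

`classify_compatibility()` turns a set of per-model minimum inter-chain Cα
distances into the fraction of models a given linker could bridge and a
three-way call: **strong** at a satisfied fraction ≥ 0.5 (the regime where
experiments report ~60% dimer, i.e. efficient cross-linking), **absent**
at ≤ 0.1 (indistinguishable from background dimerisation), and
**intermediate** between. The thresholds are exposed as arguments.

## Intra- versus inter-trimer cross-linking

A dimer band could in principle also arise from a bridge between two
*neighbouring* trimers. The geometric discriminator is
`min_inter_trimer_distance()`: hold one trimer fixed, keep both C3 axes
parallel to the membrane normal, and search the in-plane position and spin
of the second trimer for the placement that minimises the selected
inter-trimer atom distance subject to a hard-sphere clash constraint (no
atom pair closer than 3 Å by default — the analysis needs only "without
clashing", not an energy model). The search is a deterministic polar scan:
approach direction and spin on 5° grids over one C3 sector each,
centre-to-centre separation marched inward at 1 Å and refined to 0.1 Å at
the winning placement, first minimal placement winning ties. On dense
synthetic structures this agrees with an exhaustive translation-grid scan
to within a coarse grid step (tested). The qualitative conclusion it
supports is the published one: surface-exposed residues on two adjacent
trimers can approach to roughly the clash radius, while residues pointing
at the central axis stay separated by about the trimer diameter — so
cross-linking at an axis-proximal position must be intra-trimer. The
published ~13 Å / ~51 Å figures for specific positions depend on the
particular homology models used there and are not numeric targets here.

## Cross-linking combinatorics and band fractions

Each subunit carries exactly one reactive cysteine, giving three interface
pairs per trimer. The reaction scheme (`analytic_band_fractions()`,
`enumerate_band_fractions()`, `simulate_outcomes()`) visits the three
pairs in random order; an available pair bridges with probability
$p_{\mathrm{link}}$. A bridge consumes two of the three cysteines, after
which every remaining pair shares a consumed cysteine — so **at most one
bridge forms per trimer**, and the bridging probability is
$q = 1-(1-p_{\mathrm{link}})^3$ independent of visit order. Leftover free
cysteines may end as dead-end mono-adducts with probability
$p_{\mathrm{mono}}$; since a mono-adduct joins nothing, it never changes
band identity and the parameter is tracked but does not enter the
fractions. A bridged trimer runs as a trimer band with probability
$r_{\mathrm{retain}}$ (the ~160–170 kD interpretation of a more stable
bridged trimer surviving SDS), otherwise as dimer + monomer:

$$f_{\text{trimer}} = q\,r, \qquad
  f_{\text{dimer}} = \tfrac{2}{3}\,q\,(1-r), \qquad
  f_{\text{monomer}} = 1 - f_{\text{trimer}} - f_{\text{dimer}}.$$

Band intensity is proportional to subunit count, so at saturation
($p_{\mathrm{link}}=1$, $r=0$) the dimer band carries exactly $2/3$ of the
subunit signal — the 66% benchmark against which observed ~60% dimerisation
reads as "efficient". Whether the trimer band requires one or two bridges
is not decidable from gel data, so $r_{\mathrm{retain}}$ is a free
parameter (default 0), not an inferred quantity. The analytic form, the
exhaustive enumeration over all visit orders and outcomes, and the seeded
simulation are three independent routes kept separate precisely so they
can check one another in the tests.

## Ensemble analysis

The analysis layer for ab initio model sets mirrors the published
workflow shape: generate many models of the flexible intracellular region,
keep the best-scoring fraction, cluster, and read distance distributions.

* `top_fraction()` keeps $\lfloor f N \rfloor$ lowest-score models (a 10%
  filter on a 20,000-model run keeps exactly 2,000), with stable id
  tie-breaking so the filter is deterministic under score ties.
* `kabsch_superpose()` is the classic SVD superposition (proper rotation
  enforced via the determinant sign); `pairwise_rmsd_matrix()` applies it
  over the full stored selection with no mass weighting.
* `hier_cluster()` delegates to agglomerative clustering on the RMSD
  matrix. The published procedure does not state its linkage rule or
  cluster criterion; we default to average linkage and expose
  linkage/`k`/height as parameters. `cluster_representatives()` returns
  the lowest-score member of each of the largest clusters (size ties
  broken toward the cluster holding the better score).
* `pair_distance_distribution()` reduces each model to the minimum over
  the three chain-pair Cα distances of one residue and summarises with
  the minimum, 5/50/95 percentiles (linear interpolation) and a 0.5 Å
  histogram; `constraint_satisfaction()` is the corresponding satisfied
  fraction under a Cα ceiling, the descriptive counterpart of a harmonic
  modelling restraint.

Ensembles are stored as packed coordinate + score tables
(`write_ensemble()`/`read_ensemble()`) because per-file formats are
I/O-bound at the 20,000-model scale.

## Elastic-network normal modes

Whether a cross-link that is too long for the static structure could
capture a transient motion is asked of an anisotropic network model:
uniform springs $\gamma = 1$ between Cα atoms within a 15 Å cutoff,
Hessian superelements $-\gamma\,\hat r \hat r^{\mathsf T}$ with zero row
sums, diagonalised exactly. The original analysis used an
internal-coordinates NMA tool with default settings and reported only a
qualitative distance reduction, so a standard Cartesian ANM is the
appropriate level of theory here. Rigid-body modes are detected at
eigenvalue < 10⁻⁸ × the spectral maximum (six for any connected,
non-collinear system; five for a diatomic); "mode 1" means the first
internal mode above them. Eigenvector signs follow a
first-nonzero-component-positive convention so results are reproducible
across LAPACK builds. `pair_distance_delta_along_mode()` sweeps the mode
amplitude over a 201-point symmetric grid and reports the largest
reduction of a chosen pair distance; `amplitude_cap()` bounds the sweep so
the most-displaced atom moves at most 5 Å, a conservative range for
harmonic extrapolation. C3 symmetry produces degenerate mode pairs whose
individual eigenvectors are basis-dependent; per-mode results are reported
as computed, and symmetric conclusions should be drawn from the maximum
over the low-frequency set (as the tests do). The published "~5 Å"
reduction for a specific pair is a property of that particular homology
model and is out of numeric scope; the reproducible claim — that some
low-frequency mode of a C3 TM-like bundle shortens a terminal inter-chain
pair — is asserted on synthetic bundles.

## Densitometry

`extract_lane_profile()` sums image rows across the lane's columns
(chemiluminescence polarity by default, `invert` for stained gels).
Migration is calibrated as $\log_{10} MW = a + b\,x$ from ladder bands.
Baseline removal is a morphological opening — rolling minimum then rolling
maximum over the same window (25% of the lane by default) — chosen over a
plain rolling minimum because opening reproduces a linear drift exactly
instead of lagging it by half a window; the profile is first denoised
with a short area-preserving rolling mean (2% of the lane) so pixel noise
cannot drag the rolling minimum below the true baseline. The manual
baseline step of interactive gel software is thereby replaced with a
deterministic, parameterised rule. Bands are integrated by the
trapezoidal rule over fixed molecular-weight windows (45–65, 100–120,
150–180 kD defaults; the dimer window is the one that defines the
statistic), with **percent dimer = 100 × dimer-window integral /
whole-lane integral**. The whole lane is used as the denominator —
including any trimer signal — following the "whole length of each lane"
reading of the procedure; the statistic is invariant to overall gain.
Group comparisons use one-way ANOVA followed by all-pairs pooled-variance
t-tests with p-values multiplied by $k(k-1)/2$ and capped at 1, the
Bonferroni post-test family as applied per figure; the family definition
is an argument.

## Synthetic data: what it emulates and what it does not

All tests run on generated inputs with analytic ground truth; each truth
value is recomputable from a stated formula.

* `make_c3_bundle()` builds ideal helices on a ring about the z axis and
  C3-symmetrises them; an atom at distance $r$ from the axis has
  inter-chain distance exactly $r\sqrt3$. Helix geometry defaults to
  standard α-helical values (rise 1.5 Å, twist 100°, helix radius 2.3 Å);
  optional seeded flexible tails drift toward the axis.
* `make_ensemble()` plants cluster structure (independent random centre
  conformations, C3-replicated, isotropic within-cluster spread),
  score–quality correlation (score = RMSD-to-centre + noise), and, for a
  designated residue, an exact per-model inter-chain minimum drawn from a
  Gamma distribution (shape 40, scale 0.5 by default — mean 20 Å,
  matching the scale of juxta-membrane inter-subunit separations) and
  realised as an exact C3 ring. Default size is 2,000 models, the scale
  of a filtered 20,000-model run.
* `make_gel()` renders Gaussian bands at 55/110/165 kD positioned by the
  inverse migration map (band σ 2.5 kD-equivalent), with linear drift and
  white pixel noise specified as fractions of the tallest band peak, on a
  1000-row lane.

These generators reproduce the *geometry and statistics* the pipeline
consumes, not the physics behind them: no side-chain packing or membrane
energetics in the bundles, no Rosetta scoring landscape in the ensembles,
no antibody-binding nonlinearity, saturation or smear in the gels. Passing
tests therefore demonstrate that the analysis recovers planted truth under
realistic noise — not that any particular biological receptor has a given
architecture, and not that real blots are free of systematic effects the
renderer omits.

## Numerical choices and test conditions

Problem sizes in the suite are chosen to exercise each claim at full
fidelity where it is cheap (the 10% filter is checked on a literal
20,000-model ensemble; distance-distribution quantiles at 2,000 models)
and on a few hundred models where the quantity is scale-free (cluster
recovery, whose pairwise-RMSD cost grows quadratically). Monte-Carlo
agreement is asserted at 3 standard errors under fixed seeds; densitometry
recovery is asserted at <2 percentage points mean absolute error over 50
seeded lanes with planted dimer percentages {5, 20, 40, 60} at 2% pixel
noise, and end-to-end render/re-quantify agreement at 1.5 points. All
generators take explicit integer seeds and are byte-reproducible.

## Known limitations

* The constant-offset caliper ignores rotamer states, linker conformers
  and solvent accessibility; positions can fail to cross-link for
  chemical reasons no distance model captures.
* The outcome model is equilibrium-style; it does not model incubation
  time, linker concentration, or cross-linking to unrelated proteins (the
  high-molecular-weight "macro-complex" band seen on real blots).
* The inter-trimer search optimises a single selected distance under a
  hard-sphere constraint; it is a feasibility probe, not a docking
  method.
* The ANM uses uniform springs and no mass weighting; eigenvalues are in
  arbitrary units and only mode shapes and relative orderings are
  interpreted.
* PDB support covers standard ATOM records; insertion codes are rejected
  and alternate locations other than blank/'A' are dropped.
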