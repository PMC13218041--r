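---
title: "Models and methods behind dnallps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnallps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnallps)
```

`dnallps` packages the quantitative analysis stack used when studying
programmable single-stranded DNA (ssDNA) folding and ssDNA/peptide
liquid-liquid phase separation: library design, FRET and CD
spectroscopy, FRAP and droplet-fusion kinetics, coarse-grained (CG)
trajectory statistics, and primary SAXS analysis. This vignette records
the models, the tunable parameters that matter, the numerical choices,
and the places where the design was genuinely open.

## Sequence design

Constructs are screened with two rules. First, *palindrome exclusion*:
a reverse-complement palindrome (a segment equal to the reverse
complement of itself, necessarily of even length, e.g. `GTACGTAC`)
lets two ssDNA molecules dimerise in register, so candidates containing
a palindrome of 6 nt or more are removed. `find_palindromes()` reports
all *maximal* hits — segments whose two-sided one-base extension breaks
self-complementarity — and overlapping maximal hits are allowed.
Second, *minimal predicted structure*: survivors are ranked by
`fold_proxy()`, a dynamic program that maximises the number of nested
Watson-Crick pairs (A-T, G-C) with a minimum hairpin loop of 3 nt, in
the Nussinov style. The pair count is an ordinal stand-in for a
thermodynamic folding free energy: a sequence that cannot form many
pairs cannot be very stable. We deliberately do not re-implement a
nearest-neighbour free-energy model — the selection criterion is a
ranking, and a monotone proxy preserves rankings in the regime that
matters (near-unstructured sequences). Ties keep library order, so a
seeded shuffle gives one reproducible answer. Shuffling is plain
mononucleotide permutation (composition-preserving); dinucleotide-
preserving shuffling would also be defensible but the screening
criteria do not depend on stacking statistics here.

Charge bookkeeping uses one negative charge per phosphodiester bond
(length − 1 for an n-mer) and side-chain-only peptide charges
(K, R = +1; D, E = −1; H and the free termini = 0, the latter because
the N- and C-terminal charges cancel at neutral pH). A 76-nt construct
against a +5 peptide therefore needs 15 peptides for neutrality, which
is also the experimentally used peptide:DNA stoichiometry.

Intervals (chimera regions) are 0-based, half-open everywhere.

## FRET and melting

Efficiency is the donor-quenching estimate `E = 1 − F_DA/F_D` at the
donor readout wavelength (568 nm by default, nearest grid point with an
interpolation option), and distance follows from
`d = R0 ((1 − E)/E)^(1/6)` with R0 = 5.1 nm (Cy3/Cy5) by default. Noisy
near-zero-transfer samples can give `F_DA` slightly above `F_D`; the
raw efficiency is clamped to 0 with a warning rather than erroring,
because such samples are routine (unstructured constructs with distal
dyes). `E` exactly 0 or 1 has no finite distance and errors. For
replicate series, computing a mean distance from per-replicate
distances and from the mean efficiency differ by a few percent because
the map is nonlinear; both are easy to compute explicitly with
`fret_distance()`, and nothing in the package silently averages.

Renaturation melts are fitted with the Boltzmann sigmoid
`y = A2 + (A1 − A2)/(1 + exp((T − Tm)/dT))` by bounded least squares.
Initialisation is data-driven (plateaus from the outer 10% of points,
Tm from the half-amplitude crossing, dT from the 10-90% width over
`2 ln 9`), which converges on every curve the generator produces and on
noiseless data recovers the generator parameters to numerical
precision. The port algorithm is used because exact-fit data make the
default Gauss-Newton step singular.

## FRAP

The bleached-ROI series R1 is corrected with the double-normalization
formula `(R1 − R3) × (R2_pre − R3_pre)/(R2 − R3)` (background R3,
reference R2), which cancels any constant background exactly and
divides out acquisition photobleaching. The corrected series is fitted
to the exponential asymptote `y(t) = a − b·c^t` with `a, b > 0`,
`0 < c < 1`; `a` is the mobile fraction when `y` is in percent of
prebleach. The half-recovery time solves `y(t) = a/2`, giving
`t_1/2 = log(a/(2b))/log(c)`. The conventional printed closed form
`log_c(1/(2ab))` is dimensionally consistent with this only when
`a = 1`; the package treats the crossing solve as canonical and exposes
the printed expression as `half_time(fit, "closed_form")` for
comparison with legacy spreadsheet analyses. A trace that starts at or
above `a/2` returns 0 with a warning. The 0-100 min-max rescaling
(`frap_minmax_normalize()`) is provided for raw-unit traces; the
synthetic generator already emits percent-of-prebleach units, so the
recovery studies fit the double-normalized series directly —
re-scaling an already-percent trace would remap `(a, b)` without
changing the science but would spoil parameter-recovery bookkeeping.

## Droplet fusion

Aspect ratios are `l_long/l_short` with automatic axis swapping (an
ellipse fitter occasionally reports the axes in the wrong order), and
relaxation is `AR(t) = 1 + (AR0 − 1) exp(−t/τ)` with the endpoint
pinned at 1 — a liquid relaxes to a sphere. Bounded least squares
(`τ > 0`, `AR0 ≥ 1`) is initialised from the first frame and the 1/e
crossing. `summarize_tau()` aggregates per condition and reports the
ratio of means between two named conditions, the statistic used to
compare slow (palindromic, dimerising) with fast (disordered)
condensates.

## Coarse-grained trajectory statistics

Trajectories are lists of bead-coordinate frames in nm with an optional
cubic box (minimum-image convention when present); topologies carry
radii, charges, LJ parameters, and molecule/residue labels.

* **Rg** is the uniform-mass RMS distance from the selection centroid.
* **SASA** is Shrake-Rupley with a deterministic golden-spiral point
  set (960 points and a 0.14 nm probe by default; the bead radius
  default is 0.264 nm). Quadrature error on an isolated sphere is well
  below 0.1%.
* **Min-max normalization** of a metric series maps the observed range
  onto [0, 1], making (SASA, Rg) planes comparable across systems; the
  stored extremes make it invertible.
* **k-means state maps** use 10 seeded restarts keeping the best
  within-cluster sum of squares; k = 3 is the conventional choice when
  the metric distributions show three patterns.
* **GROMOS clustering** computes pairwise RMSD after Kabsch optimal
  superposition (uniform weights, reflection-guarded), then repeatedly
  pops the frame with the most neighbours within the cutoff. With
  `target_fraction` the cutoff is bisected until the largest cluster
  covers the target within ±5 percentage points — the "largest cluster
  ≈ 50%" convention for picking representative conformers. The
  achievable bracket is reported when the search cannot reach the
  target.
* **Stability score** is `log10(N_max/S)`: `N_max` the population of
  the largest cluster and `S` the fraction of a 50×50 grid over the
  normalized unit square its points occupy (floored at one cell). The
  area of a point cloud is not operationally defined by a formula
  alone; the grid-occupancy measure was chosen because it is
  scale-free, monotone in dispersion, and cheap. The grid size is a
  parameter; a convex-hull variant was considered and rejected because
  hull area is dominated by outliers. The logarithm base is 10
  (unstated in the source convention; any base shifts scores by a
  constant factor and preserves comparisons). A 3-fold random
  subsampling helper attaches a spread to the score.
* **Empirical FRET score** `E = (α/n) Σ 1/(d̄_i v_i)` over terminal
  bead pairs, with `d̄` and `v` the per-pair mean and SD of the
  terminal distance across frames. Both proximity and steadiness raise
  the score, mimicking what raises real transfer efficiency. α is an
  arbitrary scale (default 1) because the score is used comparatively;
  `v` is floored at 1e-3 nm so rigid ensembles stay finite (flagged by
  a warning). Whether the sum runs over one or several terminal pairs
  is an input (`terminal_pairs`), since bead models differ in how many
  terminal beads stand in for a dye.
* **Tight-binding cutoff**: per frame and DNA residue, the mean over
  the residue's beads of each bead's shortest distance to any component
  bead; averaged over residues and frames and reported in Angstrom
  (coordinates are nm internally; the Angstrom convention follows how
  such cutoffs are reported). Note the per-residue statistic is the
  *mean* of per-bead shortest distances, not the residue-level
  minimum — with one bead per residue the two coincide.
* **Interaction profiles** count component beads within the cutoff of
  any bead of each residue, averaged over frames; **contact maps** are
  the per-residue-pair fraction of frames with any-bead contact, masked
  within `min_separation` of the diagonal.
* **Nonbonded energy decomposition** `E_inter = E(AB) − E(A) − E(B)`
  with pairwise LJ 12-6 (Lorentz-Berthelot combination) plus
  reaction-field Coulomb, both truncated at 1.1 nm. Reaction-field
  constants default to a medium dielectric of 15 with a conducting
  boundary (`eps_rf = Inf`), the usual CG screening choice; both are
  arguments. The decomposition isolates exactly the cross-group terms,
  so it vanishes when no A-B pair is within the cutoff. Ion LJ
  parameters in synthetic topologies are documented placeholders, not
  force-field values.

## SAXS

`q` is accepted in inverse Angstrom (instrument convention) and lengths
are reported in nm; the conversion lives in one place. The Guinier fit
regresses `ln I` on `q²` *with an auxiliary `q⁴` term* and reads Rg
and I0 from the `q²` coefficient and intercept — the tangent of `ln I`
at `q → 0`. The extra term absorbs the leading systematic curvature of
real form factors (a flexible chain's log-intensity deviates from the
Guinier parabola by `(qRg)⁴/36`), which would otherwise bias a plain
linear fit by 5-6% at the conventional `qRg ≤ 1.3` window. For the same
reason the fitting window is allowed to extend to `1.25 × qRg_limit`;
the reported window statistics describe the classical `qRg ≤ 1.3`
subwindow. On noisy Debye curves this estimator recovers Rg to well
within 2% where the plain linear fit cannot.

The Kratky transform is `q²I(q)` (or the dimensionless
`(qRg)² I/I0` vs `qRg`), separating plateauing flexible chains from
peaked globules. The Porod volume is `V_p = 2π² I0/Q` with the
invariant `Q = ∫ q²I dq` assembled from a Guinier-model head
(0 to `q_min`), the trapezoid rule on the data, and a `K q⁻⁴` tail. The
Porod constant K is read from the oscillation-averaged plateau of
`q⁴I(q)`: compact-particle curves oscillate with period ≈ π/R in q, so
the series is smoothed with a running mean of that width (R from the
measured Rg) before the plateau is read. A warning reports when the
extrapolated tail carries more than 20% of the invariant. On the
0.002-0.3 1/Angstrom range this reaches spheres of radius ≳ 1.5 nm to
within ~1%; below that the unmeasured tail dominates the invariant and
no extrapolation of this family is trustworthy — the tail-share
diagnostic is the honest signal.

## Synthetic data: what it does and does not establish

Every generator stores its ground truth and is deterministic given a
seed (generators snapshot and restore the caller's RNG state).

* `gen_polymer_ensemble()` draws an ideal freely jointed chain per
  frame (default 76 beads, 0.5 nm bonds — a tRNA-length construct) and
  contracts it about its centroid by `1/(1 + compactness)`. This makes
  compactness jointly reduce Rg, SASA, and the terminal-distance mean
  *and* SD, which is exactly the qualitative structure the
  compact-vs-extended analyses assume; 15 binder beads with a residence
  probability emulate the peptide droplet stoichiometry. It is an
  emulation of ensemble geometry, not physics: there are no
  excluded-volume, electrostatic or kinetic correlations between
  frames, so a green contrast test establishes that the statistics
  order ensembles correctly, not that any force field would produce
  those ensembles.
* `gen_frap_trace()` builds the raw three-channel trace backwards from
  the clean recovery so that double normalization inverts it exactly at
  zero noise — the algebraic round trip is the point, and linear
  reference bleaching plus constant background are the distortions the
  formula is designed to remove.
* `gen_fusion_event()` samples the relaxation model at 7.6 frames/s
  (brightfield video rate) with Gaussian noise floored at AR = 1.
* `gen_melt_curve()` and `gen_spectra_pair()` add Gaussian noise to the
  sigmoid and to Gaussian emission bands; the acceptor band sits far
  enough to the red (668 vs 568 nm) that donor-channel crosstalk is
  numerically zero, so the efficiency pipeline round-trips `E_true`
  exactly at zero noise.
* `gen_scattering()` evaluates the analytic Debye-chain or sphere form
  factor on the instrument q-range with multiplicative noise.

Defaults mirror the experimental conditions where those are stated
(76-nt constructs, 15 binders, 7.6 frames/s, 566-700 nm emission scan,
0.002-0.3 1/Angstrom q-range, ~30 s FRAP analysis windows); noise
levels in the recovery studies (2% of amplitude for melts and FRAP,
0.02 AR units for fusion, 1% multiplicative for SAXS) are typical
plate-reader/video noise floors and are fixed in the tests, not tuned.

## Known limitations

* The fold proxy ranks; it does not predict Tm, salt dependence, or
  absolute stability.
* GROMOS bisection assumes the largest-cluster fraction is monotone in
  the cutoff, which can fail on pathological RMSD landscapes; the
  search then reports its bracket instead of guessing.
* Porod volumes for particles smaller than ~1.5 nm radius on this
  q-range are extrapolation-dominated (see above).
* The CG energy decomposition is a single-point evaluation of a pair
  potential; it is not a sampled free energy.
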