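# dnallps

Design and quantitative analysis of single-stranded DNA (ssDNA) /
peptide condensates.

Short cationic peptides coacervate with ssDNA into liquid droplets, and
the DNA's secondary structure programs the outcome: locally folded
hairpin constructs phase-separate readily, while disordered sequences —
especially ones carrying reverse-complement palindromes that let two
strands dimerise — form slower, more viscous, or arrested condensates.
`dnallps` packages the full analysis stack such a study needs, for
experimentalists designing construct libraries and for modellers
post-processing coarse-grained bead simulations:

* **Library design** — sequence shuffling, reverse-complement palindrome
  screening (`find_palindromes`), nested Watson-Crick base-pair
  maximisation as an ordinal stability proxy (`fold_proxy`), two-rule
  candidate selection (`select_candidate`), hairpin chimera assembly,
  and charge stoichiometry (one negative charge per phosphodiester:
  a 76-mer needs 15 copies of a +5 peptide for neutrality).
* **FRET / CD** — donor-quenching efficiency `E = 1 − F_DA/F_D`,
  Förster distance `d = R0 ((1−E)/E)^{1/6}` (R0 = 5.1 nm default), and
  Boltzmann-sigmoid melting fits with data-driven initialisation.
* **FRAP** — the double normalization
  `(R1−R3)(R2_pre−R3_pre)/(R2−R3)`, 0-100 rescaling, the exponential
  asymptote `y(t) = a − b·c^t`, and the half-recovery time
  `t_{1/2} = log_c(a/(2b))`.
* **Droplet fusion** — aspect-ratio relaxation
  `AR(t) = 1 + (AR0−1)e^{−t/τ}` and cross-condition τ summaries.
* **Coarse-grained trajectory statistics** — Rg, Shrake-Rupley SASA,
  min-max normalized (SASA, Rg) state maps with seeded k-means, GROMOS
  conformational clustering with automatic "largest cluster ≈ 50%"
  cutoff search, the dispersion-based stability score
  `log10(N_max/S)`, an empirical FRET score
  `(α/n) Σ 1/(d̄ v)` over terminal bead pairs, tight-binding cutoffs,
  per-residue interaction profiles, contact maps, and the nonbonded
  decomposition `E_inter = E(AB) − E(A) − E(B)` (LJ 12-6 +
  reaction-field Coulomb, 1.1 nm cutoff).
* **SAXS** — curvature-corrected Guinier fits, Kratky transforms, and
  Porod-invariant volumes.
* **Synthetic data** — generators for every input class with stored
  ground truth (polymer ensembles, FRAP traces, fusion events, melt
  curves, scattering curves, spectra pairs), so the whole pipeline is
  testable without instrument data.

## Worked example

```r
library(dnallps)

## design: shuffle a 50-mer, drop palindromic sequences, pick the least
## structured survivor
lib  <- shuffle_library("CAGGATTCCTAGCCGATTCAAGGTTCAAGATCCGGTTACCGATTGGAACC",
                        n = 100, seed = 7)
cand <- select_candidate(lib, min_palindrome = 6, rank = 1)
names(cand)                          # "seq_shuf027"
fold_proxy(cand)$pair_count          # 15 nested pairs (pool minimum)
find_palindromes("GTACGTAC", 6)      # 1 hit: start 0, length 8

## spectroscopy: donor quenched from 100 to 64 by the acceptor
fret_measurement(F_DA = 64, F_D = 100)
#> FRET: E = 0.360, d = 5.613 nm (R0 = 5.10 nm)

## FRAP: synthetic trace with 15% reference bleaching, 2 units of noise
tr  <- gen_frap_trace(a = 80, b = 60, c = 0.9, noise_sd = 2,
                      reference_bleach_frac = 0.15, seed = 42)
fit_recovery(tr$t, frap_double_normalize(tr))
#> FRAP fit: y(t) = 80.28 - 58.28 * 0.9053^t ; t1/2 = 3.747 s, mobile fraction 80.3%

## fusion: one noisy event at 7.6 frames/s
ev <- gen_fusion_event(AR0 = 1.8, tau = 5, noise_sd = 0.02, seed = 3)
fit_fusion_decay(ev$t, ev$AR)
#> Fusion fit: AR0 = 1.791, tau = 5.086 s (rss 0.0729)

## SAXS: Guinier Rg of a 2 nm Debye chain with 1% noise
sc <- gen_scattering("debye_chain", size_param = 2, noise_frac = 0.01,
                     seed = 11)
guinier_fit(sc)
#> Guinier fit: Rg = 1.967 nm, I0 = 0.9949 (65 pts, q*Rg <= 1.29, R^2 = 0.9985)
```

The fitted numbers sit on their generator ground truths (a = 80,
c = 0.9; τ = 5 s; Rg = 2 nm) within the noise the generators injected —
the test suite quantifies those recovery errors systematically
(medians < 5% for FRAP, < 10% for τ, < 2% for Guinier Rg).

## Command line

A thin CLI wraps the same functions (`inst/cli/dnallps`):

```sh
dnallps simulate fusion --ar0 1.8 --tau 5 --noise-sd 0.02 --seed 3 --out ev.tsv
dnallps fusion fit --in ev.tsv
dnallps design palindromes --in constructs.fa --min-len 6
dnallps saxs guinier --in curve.tsv
```

Every `simulate` command writes a `.truth.json` sidecar with the
generator parameters.

## Documentation

`vignettes/dnallps-methods.Rmd` describes the models, the parameter
defaults and why, the numerical choices (fit initialisations,
tolerances, degenerate-input handling), what the synthetic generators
emulate and deliberately do not, and known limitations.
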