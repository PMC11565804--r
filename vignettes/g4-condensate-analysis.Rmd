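---
title: "Methods: G-quadruplex binding and condensate analysis with g4kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-quadruplex binding and condensate analysis with g4kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4kit)
```

This vignette documents the models, conventions and numerical choices
behind `g4kit`, the way a methods section would: what each procedure
assumes, which parameters matter and why their defaults are what they
are, what the synthetic generators do and do not emulate, and where the
package made a choice the underlying science left open.

## 1. The scientific setting

RNA G-quadruplexes (rG4s) are four-stranded RNA structures built from
stacked G-quartets: planar cycles of four guanines, each donating two
Hoogsteen hydrogen bonds (N1–H···O6 and N2–H···N7) to its clockwise
neighbor. Small, highly charged disordered proteins bind these
structures with sub-micromolar affinity and co-condense with them into
liquid droplets. Characterizing that system quantitatively requires a
chain of analyses — sequence-level binding preference (bind-n-seq),
binding isotherms (fluorescence polarization), droplet dynamics (FRAP,
single-particle tracking), and structural readouts from multi-chain
simulation trajectories (hydrogen bonds, contacts, clustering, density).
`g4kit` implements that chain with synthetic ground-truth generators in
place of the raw experimental data, so every stage is testable offline.

## 2. Hydrogen-bond and quartet detection

A hydrogen bond is a donor–acceptor pair within `d_max` (default 3.5 Å,
inclusive, compared at double precision with no epsilon) whose
donor–hydrogen–acceptor angle deviates from linearity by at most
`angle_dev_max` (default 30°, i.e. D–H–A ≥ 150°, the convention of the
standard trajectory-analysis toolkits). Hydrogens are located as H atoms
of the same residue within 1.25 Å of the donor; donors with no attached
hydrogen are skipped with a warning rather than silently matched, and a
distance-only mode (`require_hydrogens = FALSE`) exists for
hydrogen-free coarse models.

For Hoogsteen counting the donor set is N1/N2 and the acceptor set
N7/O6, restricted to guanine residues on both sides. One methods
description of this analysis also lists a guanine donor "O2"; guanine
has no O2 atom, and the expected count of an intact quartet (two bonds
per edge, 8 per quartet, 40 for five quartets) is reproduced exactly by
N1→O6 and N2→N7 donations alone. The package therefore reads that atom
as the ribose 2′-hydroxyl (O2′), excludes it from the default donor set,
and leaves it available as a criteria override; the fixture generator
can emit a minimal ribose proxy to exercise that override.

Quartets are detected as directed 4-cycles in the residue-level guanine
bond graph, each guanine claimed by at most one quartet (cycles are
claimed in a deterministic order keyed by residue identity). Stack
levels come from projecting quartet centroids onto their principal axis;
the axis is oriented so residue indices increase with level, a
deterministic convention that is invariant under rigid motion and atom
reordering. No periodic-boundary treatment is applied by default — the
fixtures are non-periodic — and no base-pair classification beyond
guanine–guanine Hoogsteen donation is attempted.

## 3. The ideal quadruplex fixture

`build_ideal_g4()` constructs coordinates, not physics: a planar
template guanine (idealized base geometry) is placed by a rigid 2-D
transform calibrated once — by least squares, with the resulting three
numbers frozen in the source — so that rotating the placed guanine by
90° about the quartet axis puts its O6/N7 acceptors exactly 2.90 Å from
the neighbor's N1/N2 donors. Donor hydrogens are then aimed exactly
along the donor→acceptor directions, making the D–H–A angles linear by
construction. Quartets stack with a rise of 3.4 Å and a twist of 30° per
step (typical parallel-quadruplex values), and within-strand residue
numbering uses an offset of 6 between stacked guanines, emulating the
i → i+6 stacking pattern of a five-quartet fold. The tetrameric topology
puts one guanine column on each of four strands; the dimeric topology
puts two columns on each of two strands. What the fixture does *not*
model: ribose/backbone torsions, the central cation channel, loop
nucleotides, and any energetics. A green test on this fixture
establishes that the detection criteria and the counting logic are
correct — not that any force field would hold the structure together.

## 4. Condensate networks

Two molecules are "in contact" when their minimum pairwise heavy-atom
distance is at or below 8 Å — the atom scope is a package convention,
since the source criterion states only the distance. Multivalency is the
degree distribution of the resulting bipartite protein↔RNA graph.
Crowder proximity counts each PEG molecule at most once per frame when
any of its atoms is within 6 Å of any protein or RNA atom (per-molecule,
not per-atom, counting). Hydrogen-bond occupancy is the fraction of
frames in which a residue pair forms at least one bond; it equals the
mean of the per-frame 0/1 indicator, which is exactly how the tests
recount it.

The radial density profile bins atoms into spherical shells about the
assembly center of mass (or a given point). Because "core diameter" has
no standard definition, the package states one: twice the outer edge of
the initial run of bins, scanning outward from the center, whose density
stays below 10% of the profile's peak. It is a documented, testable
convention — not a reconstruction of how any particular reported core
size was measured.

Conformational clustering follows the GROMOS/Daura procedure: pairwise
RMSD after optimal least-squares (Kabsch) superposition, then repeatedly
extract the frame with the most neighbors within the cutoff (default
0.2 nm) as a cluster center and remove it with its neighbors. Ties in
neighbor count break toward the lowest frame index, for determinism. The
default selection is the backbone heavy atoms of a single molecule
(falling back to all heavy atoms for bead models); whether the original
analysis clustered single molecules or whole assemblies is not stated,
and single-molecule selection is the package's default choice.

## 5. Dynamics

MSD uses overlapping windows: `MSD(l)` is the mean over all ordered
pairs `(t, t + l)`, pooled across molecules or tracks for ensemble
averaging. Overlapping windows make neighboring lags statistically
dependent; the package accepts this standard trade-off. Diffusion
estimates are either the point relation `D = MSD(t)/(2 d t)` — the 3-D
form `MSD/(6t)` — or an origin-constrained least-squares slope over a
lag range, with an unconstrained intercept variant for
localization-noise offsets. Dimensionality is always an explicit
argument carried by the profile, never inferred. Per-track estimates fit
the first 25% of each track's lags, the usual single-particle-tracking
compromise between bias (late lags) and noise.

Coordinates are Ångström internally (the native unit of the coordinate
formats); the dynamics layer converts to micrometers at its boundary, so
diffusion coefficients are in µm²/s throughout. The Förster conversion
uses `E = 1/(1 + (r/R0)^6)` with a default `R0` of 5.4 nm — a typical
value for a cyanine donor–acceptor pair, configurable because the
underlying study does not print its conversion parameters.

## 6. Bind-n-seq enrichment

The R statistic is position-level: the frequency of a k-mer among all
k-mer instances of the bound pool divided by its frequency in the input
pool. k-mers absent from the input are excluded by default (no smoothing
rule is stated in the source methods); a `+1` pseudocount over the full
4^k universe is available behind a flag. Pattern enrichment, in
contrast, is read-level: the fraction of bound reads in a class over the
fraction of input reads in that class, per the respective definitions.

The strong-G4 pattern `(G3–6 N0–7)4` is treated as a pattern *family*
with existence semantics: a sequence matches if *any* decomposition into
four G-runs (3–6 guanines) separated by loops of 0–7 nucleotides exists.
Loops may contain guanines and runs may abut, so a long G-tract can
supply several runs — a greedy regular expression is not equivalent and
is deliberately not the implementation; the matcher is a memoized
backtracking scan, validated against an exhaustive recursive enumerator.
Classification is three-way: `strong_g4` (pattern match, searched on the
randomized region plus adapters, which are part of the RNA presented to
the protein), `non_g4_control` (no match but ≥ 8 guanines in the
randomized region — the methods text says "greater than 8" where the
figure legend says "≥ 8"; the package defaults to ≥ 8 and makes the
threshold configurable), else `other`. The guanine count always uses the
randomized region only.

FOREST normalization subtracts the no-protein control per probe and
averages probes sharing a structure across barcodes, retaining negative
net intensities.

## 7. Curve fits

Both named models are fitted by nonlinear least squares (`nls`,
Gauss–Newton with up to 1000 iterations), with the strictly positive
parameters (`K_D`, `K`) log-parameterized so positivity is structural
rather than enforced by bounds. Starting values are derivative-free:
`K_D` starts at the concentration nearest half the signal span, `K` at
`ln2` over the time nearest half recovery. Fits are unweighted by
default (matching the common practice of the graphical fitting tools
used for such data); `1/Y²` weighting and a nonspecific linear term
(`+ NS·X`) are available behind flags but off by default, since only the
specific one-site model is named by the source. A numerically perfect
fit can terminate with a singular gradient; the package treats a
residual sum of squares at rounding level as converged. The recovery
halftime is reported as `ln2/K` exactly, so the identity
`t_half · K = ln 2` holds by construction, and the mobile fraction
`Plateau − Y0` is meaningful for full-scale normalized curves. FRAP
normalization is full-scale — `(I − I_bleach)/(I_pre − I_bleach)` with
the clock re-zeroed at the first post-bleach point — a stated
convention, as the source fits recovery without printing its
normalization.

## 8. Synthetic generators: what they emulate, and what a green test means

Every generator is seeded and bit-reproducible.

- **Quadruplex fixtures** (§3) make the geometric criteria true by
  construction; they validate detection, not stability.
- **Condensate frames** place coarse bead chains so each RNA has exactly
  the requested number of protein partners at an engineered minimum
  distance (7 Å, inside the 8 Å cutoff) while bystanders stay beyond
  10 Å, with crowders at a controlled 5 Å. Molecules then take rigid
  Gaussian steps of per-axis variance `2 D dt`. This validates contact,
  proximity and density bookkeeping; it has no excluded volume, no
  interactions, and contact counts are guaranteed only in the initial
  frame once diffusion is switched on.
- **Brownian tracks** are exact realizations of the model the estimators
  assume (i.i.d. Gaussian steps, variance `2 D dt` per axis), so
  parameter-recovery tests probe estimator bias and variance, not model
  misspecification.
- **Read pools** draw the randomized region uniformly over A/C/G/U and
  resample the bound pool with weights multiplicative in the enrichment
  factors of the motifs present. Under this selection model the measured
  k-mer R equals the factor only up to the mean-weight normalizer
  (`R ≈ f / E[w]`, a ~3% effect at default densities); tests therefore
  check both the exact reweighting expectation computed from the
  realized pool and proximity to `f`. The full 4-run pattern occurs at
  only ~10⁻⁴ in uniform 40-mers — roughly ten reads per 10⁵ — so
  pattern-level recovery is demonstrated with a 2-run member of the
  family (~3% class rate), where sampling error is a few percent; the
  reserved enrichment key `strong_g4` takes the pattern spec as a
  parameter for exactly this reason.
- **Curves** are the named models plus Gaussian noise scaled to the
  noiseless dynamic range, replicates differing only in noise.

## 9. Numerical conventions and degenerate inputs

Distance cutoffs are inclusive; no epsilon is applied at boundaries.
Frames must carry identical atom ordering throughout a trajectory, and
every operation preserves input ordering. The CSV trajectory dialect
writes doubles at 17 significant digits, so its round trip is bit-exact;
multi-model PDB round-trips to the format's 3-decimal precision, and
coordinates outside the fixed-column range (−999.999 to 9999.999 Å) are
a formatting error, not silently truncated. Degenerate cases error
loudly and early: empty trajectories, atom-count mismatches between
models, unmapped residue names (named in the message), unbleached FRAP
series (`I_pre = I_bleach`), selectors matching zero or multiple atoms.
Empty *selections* (a filter matching nothing) are valid results, not
errors. Molecule-kind inference uses a named residue→kind map covering
standard amino acids, ribonucleotides, PEG, K⁺/Cl⁻ and water; it is an R
named vector rather than a configuration file, and callers can extend or
replace it.

## 10. Known limitations

The package analyzes trajectories; it does not produce them (no MD
integration, force fields, or periodic-boundary imaging beyond an
optional flag). Sequence analysis has no error model, no UMIs, and no
quantitative G4 scoring beyond the binary pattern family. The
hollow-core estimator and the FRAP normalization are stated conventions
standing in for unpublished definitions, and the Förster radius default
is an assumption to be overridden when the dye pair is known. Statistical
comparisons between enrichment distributions (rank tests and the like)
are left to the standard library functions users already have.
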