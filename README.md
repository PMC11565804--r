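# g4kit

Quantitative analysis of protein–RNA G-quadruplex (rG4) binding and the
liquid–liquid phase transitions it drives. The package implements, as
tested reusable R code, the analysis pipeline of a study of a small
disordered protein that binds rG4 structures and co-condenses with them:

- **Quadruplex geometry** — detection of Hoogsteen hydrogen bonds
  (guanine donors N1/N2, acceptors N7/O6; 3.5 Å donor–acceptor cutoff,
  30° deviation from D–H–A linearity) and of G-quartets as directed
  4-cycles in the guanine bond graph, with stack-level assignment and
  stacking-offset reports. An intact quartet contributes 8 bonds; a
  five-quartet quadruplex, 40.
- **Condensate networks** — per-frame bipartite protein↔RNA contact
  graphs (minimum heavy-atom distance ≤ 8 Å), multivalency statistics,
  crowder (PEG) proximity within 6 Å, radial density profiles with a
  hollow-core diameter estimator, hydrogen-bond occupancy tables, and
  GROMOS/Daura conformational clustering at a 0.2 nm RMSD cutoff.
- **Dynamics** — time-averaged/ensemble MSD with overlapping windows,
  diffusion coefficients via the point relation `D = MSD(t)/(2 d t)`
  (`MSD/(6t)` in 3-D) or origin-constrained slope fits, per-track D
  distributions, end-to-end distances, and the Förster conversion
  `E = 1/(1 + (r/R0)^6)`.
- **Bind-n-seq enrichment** — the R statistic (bound/input k-mer
  frequency ratio), backtracking matcher for the strong-G4 pattern
  family `(G3–6 N0–7)4` with existence semantics, three-way pool
  classification (strong G4 / G-rich non-G4 control / other),
  read-level pattern enrichment, and FOREST barcode normalization.
- **Curve fits** — one-site specific binding
  `Y = baseline + Bmax·X/(KD + X)` and one-phase association
  `Y = Y0 + (Plateau − Y0)(1 − e^(−Kt))` with `t1/2 = ln2/K`, plus
  full-scale FRAP normalization.
- **Synthetic data** — generators with known ground truth for every
  input class: ideal stacked G-quartet coordinates (Hoogsteen geometry
  correct by construction), condensate frames with engineered contact
  counts and crowder placement, Brownian tracks at known D, randomized
  40-mer read pools with controlled enrichment, and noisy model curves.
- **Trajectory I/O** — multi-model PDB and an exact CSV trajectory
  dialect, with residue-name → molecule-kind inference.

## Worked example

```r
library(g4kit)

# idealized five-tetrad tetrameric quadruplex: 40 Hoogsteen bonds, 5 quartets
frm  <- build_ideal_g4(g4_fixture_spec(n_tetrads = 5))
count_hoogsteen(trajectory(list(frm)))
#>   frame time count
#> 1     1    0    40
length(detect_tetrads(frm))
#> [1] 5

# diffusion from a printed condensed-phase MSD: 6.4 um^2 at a 1 s lag, 3-D
prof <- structure(data.frame(lag = 1, msd = 6.4, n_pairs = 1),
                  ndim = 3, class = c("msd_profile", "data.frame"))
diffusion_from_msd(prof, method = "point", at_lag = 1)$D
#> [1] 1.066667

# K_D from a noisy fluorescence-polarization titration
conc <- 10^seq(log10(0.01), log10(10), length.out = 12)
cur  <- generate_curves("one_site", list(K_D = 0.30, B_max = 1, baseline = 0),
                        conc, noise_sd = 0.02, seed = 11)[[1]]
fit_one_site(cur)$parameters[["K_D"]]
#> [1] 0.2714197
```

The first block reproduces the reference counts for an isolated
five-tetrad quadruplex (40 bonds, 5 quartets). The diffusion value is the
3-D point relation applied to the printed average MSD. The last fit
recovers the generating dissociation constant (0.30 µM) to within the
noise of a single replicate; averaging 200 replicates recovers it to
within ~1% (see `analysis/05_curve_fitting.R`).

## Analysis workflow

Numbered drivers under `analysis/` reproduce the main analyses and write
tables under `results/`:

```sh
Rscript analysis/01_quadruplex_integrity.R   # Hoogsteen counts, tetrads
Rscript analysis/02_condensate_networks.R    # contacts, crowders, clustering
Rscript analysis/03_diffusion_dynamics.R     # MSD, per-track D, FRET
Rscript analysis/04_bindnseq_enrichment.R    # k-mer R, G4 pattern classes
Rscript analysis/05_curve_fitting.R          # binding and FRAP fits
```

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch through the installed
package, the study's desk-scale reference numbers: the Hoogsteen bond
count of the idealized five-tetrad fixture, and the mean recovered
dissociation constant and FRAP halftime over 200 noisy synthetic
replicates generated at the study's reported values. Run it from the
repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                   implementation
tests/testthat/      unit, property and acceptance tests (oracle helpers
                     in helper-oracles.R)
analysis/            numbered narrative drivers
scripts/acceptance.R acceptance recomputation
vignettes/           methods notes (model, conventions, limitations)
```
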