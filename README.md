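# statelipid

State-resolved protein–lipid interaction analysis for membrane-protein
molecular-dynamics trajectories.

## The problem

Pentameric ligand-gated ion channels (and membrane proteins generally) are
surrounded by annular lipids whose binding can depend on the protein's
conformational state.  Given MD trajectories plus a per-frame table of
discrete state labels (e.g. closed/open cluster assignments from a Markov
state model), `statelipid` computes the trajectory-side quantities used to
find and characterise lipid binding sites:

- **Contact statistics** — a residue *r* and lipid *l* are in contact in a
  frame iff min over atom pairs of the minimum-image distance ≤ 4 Å; maximal
  runs of contact frames give per-residue mean interaction durations, and
  the number of distinct contacting lipids gives exchange counts.
- **Lateral diffusion** — for disjoint first-shell (any atom within 4 Å of
  the protein at frame 0) and bulk lipid sets, the Einstein relation
  ⟨‖rᵢ(t) − rᵢ(0)‖²⟩ → 4·D·t is fitted to the lateral MSD with the protein
  centre-of-mass contribution removed; `rmsd_from_D(D, t) = √(4·D·t)`
  converts a coefficient to a root-mean-square displacement.
- **Occupancy densities** — per state, the fraction of frames in which each
  voxel lies inside an atom of a whole lipid found within 3 Å of the
  protein; thresholded at ≥ 40 % occupancy into binding-site densities,
  differenced between states, and scored for C5 symmetry.
- **Representative frames** — frames ranked by correlation between their
  instantaneous lipid density and a reference occupancy grid, selected
  greedily with at most 40 % of the picks from any single trajectory.
- **Pore-axis geometry** — radial lipid-approach minima, penetration
  fractions, residue–lipid minimum distances per state, and projection of
  scalars onto a 2D collective-variable landscape.

A bundled synthetic bilayer generator (C5-symmetric pseudo-protein, rigid
three-bead lipids with Brownian lateral dynamics, telegraph-process binding
sites gated by a state schedule) provides exact ground truth — diffusion
coefficient, mean residence time `1/k_off`, bound fractions — so every
estimator is testable without external data.  See
`vignettes/statelipid-methods.Rmd` for the full model description.

## Worked example

```r
library(statelipid)

cfg <- sl_synthetic_config(n_lipids_per_leaflet = 100, n_frames = 1000,
                           dt = 1, seed = 42)
sim <- simulate_bilayer(cfg)
sim$trajectory
#> <sl_trajectory> 'synthetic': 670 atoms x 1000 frames, dt = 1 ns

shells <- assign_shells(sim$trajectory, sim$topology, cutoff = 4)
length(shells$first_shell); length(shells$bulk)
#> 26 first-shell lipids, 174 bulk lipids

msd <- lateral_msd(sim$trajectory, sim$topology, shells$bulk, label = "bulk")
fit_diffusion(msd)
#> <sl_diffusion> bulk: D = 1.364 nm^2/us (slope 0.5457 A^2/ns, R^2 = 0.9979,
#>                window 100-499 ns)
```

The generator's bulk diffusion coefficient is 1.47 nm²/µs; the fit recovers
it from a single 1 µs trajectory of 174 bulk lipids to within sampling
error.  Contact durations at the five designated site residues (one per
subunit, mean residence 1/k_off = 50 ns):

```r
cs <- contact_series(sim$trajectory, sim$topology,
                     residues = sim$sites[c("chain", "resid")])
duration_stats(cs)
#>  chain resid resname mean_duration_ns n_runs n_lipids censored
#>      A     6     SIT         57.41176     17        2     TRUE
#>      B     6     SIT         60.87500     16        3     TRUE
#>      C     6     SIT         53.38889     18        2     TRUE
#>      D     6     SIT         39.44000     25        4     TRUE
#>      E     6     SIT         61.37500     16        3     TRUE
```

Each subunit's site residue shows mean interaction durations scattered
around the 50 ns ground truth, contacts from 2–4 distinct lipid molecules
(exchange), and a censoring flag because some runs touch the trajectory
ends.  The full pipeline — contacts, diffusion, state-resolved occupancy
grids (OpenDX/MRC), frame selection, pore-axis geometry, and a checksummed
manifest — runs from one call:

```r
run_pipeline(list(synthetic = list(n_lipids_per_leaflet = 60,
                                   n_frames = 600, box = c(120, 120))),
             out_dir = "demo_out", seed = 1)
```

or from the shell via the thin wrapper `inst/exec/statelipid`
(`statelipid run --config cfg.yaml --seed 1 --out demo_out`).

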