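---
title: "Methods: state-resolved protein-lipid interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-resolved protein-lipid interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statelipid)
```

## Scope and data model

`statelipid` analyses molecular-dynamics trajectories of a membrane protein
in a lipid bilayer, with each frame carrying a discrete conformational
state label (typically `closed` / `open`, as produced upstream by a Markov
state model; the labels are an *input*, this package never builds the MSM).
Around that state axis it computes the quantities used to discover and
characterise lipid binding sites:

* per-residue lipid **contact durations** and **exchange counts**;
* **lateral diffusion coefficients** of first-shell versus bulk lipids via
  the Einstein relation;
* state-classified **occupancy density grids**, their thresholded
  binding-site versions, state differences, and five-fold symmetry
  statistics;
* **representative frames** selected by density correlation;
* state-dependent **geometric analyses** around the pore axis.

Internally all lengths are Angstrom and all times nanoseconds; frames are
0-based; residue numbers are taken verbatim from input files.  Diffusion
coefficients are reported in nm^2/us (1 nm^2/us = 0.1 A^2/ns).
Coordinates live in plain arrays inside light S3 containers
(`sl_topology`, `sl_trajectory`, `sl_grid`), in the style of `bio3d`.

## Contact statistics

A residue and a lipid molecule are in contact in a frame iff the minimum
over all atom pairs of the minimum-image distance is at or below the
cutoff.  The default cutoff is **4 A over all atoms**; the minimum-image
convention is applied in x, y and z for orthorhombic boxes only.

Per (residue, lipid) pair, maximal runs of consecutive contact frames
define interaction durations.  `gap_tolerance` (default **0 frames**,
strict) merges runs separated by short losses of contact, counting the gap
into the duration; strictness is the reproducible default because any
smoothing choice is arbitrary.  Runs truncated by either trajectory end
are **included at their observed length and flagged censored** — long
interactions are then bounded by the trajectory length, which is the
honest reading when residence times approach the simulated time.  Exchange
is the number of distinct lipid molecules with at least one contact frame
at the residue.

Ensembles are aggregated by arithmetic mean over trajectories, matching
residues by `(chain, resid)`; with `pool_subunits = TRUE` the chains of a
symmetric oligomer are pooled as independent samples, which shrinks the
standard error by about the square root of the number of subunits.

## Lateral diffusion

Shell membership is fixed at the reference frame (frame 0): a lipid is
first-shell iff any atom lies within 4 A of any protein atom there; the
two sets are disjoint and are *not* re-assigned when lipids exchange
shells mid-trajectory.

The mean-square displacement uses the lateral (x, y) components of
unwrapped lipid centres of geometry, with the protein's lateral
centre-of-geometry displacement relative to frame 0 subtracted from every
lipid position (removing collective drift).  If no unwrapped coordinates
are stored, they are reconstructed by accumulating nearest-image per-frame
displacements; a displacement at exactly half the box is ambiguous and
raises an error.  All sliding time origins are averaged, computed exactly
with the FFT autocorrelation identity (order N log N); whether to use
multiple origins is a free choice and the standard sliding-origin average
was adopted and recorded here.

`D` is the slope of a free-intercept least-squares line through the MSD
restricted to a lag window, divided by 4 (two-dimensional diffusion).  The
window default is **10-50 % of the maximum lag**: early lags are dominated
by the ballistic/bead-resolution regime and late lags by origin starvation
noise; the window is configurable and echoed in the fit result.
`rmsd_from_D(D, t) = sqrt(4 D t)` converts a coefficient into the
root-mean-square lateral displacement over a time span.

## Occupancy densities

For each frame of one state, *whole* lipids with any atom within **3 A**
of the protein surface are selected, and every voxel whose centre falls
inside any selected lipid atom's sphere (per-atom van der Waals radius,
1.7 A for synthetic beads) is marked occupied.  The grid value is the
fraction of frames occupied, so values lie in [0, 1] and grids over
disjoint frame subsets combine as frame-count-weighted averages.  This
voxel-centre-inclusion definition mirrors occupancy-style volmap
semantics and yields the "fraction of frames" reading directly, rather
than an additive Gaussian density.

The grid spacing defaults to **1 A** (the reference spacing for such maps
is not standardised; 1 A resolves the 1.7 A beads without aliasing).
Thresholding keeps voxels with occupancy **at least** the level (default
0.4); the threshold is inclusive by decision, and lowering it (e.g. to
0.3) can only reveal a superset of voxels.  State differences are simple
voxelwise subtractions with operand states recorded in metadata.

Five-fold symmetry is scored by correlating a grid with its rotations by
k x 72 degrees about the pore axis (trilinear resampling), over the union
of nonzero voxels; the symmetrised grid is the mean over the five
rotations.  Grids are computed globally (all subunits at once) and the
symmetry comparison is applied to the global grid; a per-subunit variant
is available by passing per-chain selections.

## Representative frames

Each candidate frame's instantaneous (binary) lipid density on the
reference grid geometry is correlated with the reference occupancy grid
(product-moment, over the union of nonzero voxels).  Frames are then
accepted greedily in order of decreasing correlation, skipping frames
from any trajectory that has already contributed `floor(cap * n)` frames
(default cap 0.4, n = 100, i.e. at most 40 frames per trajectory).  The
cap is interpreted against the *requested* n, not the number selected so
far, and ties are broken by ascending trajectory id then frame index, so
the selection is deterministic.  Greedy selection matches the simple
published description; no global optimisation is attempted.

## Geometry around the pore axis

The pore axis is the membrane normal (z by convention) through the
protein centre of geometry; no automatic principal-axis alignment is done
(supply pre-rotated coordinates if the membrane normal is not z).  Radial
statistics report the minimum perpendicular distance of slab lipids to
the axis, optionally per azimuthal 72-degree sector anchored at the first
subunit; slab z-bounds are configuration, as no canonical values exist.
Penetration fractions count frames whose radial minimum is at or below a
threshold.  Residue-lipid minimum distances and their per-state contact
fractions (threshold 3 A) quantify state-gated interactions.  A scalar
series can be projected onto a 2D collective-variable landscape as
per-bin means with empty bins flagged; the landscape itself (free
energies, bin placement) is an input, never recomputed.

## The synthetic generator

The generator produces the ground-truth-bearing system every estimator is
tested against.  It emulates:

* a **C5-symmetric pentamer**: five identical subunits of surface-bead
  rings at four membrane depths (radius 15 A), one pore-lining gate bead
  per subunit that moves radially outward in `open` frames, and one
  recessed "site residue" bead per binding site;
* a **two-leaflet bilayer** of rigid three-bead lipids (head at the
  leaflet plane, two tail beads toward the midplane) that move laterally
  as units; leaflet z positions are fixed;
* **lateral Brownian motion** with per-axis step variance `2 D dt`
  (default D = 1.47 nm^2/us, a POPC-like bulk value), periodic in x, y
  only, with radial reflection off a cylindrical exclusion zone at the
  protein;
* **telegraph-process binding sites**: a free lipid whose head enters a
  site's lateral capture radius binds with probability
  `1 - exp(-k_on dt)` per frame if the site is active in the current
  state and unoccupied; bound lipids are held at the site anchor plus
  0.5 A Gaussian jitter and unbind with probability `1 - exp(-k_off dt)`.
  Sites hold one lipid at a time, which makes residence times exactly
  exponential with mean `1/k_off`; a lipid released in a step cannot
  rebind in the same step, so binding events and contact runs correspond
  one-to-one.  When a state change deactivates a site, its occupant is
  released immediately (flagged `gated`, excluded from residence-time
  statistics);
* a **state schedule** of labelled frame ranges that both gates site
  availability and drives the gate beads, so a purely geometric
  classifier can recover the schedule.

Site geometry is arranged so that ground truth is unambiguous: the site
residue bead is recessed 3 A into the protein wall and free lipids are
excluded beyond 1.5 A from the surface, hence only a *bound* lipid (at
the anchor, 2 A from the site bead) can come within the 4 A contact
cutoff of a site residue.  The default simulation is 1000 frames at 1 ns
per frame with 100 lipids per leaflet in a 140 x 140 A patch.

What the generator does **not** emulate: internal lipid conformational
dynamics, membrane undulations and flip-flop, protein motion beyond the
discrete gate schedule, crowding between lipids, and realistic force
fields.  Passing tests therefore demonstrate estimator correctness
(parameter recovery against known kinetics and diffusion), not fidelity
of any particular biological system.

Two measurement subtleties follow from the discrete-time kinetics.
Bound intervals are geometric in frame counts with mean
`dt / (1 - exp(-k_off dt))`, about `1/k_off + dt/2`, so duration
estimates carry an O(dt/2) discretisation offset that is far inside the
15 % recovery tolerance used in the tests.  And when the distributional
shape is tested against `Exponential(k_off)`, the frame-quantised
durations are first "dejittered" by drawing the within-frame event offset
from its exact truncated-exponential conditional, which makes correctly
generated intervals exactly exponential — the Kolmogorov-Smirnov check
then probes the kinetics rather than the frame grid.

## File formats

PDB (single and multi-model) is read through `bio3d`; GRO, OpenDX and
MRC/CCP4 (mode-2 float32) are read and written by compact readers and
writers in this package, each round-tripping within format precision
(1e-3 A for PDB coordinates, 1e-5 for grids).  DCD is read through
`bio3d`; XTC is not supported — convert to DCD or multi-model PDB.  Both
grid writers store the origin as the centre of the first voxel and an
isotropic spacing in Angstrom, and a single-voxel test pins the axis
order convention (x fastest in MRC, z fastest in OpenDX text) to the same
in-memory layout.  Lipid identity is inferred from a configurable residue
name list (POPC and friends by default), so phosphatidylglycerol or
ethanolamine systems are supported by configuration alone.

## Problem sizes and reproducibility

The bundled tests and the acceptance script run synthetic systems of
120-400 lipids and 600-4000 frames; these sizes were chosen so that the
statistical tolerances (10 % for diffusion recovery at >= 200 lipids and
>= 1000 frames, 15 % for residence recovery at >= 200 binding events)
have comfortable margins under the estimators' sampling variance.
Simulations are exactly reproducible for a fixed seed, and the pipeline
writes a manifest of parameters and output checksums so that a rerun with
the same configuration and seed is byte-identical.

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* Shell membership and grid geometry are fixed at a reference frame; a
  drifting protein is handled for MSD (COM removal) but not for the grid
  frame, so centre the protein before occupancy mapping.
* The per-lipid-atom contact fingerprint is available only as the raw
  pair-count table (`contact_series` contains the full boolean array);
  no per-atom visualisation is provided.
* Pose clustering of selected frames is out of scope; the selection
  itself (ranking plus per-trajectory cap) is provided.
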