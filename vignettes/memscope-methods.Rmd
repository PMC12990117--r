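---
title: "Methods behind memscope: surfaces, networks, WHAM and kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind memscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscope)
```

memscope analyses coarse-grained simulations of stacked lipid bilayers
interacting with amphiphilic ions. This vignette explains the models and
procedures it implements, the conventions it fixes where the underlying
methods leave room, and what the synthetic-data validation does and does
not demonstrate. Units are nm, ps and kJ/mol throughout.

## The two-bilayer geometry

The systems of interest contain **two** bilayers in a periodic orthorhombic
box, so that a genuinely *internal* aqueous compartment exists: with a
single bilayer, ions added on one side reach the other side trivially
through the periodic image, whereas with two bilayers the internal solution
is reachable only by actually crossing a membrane. Going up the z axis from
the periodic boundary (which lies in the external solution by convention),
the four leaflets are labelled `b1_external`, `b1_internal`, `b2_internal`,
`b2_external`, and the box decomposes into external solution, bilayer 1,
internal solution, bilayer 2.

### Leaflet height fields

Each leaflet's phosphate beads are interpolated into a single-valued
periodic height field z(x, y):

1. phosphate (x, y) points are augmented with **periodic ghost images**
   within a margin of the box boundary (default `2·sqrt(LxLy/n)`, which
   covers quasi-uniform point sets);
2. the augmented set is Delaunay-triangulated (Bowyer–Watson); exact-lattice
   cocircular degeneracies are broken by a deterministic jitter of relative
   amplitude 1e-8 — far below the 1e-3 nm precision of GRO coordinates;
3. the piecewise-linear (barycentric) interpolant is sampled on a regular
   nx × ny grid. Default resolution is `ceiling(sqrt(2n))` capped at 128,
   about two grid nodes per data point: finer grids add no information,
   coarser ones blur the undulations.

Any grid node not covered by a triangle is a hard error (it indicates an
insufficient ghost margin), and collinear input is rejected. Surfaces are
single-valued by assumption: overhangs and pores are out of contract.

**Leaflet assignment** sorts phosphate z values and cuts the circular
sequence at the four largest gaps. A separability guard requires the 4th
largest gap to exceed twice the 5th largest; merged leaflets therefore fail
loudly with gap diagnostics rather than silently mis-partitioning. Which
gap is the external solution is fixed by a user-supplied coordinate
(`external_z`, default 0, the box face), because no intrinsic property of
the geometry distinguishes external from internal.

### Morphology metrics and conventions

* **Surface area** sums the 2·nx·ny triangles tiling the periodic height
  field. It is bounded below by Lx·Ly with equality exactly for flat
  fields; a sinusoid of amplitude 2 nm over a 20 nm box agrees with 1-D
  quadrature to 0.03% at 64 × 64.
* **Thickness** is the node-wise *vertical* (z) separation of two leaflet
  grids, periodic-minimum, averaged over nodes. A surface-normal distance
  would differ on strongly tilted patches; the vertical convention is the
  simplest consistent reading and is stated here as a documented choice.
* **Compartment volumes** cut each grid column's periodic z extent by the
  four interpolated heights; interval lengths times the cell area give
  volumes that sum to the box volume *identically*, so the volume-closure
  test checks the column bookkeeping, not a numerical tolerance. Crossing
  surfaces (a negative interval) name the offending column.
* **Compartment assignment** of a particle interpolates the four heights
  bilinearly at the particle's (x, y) and locates its z interval.

### The reaction coordinate ξ

ξ is the signed z offset from a bilayer's midplane (the mean of its two
leaflet grid means, per frame), periodic-minimum, with the sign chosen so
that **negative ξ points toward the external solution**. The midplane is
global per frame rather than column-local — profiles therefore mix
undulation into ξ at the undulation amplitude scale, which is the standard
convention for planar-membrane profiles; a column-local variant would be a
curvature-corrected profile, which is out of scope. The bilayer normal is
fixed to z (planar geometry).

## Density, orientation and RDF profiles

Density profiles bin group reference sites (bead positions or per-molecule
centroids) in ξ and normalize by slab volume and frame count, so the
profile integrates exactly to the mean per-frame group count — an identity
the tests assert rather than approximate. Default bin: 0.05 nm.

Orientation profiles compute, per cation, the cosine of the angle between
the tail-centroid → head-centroid vector and the *outward* normal (+z
flipped by the side of the midplane the head sits on), so cos θ = +1 means
the polar head points away from the bilayer center. Values are binned by
head ξ (0.1 nm bins) and smoothed with a trailing 4-bin running mean, the
noise-reduction convention also used for the concentration series.
Zero-count bins stay NA; molecules with coincident centroids are skipped
and counted.

RDFs use minimum-image distances, shell normalization `4πr²·dr·ρ_B`, and
exclude self-pairs for overlapping groups (0.01–0.05 nm bins). The
`first_minimum()` detector smooths over 3 bins, finds the first *prominent*
local maximum — at least half the global maximum, which rejects noise
wiggles in the excluded-volume region where g ≈ 0 — and returns the first
local minimum after it. That value (0.7 nm for the tail–tail RDFs of the
systems this package targets) is the contact cutoff used below.

## Contact graphs and centralities

Nodes are whole molecules (cations, or lipids); an edge joins two molecules
when **any tail bead of one is within the cutoff of any tail bead of the
other**. Heads and phosphates identify the molecules but do not define
contacts: aggregation of amphiphiles is a hydrophobic-tail phenomenon, and
using the same tail-site rule for lipids keeps the two networks comparable.
Neighbor search uses a cell list with cell edge ≥ cutoff (exact brute-force
fallback below 400 beads or when fewer than 3 cells fit an axis); both
paths are tested to return identical pairs.

Degree is the incident-edge count over *all* nodes of the kind, isolated
ones included. Closeness uses the reachable-set convention: for a node with
r reachable nodes (itself included) and shortest-path sum S,

    closeness = ((r − 1)/(n − 1)) · ((r − 1)/S),

which is 0 for isolated nodes, (n−1)/S on connected graphs, and 1 only for
a node adjacent to everything in a connected graph. On the disconnected
graphs typical of partly dispersed ions this scaling makes the value
directly interpretable as aggregation: dispersed cations score ≈ 0,
droplet members score near 1. Shortest paths and components are computed
with igraph; the suite cross-checks every value against an independent
hand-written BFS oracle on random graphs.

Time aggregation pools per-node per-frame values over a window (default
the final 20% of frames) and reports pooled means and histograms; whether
to average over frames first is a real choice, and pooling was chosen as
the default because the histograms of interest are pooled anyway.

## Umbrella sampling and WHAM

Windows carry a center ξ_j, a harmonic force constant k (1000 kJ mol⁻¹ nm⁻²
in the target systems, 46 windows spanning ξ = 0–4.5 nm), and the
time-ordered samples of ξ. WHAM solves

    p_b ∝ Σ_j n_j(b) / Σ_j N_j exp((F_j − w_j(ξ_b))/kT),
    F_j = −kT ln Σ_b p_b exp(−w_j(ξ_b)/kT)

by direct iteration in log space (stable against the enormous bias factors
far from a window's center), converging on max |ΔF_j| < 10⁻⁷ kJ/mol within
10⁵ iterations, with the residual trace kept for inspection. G = −kT ln p
is zeroed at the reference bin — the aqueous end by default, since ΔG
values are reported relative to solution. Empty bins are NA, never imputed.
kT defaults to 0.0083145 × 309 ≈ 2.569 kJ/mol (the target systems'
thermostat temperature; configurable). Default bins of 0.1 nm resolve the
0.05 nm biased-distribution width without starving the histograms; the
validation battery uses 0.05 nm.

Two degenerate limits anchor correctness: a single unbiased window must
reproduce direct Boltzmann inversion of its histogram exactly, and
duplicated windows must not move the profile.

**Window overlap matters.** The window free energies F_j are chained
through the overlap of adjacent biased distributions; with spacing much
beyond ~2σ of the biased width (σ = sqrt(kT/(k+U''))), the chaining error
accumulates as a random walk along ξ and the reconstruction degrades even
though each window is individually well sampled. The validation layouts
therefore space windows at ≈1.6σ, which is ordinary practice; this is a
property of umbrella sampling, not of the implementation.

**Bootstrap errors** divide each window's samples into five contiguous
blocks and compute one full WHAM profile per block index; the per-bin
standard deviation across the five profiles is the error bar. Contiguous
(time-ordered) blocks respect autocorrelation; resampling individual
points would not. Identical blocks give exactly zero error. Because a
whole reconstructed profile drifts coherently, per-bin errors are strongly
correlated: 1σ coverage fluctuates widely between realizations, and the
calibration check pools several independent realizations.

**Summaries.** `delta_g()` reads G at the global minimum, the bilayer
center, and the solution reference (nearest defined bin), reporting
water→minimum, water→center, and their difference — the barrier a
penetrating cation must pass at the bilayer center. `fit_linear()` is
ordinary least squares of ΔG on alkyl-chain carbon count.

## Diffusion and concentration kinetics

Unwrapping accumulates minimum-image frame-to-frame increments; a
displacement at or beyond half a box edge is ambiguous and errors with the
bead and frame. MSD uses every sliding origin; the sum over origins is
evaluated with the FFT autocorrelation algorithm (mean-centered per series
for conditioning), validated bin-for-bin against the naive O(T²) double
loop. D comes from the least-squares slope over 10–50% of the lag range —
skipping short-time behavior and the poorly averaged tail — divided by 2d;
d = 3 for free ions, d = 2 (xy) for lipids, whose diffusion in a bilayer is
conventionally lateral. Both are exposed because the choice scales D.
1 nm²/ps = 10⁻² cm²/s.

Concentration series assign each tracked molecule (anion bead, or cation
head centroid) to a compartment per frame — no dwell-time hysteresis — and
convert counts to mol/L via c = N/(0.6022·V[nm³]), using each frame's
compartment volumes. A trailing 12-frame running mean smooths the reported
series; raw counts are kept and always sum to the group size.

## The synthetic generators, and what the tests do and do not show

The generators emulate the *geometry and statistics* the analyses consume,
not the physics that produces them:

* `generate_two_bilayer_system()` builds exact phosphate sheets at
  z_center ± thickness/2 plus an integer-period sinusoidal undulation
  (exactly box-periodic, so analytic areas are exact quadratures), 8 tail
  beads per lipid pointing at the midplane, and lattice water restricted to
  the aqueous compartments. Defaults (0.64 nm² per lipid, 4 nm thickness)
  match fluid-phase DPPC at the coarse-grained scale; test systems use 64
  lipids per leaflet so that a hundred systems triangulate in seconds,
  while the code paths are size-independent.
* `place_ions()` plants the penetration regimes: dispersed solution ions
  (pairwise molecule separations > 1 nm, so a 0.7 nm cutoff sees only
  singletons), interfacial layers, micelles, and a core nanodroplet whose
  chain anchors sit on a 0.55 nm compact lattice — guaranteeing
  connectivity at the 0.7 nm cutoff by construction. Ground-truth labels
  (compartment, cluster) are returned out-of-band, never encoded in bead
  names.
* `brownian_trajectory()` draws Gaussian steps of variance 2·D·dt per axis
  and keeps wrapped and unwrapped coordinates; `sample_umbrella_windows()`
  is a Metropolis sampler of the analytically biased density (step size
  sqrt(kT/k), 10³-sample burn-in, ≈70% acceptance on the harmonic
  targets).

Passing the suite therefore demonstrates that the *analyses* are correct on
inputs whose answers are known: it says nothing about force fields,
equilibration, or whether real trajectories satisfy the single-valued
surface assumption. Real data with membrane pores, overhanging leaflets, or
ions straddling compartment boundaries for long times will exercise the
documented error paths (crossing surfaces, leaflet separability) rather
than produce silently wrong numbers.

## Numerical choices and edge cases

* GRO I/O: fixed columns, coordinates at 3 decimals (C `printf` rounding),
  velocities read and discarded, triclinic boxes rejected, byte-stable
  output.
* Minimum image: components in [−L/2, L/2); a separation of exactly L/2 is
  reported as −L/2 (half-open convention).
* Degenerate triangles (collinear circumcircle) are treated as
  all-containing and eliminated by the jitter; interpolation tolerates
  barycentric coordinates down to −10⁻⁹ for boundary robustness.
* WHAM underflow: bias factors are handled in log space; windows with no
  samples in range would make F_j undefined and are rejected by the
  histogramming.
* Validation problem sizes (64–144 lipids per leaflet, 20–24 windows of
  2 000–5 000 samples, 500 walkers × 10⁴ steps) were chosen so the full
  battery completes in about a minute while every estimate sits well inside
  its tolerance; all are parameters, not limits.

## Known limitations

* Surfaces are single-valued height fields: no pores, vesicles or
  overhangs.
* ξ uses the global per-frame midplane; no curvature correction.
* No MBAR/umbrella-integration estimators, no autocorrelation-time
  machinery beyond contiguous-block bootstrapping.
* Binary trajectory formats are not read natively; convert to multi-frame
  GRO first (the GRO path is the contract, and an external converter
  preserves it).
* Centrality extras beyond degree/closeness (betweenness, Katz,
  eigenvector) are not implemented; degree and closeness are the measures
  the downstream analyses use.
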