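---
title: "Lipid packing defects on triangulated leaflet surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid packing defects on triangulated leaflet surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defectmesh)
```

## The problem

Lipid packing defects -- contiguous interfacial patches where aliphatic
(hydrophobic) lipid material is exposed to the solvent instead of being
covered by polar headgroups -- regulate the binding of amphipathic peptides
and proteins to membranes. On a planar membrane they are classically
quantified on a regular square grid: every atom or bead is projected onto
the grid, grid cells within a bead's van der Waals radius acquire a value
determined by the bead's chemistry and depth, connected defect cells are
clustered, and the cluster-size distribution is fitted.

The size distribution of defects follows, to good approximation, a
single-exponential law

$$p(A) \;=\; c\, e^{-A/\pi}, \qquad A \text{ in } \mathring{A}^2,$$

a form consistent with a 2D percolation picture of transient,
non-interacting defects that coalesce. The decay constant $\pi$ (the
*defect constant*, units of square Angstrom) is interpretable as the
average defect size and is the package's central quantity.

Square grids require a planar (or perfectly spherical/cylindrical)
reference geometry. `defectmesh` removes that restriction by mapping the
coarse-grained configuration onto a *triangulated surface per leaflet*
reconstructed from the lipid positions themselves, so that membranes of
arbitrary shape -- buckles, vesicles, nanoparticles, fusion intermediates --
can be analyzed with the same defect rules.

## The pipeline

For each frame and each leaflet:

1. **Leaflet pools.** Lipids are clustered into leaflets as connected
   components of the anchor-bead proximity graph (minimum-image distances,
   default cutoff 15 A). The anchor bead is the glycerol-backbone bead
   named in the force-field descriptor (e.g. `GL2`). The proximity graph
   handles flat, buckled and closed geometries alike; undersized components
   are merged into the nearest leaflet, and a declared bilayer is reduced
   to exactly two pools.

2. **Oriented point cloud.** Each lipid becomes a point (its anchor) plus a
   unit normal from a local plane fit (PCA) over its `k = 12` nearest
   anchors, flipped where needed so every normal points toward the lipid
   tails. Neighbourhoods are completed across periodic faces with ghost
   copies; the ghost margin is sized from a first-pass nearest-neighbour
   spacing estimate so that face-adjacent lipids see exactly their
   minimum-image neighbourhood (this also makes the normals exactly
   invariant under rigid translation with box wrapping).

3. **Indicator-function surface reconstruction.** The oriented normals are
   splatted onto a periodic grid with a Gaussian kernel and the scalar
   indicator field (one on the tail side, zero on the solvent side) is
   obtained by spectrally inverting the Poisson equation
   $\nabla^2\chi = \nabla\cdot\vec V$ on the box (FFT). The iso-surface at
   the mean indicator value over the input points is extracted by marching
   tetrahedra. For an open (plane-like) periodic surface the periodic
   Poisson solution necessarily contains a compensating sheet half a box
   away; mesh components are therefore discarded when they are not
   supported by data (median vertex distance to the nearest input point
   above three anchor spacings) or carry less than 1% of the total area.

4. **Remeshing (division and smoothing).** The raw mesh is refined by
   long-edge subdivision (no edge longer than 4/3 of the target length,
   default 1 A), decimated by shortest-edge collapse down to the vertex
   count of a uniform equilateral tiling at the target edge length, and
   relaxed by iterative centroidal smoothing: each interior vertex moves
   toward the area-weighted centroid of its incident triangles with the
   displacement projected onto the local tangent plane, which preserves the
   surface shape and total area (observed area drift below 0.1%). Tiles
   end up near 0.43 square Angstrom, comparable to the 1 A cells of the
   square-grid convention the defect rules were calibrated against.

5. **Projection and tile values.** Every bead of every lipid is projected
   along the lipid's local surface normal (the average of mesh vertex
   normals within 5 A of the anchor) onto the mesh. Tiles whose midpoint
   lies within the bead's van der Waals radius of the projected footprint
   centre are touched; among touching beads the most solvent-proximal wins
   (ties: smaller radius, then smaller residue id). The tile value follows
   the established convention: polar bead 1 (no defect); aliphatic bead
   0.001 (shallow defect) when less than 4.5 A below the reference
   glycerol-level bead of its own lipid, 0 (deep defect) at or beyond
   4.5 A. Depth is measured along the outward normal, positive toward the
   tails. Tiles touched by no bead stay unassigned and are disregarded,
   so membrane inclusions never masquerade as large defects.

6. **Clustering and filtering.** Defect tiles (value < 1) sharing a mesh
   vertex are clustered into connected components; unassigned tiles never
   act as connectors. Clusters containing a tile on the open mesh boundary
   (the cut where the periodic surface is opened, or a genuine mesh edge)
   are removed, because such clusters are truncated by the box. The
   extraction cut is anchored to the circular mean of the lipid cloud, so
   the censoring -- like every other stage -- is equivariant under rigid
   translations.

7. **Fitting.** Surviving cluster areas are pooled over frames, binned
   (default width 5 square Angstrom), and $\ln p$ is regressed on the bin
   midpoint; $\pi = -1/\text{slope}$. The window can be searched over both
   bounds or, following the classical fixed-floor convention, pinned at
   the 15 square Angstrom lower bound with only the upper bound selected
   (`a_min_fixed = TRUE`); on clean exponential samples the fixed-floor
   variant has a somewhat lower error probability, because a free lower
   bound mostly adds selection noise, while for distributions contaminated
   above the floor the two-sided search is the safer default.

By default no distinction is drawn between shallow and deep defects (the
*overall* kind); per-kind analyses are available.

## The fitting window and regression diagnostics

The exponential law holds only in a restricted range: the smallest areas
reflect hard-sphere excluded volume (local order) rather than defects, and
the largest areas are undersampled. The lower bound therefore never drops
below 15 square Angstrom (configurable), and the upper bound never extends
past the first bin whose count drops below `min_count = 5` -- applying the
signal-to-noise truncation *contiguously* matters, because otherwise the
highest-$R^2$ rule reliably selects short, noise-dominated windows in the
sparse tail. Candidate windows must hold at least eight occupied bins; the
window with the highest $R^2$ among those whose fits pass all four
regression diagnostics is selected, and if none passes, the best-$R^2$
window is returned flagged.

The regression is weighted by bin counts. A Poisson count $N$ has
$\operatorname{Var}(\ln N) \approx 1/N$, so weighting by $N$ is the
inverse-variance choice; on exact exponential draws it roughly halves the
spread of $\hat\pi$ at $n = 10^4$ samples relative to the unweighted fit.
Plain least squares is available via `weighting = "none"`.

Four standard diagnostics validate each fit, with conventional textbook
cutoffs: residual-vs-fitted trend and scale-location trend (Spearman
$|\rho| < 0.5$), residual normality (Shapiro-Wilk at $\alpha = 0.01$),
Cook's distance (max $\le 4/n$) and leverage (max $\le 3p/n$, $p = 2$).
The reported uncertainty is one standard error of $\pi$ propagated from
the slope standard error; frame-block resampling is a possible
alternative estimator that the package does not currently implement.

## Curvature-sign domains

For geometries whose curvature is constant along one Cartesian direction
(a buckle invariant along $y$), the mesh is binned along the profile
direction, normals are area-averaged per bin, and the signed turning
between neighbouring bin normals -- $\langle \Delta \vec n_\text{out},
\hat t\rangle$, the discrete curvature of the profile curve -- classifies
bins into positive (J+), negative (J-) and flat (J0) domains. The sign
convention: J+ means the leaflet bulges toward its own solvent side
(convex as seen from the headgroups), so the crest of the upper leaflet of
a buckle is J+. Turnings within 2 degrees per neighbouring-bin pair count
as flat, bins are about 10 A wide, and isolated single-bin labels are
absorbed by their neighbours; these defaults were chosen once against the
analytic sign map of sinusoidal test surfaces. Closed cross-sections (a
cylinder seen along its axis) are detected automatically and binned by
angle instead of by a Cartesian coordinate. Each defect cluster is
assigned to the domain holding the majority of its area (exact ties go to
the curved domain), and the per-domain area lists feed the unchanged
fitting machinery. For closed or irregular surfaces without an invariant
axis the classification degenerates to a single overall domain.

## Mixtures: contact fraction and superposition

Mixing is monitored by the concentration-normalized contact fraction
$\phi$: for each lipid of type $a$, the fraction of type-$b$ lipids among
its anchor-bead neighbours within 11 A (minimum image), averaged and
divided by the global number fraction of $b$ among potential neighbours.
$\phi = 1$ under ideal mixing, identically 1 for a one-component membrane,
and $\to 0$ for complete demixing.

Because defects are local and non-interacting, the defect constant of a
two-component membrane follows from the pure-component constants by
superposition. The mixture defect-size density is the fraction-weighted
sum of the component exponentials with equal per-component normalization,
and the effective single-exponential constant is matched at a reference
area $A_0$ (default 50 square Angstrom, inside the fit validity window):

$$\pi_3 \;=\; \frac{f_1 w_1 + f_2 w_2}{f_1 w_1/\pi_1 + f_2 w_2/\pi_2},
\qquad w_i = e^{-A_0/\pi_i},$$

the inverse local log-slope of the mixture density at $A_0$. $\pi_3$ is
continuous and monotone in the fractions, symmetric, and always lies
between $\pi_1$ and $\pi_2$. Against a numerical oracle (a least-squares
single-exponential fit to the analytic mixture density over 15-100 square
Angstrom) the closed form agrees within 10% over $\pi \in [5, 50]$ and
fractions 0.1-0.9, with the largest deviations at extreme $\pi$ ratios
where the mixture is genuinely not single-exponential. Three or more
components are composed pairwise and flagged experimental.

## The synthetic fixture generator

Every test runs on fully synthetic membranes with known ground truth. A
minimal 4-bead lipid (polar head, polar glycerol-level reference bead, two
aliphatic tail beads stacked along the local inward normal) is placed on
flat, buckled, spherical or cylindrical lattices at 60 square Angstrom per
lipid, Martini-like bead radii of 2.64 A, and two noise scales: a rigid
per-lipid displacement (sigma 0.5 A, thermal diffusion) plus a small
independent per-bead jitter (sigma 0.2 A, conformational noise). The
per-bead jitter exposes thin tail slivers between neighbouring heads and
is the sole source of the small-defect background; with no planted
patches, the measured defect constant of this background is well below
5 square Angstrom, so it lies under the 15 square Angstrom fitting floor
and emulates the excluded-volume artifact region of real membranes.

Planted defects draw target areas from an exponential law with a known
constant and realize each one as concentric rings of small aliphatic beads
(radius 1.4 A) covering a disc whose outer radius matches the target area,
placed just above the head level so they win every contested tile; a tiny
on-surface anchor bead ties each patch into the leaflet bookkeeping
without perturbing the reconstruction. Realized cluster areas track the
drawn targets with unit slope to within a few percent; draws below the
one-bead minimum (about 6 square Angstrom) pile up at that size, below the
fitting floor. Defaults: 8 patches per leaflet per frame -- dilute enough
that patches rarely coalesce (a 30% leaflet-area budget is enforced), yet
800 samples accumulate over the standard 50-frame recovery run.

What the fixtures do *not* emulate: real conformational dynamics, tail
order parameters, lipid shape diversity, electrostatics, or correlated
defect dynamics between frames. Passing tests therefore demonstrate that
the geometry, assignment, clustering and fitting machinery is correct and
unbiased on membranes whose defect statistics are known, not that any
particular force field reproduces experimental defect constants.

## Numerical choices and determinism

* Reconstruction grid: cell size half the mean anchor spacing, splat
  kernel width one anchor spacing (support 2.5 sigma). Cells coarser than
  the anchor spacing fail the geometric accuracy targets on curved
  surfaces, which is why the default is finer than one might first guess.
* The grid is anchored to the circular mean of the cloud modulo the cell
  size, and the periodic extraction cut is rolled to the antipode of the
  circular mean (through the data-sparse half of the box), so the entire
  pipeline -- including the boundary censoring -- is exactly equivariant
  under rigid translations with box wrapping and under relabelling of the
  lipid storage order. Rotations, including axis-aligned ones, re-sample
  the fixed tetrahedral cell decomposition and reorder the greedy
  decimation, so they are only statistically invariant: individual planted
  clusters keep their areas to within tile-level discretization, but
  marginal sliver clusters near the percolation threshold can split or
  merge, and a fitted pi can move by a few percent between orientations.
* The greedy edge collapse sorts on quantized squared lengths so that
  last-bit floating-point noise cannot reorder near-ties and cascade into
  macroscopically different meshes.
* No stage uses random numbers; given identical inputs every result is
  bit-reproducible. Fixture generation is seeded and reproducible.
* Problem sizes used in the validation suite: the recovery fixture is
  3000 lipids over 50 frames (about 90,000 square Angstrom per leaflet,
  about 208,000 tiles at the default edge length); geometric checks use
  spheres and cylinders of radius 80-100 A.

## Known limitations

* Trajectory input is limited to multi-frame GRO and DCD (plus GRO/PDB
  topologies); compressed GROMACS formats (XTC/TRR) are not read.
* Leaflet assignment is per frame; lipids are not tracked across frames
  and flip-flop is invisible.
* Stalk-like topologies where leaflets merge are resolved by the proximity
  graph into whatever components it finds; each lipid's beads are only
  ever projected onto its own leaflet's mesh.
* The mixture closed form fixes the matching point $A_0$; strongly
  contrasting component constants make the mixture visibly
  non-exponential and any single constant approximate.
* The fit standard error reflects regression uncertainty only, not
  frame-to-frame correlation of the defect population.
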