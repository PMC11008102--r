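# defectmesh

Lipid packing defects — interfacial patches where the hydrophobic membrane
core is exposed to solvent — control the recruitment of amphipathic
peptides and curvature-sensing proteins to membranes. Their sizes follow a
single-exponential law,

```
p(A) = c · exp(−A / π),     A in Å²
```

whose decay constant **π** (the *defect constant*, interpretable as the
average defect size) is the standard quantitative descriptor. Established
tools measure it on a square grid and are therefore restricted to planar
membranes. `defectmesh` maps coarse-grained membrane configurations onto a
**triangulated surface per leaflet** — oriented anchor-bead point cloud →
indicator-function (Poisson) reconstruction on the periodic box → marching
tetrahedra → centroidal remeshing to a dense, near-uniform tiling — and
then applies the established defect rules on that mesh: bead projection
along local normals, van-der-Waals tile claiming with solvent-proximal
arbitration, polar/shallow/deep tile values (1 / 0.001 / 0, shallow–deep
split at 4.5 Å depth relative to the glycerol-level reference bead),
vertex-connected clustering, and removal of box-boundary clusters. This
makes defect constants measurable on buckled membranes, vesicles,
cylinders and other curved geometries, split by curvature-sign domain
(J+/J−/J0) where useful.

The package is aimed at membrane-simulation researchers working with
coarse-grained models (Martini-style force fields); it reads GRO/PDB
topologies and multi-frame GRO or DCD trajectories, plus a small YAML
descriptor of per-bead radii and chemistry.

Also included: a diagnostics-validated log-linear fitting procedure for π
(R²-driven window selection above the 15 Å² excluded-volume floor, with
residual, normality, Cook's-distance and leverage checks), a
concentration-normalized lipid contact fraction φ for mixing analysis, a
superposition predictor for mixture defect constants, and a fully
synthetic fixture generator with exact ground truth that the entire test
suite runs on — no external data needed.

## Worked example

Generate a synthetic flat bilayer with planted hydrophobic patches whose
areas are drawn from an exponential law with π = 20 Å², run the pipeline,
and fit the defect constant:

```r
library(defectmesh)

spec <- fixture_spec(geometry = "flat", n_lipids = 800, planted_pi = 20,
                     patches_per_frame = 6, seed = 7)
fx    <- generate_fixture(spec, n_frames = 10)
areas <- analyze_frames(fx$frames, fx$ff)      # per-cluster defect areas
fit   <- fit_defect_areas(areas$area, bin_width = 5, a_min_floor = 15)
#> Warning: fewer than 8 usable bins; window support relaxed to 3 bins
fit
#> Defect constant pi = 19.06 +/- 9.33 A^2
#>   window [15.0, 35.0] A^2, 4 bins, R^2 = 0.6760
#>   diagnostics: pass
```

`pi` is the fitted defect constant in Å² (the planted value was 20), with
a wide uncertainty at this deliberately small sample — about 120 surviving
clusters; the validation suite's standard run uses 3000 lipids over 50
frames and recovers the planted constant to a few percent. The reported
uncertainty is one standard error propagated from the log-linear slope;
the window is the selected fitting range, and the diagnostics line reports
the four regression checks. `areas` is a tidy table (frame, leaflet, kind,
area) that `write_area_tsv()` serializes.

The same machinery runs from the shell via the thin `exec/defectmesh`
script:

```sh
defectmesh synth   --geometry flat --n-lipids 800 --planted-pi 20 --seed 7 --out fix.gro
defectmesh analyze --topology fix.gro --forcefield fix.gro.ff.yaml --out areas.tsv
defectmesh fit     --areas areas.tsv --bin-width 5 --a-min 15 --out fit.json
defectmesh predict --pi1 17.5 --pi2 26.7 --frac 0.5
```

For real trajectories, point `--topology`/`--trajectory` at GRO/PDB + GRO/
DCD files and supply a force-field descriptor (a bundled Martini-style
example lives at `inst/extdata/martini_lipids.yaml`; adjust radii to your
parameter set).

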