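---
title: "Surface reconstruction and clinical scoring: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface reconstruction and clinical scoring: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermamesh)
```

This vignette is the package's own account of what it computes and why the
pieces are built the way they are.

## The scalar-volume model

A `scalar_volume` is a dense grid of finite samples with a strictly
positive physical step per axis and an origin. Grid coordinates are
0-based: index `(x, y, z)` sits at `origin + c(x, y, z) * spacing`. Slice
stacks are anisotropic in practice — in-plane pixel pitch of micrometres
against slice intervals of millimetres — so all interpolation happens in
index space and coordinates are scaled to physical units only when mesh
vertices are emitted. That keeps the case classification and the edge
parameter t independent of the units while vertices, areas and
displacement statistics come out in physical units.

Three loaders feed the same container: a minimal DICOM reader
(explicit-VR little-endian, single-frame grayscale), raster stacks
(PNG/BMP), and raw binary grids with a JSON sidecar. The DICOM reader
keeps only the pixel grid, the rescale pair (slope, intercept), and the
ordering/geometry attributes; every other element — names, IDs, dates — is
read past and dropped, so de-identification is structural rather than a
filtering step. Slices are ordered by position along the stack normal,
falling back to instance number and then file order; the z spacing is the
median slice-position difference, falling back to the slice thickness.
There is no installed R DICOM reader in this stack, so the parser is part
of the package; it deliberately covers only the subset its own writer
produces plus ordinary single-frame grayscale files, and it is paired with
a writer so that test series can be synthesized on the fly.

Window/level conversion to 8-bit rasters defaults to full-range min–max
normalization because reflectance-confocal intensities carry no calibrated
unit convention (nothing like Hounsfield units exists for them); an
explicit `c(center, width)` window is available when the caller knows
better. The mapping is monotone by construction, and a constant slice maps
to zero. When a whole volume is exported, one global window is used for
all slices so the axial intensity profile survives quantization.

## Marching cubes

Cells are classified with the corner order fixed in `R/tables-mc.R`
(corner 0 at the cell base, 0–3 counter-clockwise around the bottom face,
4–7 above); the same order drives sampling, the case index, and the
tables. The inside rule is `f >= Q`, so ties land on the inside — a
deterministic choice that matters only when the isovalue hits samples
exactly. The 256-entry triangle table is the standard published one
derived from the 15 classic base cases. Its known face-ambiguity cases are
accepted as-is (no asymptotic decider); the fixtures asserted to be
watertight were checked to avoid them, and the acceptance suite verifies
per-configuration triangle counts and vertex sets against an independent
implementation of the same classic tables. Where a crossed quad admits two
diagonals, published tables differ legitimately; for that reason
cross-implementation checks compare vertex sets and counts, never
triangle-by-triangle groupings.

Two vertex placements share that machinery:

* **linear**: `t = (Q - v_a) / (v_b - v_a)` along the crossed edge,
  clamped to the edge; if both endpoints equal Q, the midpoint is used.
* **midpoint** (accepted alias **median**): `t = 1/2` always — the
  geometric middle of the crossed edge, e.g. `(x + 1/2, y, z)` on an
  x-edge. The name reflects the placement at the median of the edge's
  endpoint coordinates; it is a geometric midpoint, not a statistical
  median. No per-vertex division is performed, which the extractor proves
  by counting interpolator divisions (`division_count`: one per unique
  crossed edge in linear mode, zero in midpoint mode).

Because the case table alone decides connectivity, the two modes produce
identical triangle counts, vertex counts and face graphs; only positions
move, by at most half an edge. The winding of the published table is
uniform, so orientation is fixed once at the table level (each triple
reordered so triangles are counter-clockwise seen from the normal side)
rather than flipped per triangle; a per-triangle geometric flip was tried
first and rejected because near-degenerate slivers could flip in one mode
only, breaking the mode-equivalence of connectivity.

Normals are central-difference gradients — exact for linear fields, with
one-sided differences at the grid boundary where the symmetric form is
undefined — interpolated along the crossed edge at the vertex position and
negated, so they point toward decreasing field values (outward, for
positive-inside signed-distance fields). A vanishing interpolated gradient
falls back to the triangle's geometric normal.

**Degenerate triangles.** When Q exactly equals a grid sample, linear
placement puts vertices on grid corners and some triangles collapse to
segments; these are dropped at emission and counted
(`degenerate_dropped`). This is the one situation where the two modes'
triangle counts can differ (midpoint placement never collapses), which is
why topology-equality checks use generic fixtures whose samples never hit
the isovalue exactly.

## Meshes

`deduplicate()` merges soup vertices within a tolerance of
`1e-9 × bounding-box diagonal` — vertices of shared edges are bit-identical
by construction, so the tolerance only absorbs float noise — keeping the
first-seen representative, averaging and renormalizing normals, and
preserving winding. `mesh_report()` gives the comparison metrics: triangle
and vertex counts, area, unique undirected edges, boundary edges, Euler
characteristic V − E + F, and watertightness (no boundary edges). STL
(binary, the interoperability default), OBJ and PLY (ascii) writers
round-trip through the matching readers; STL stores an unindexed soup, so
its reader recovers connectivity by exact-match deduplication.

Visual smoothness claims about the midpoint surface are deliberately not
asserted: no accepted scalar metric captures them, so the benchmark
reports max/mean vertex displacement between modes and leaves judgement to
the reader. Wall-clock timings are printed by `benchmark_modes()` but
never tested — they are hardware facts, not algorithm facts; the
division-count instrumentation is the portable statement of the midpoint
mode's arithmetic advantage.

## Synthetic volumes

`generate_volume()` supplies the study conditions for tests and
benchmarks: signed-distance spheres and tori (positive inside, so the
expected outward normal direction is known analytically), unions of two
spheres, linear ramps (on which central differences are exact — the
sharpest possible gradient test), and seeded smooth noise (Gaussian white
noise through three box-blur passes per axis, exactly reproducible from
its seed). Default fixture sizes are 17³–41×41×17 voxels: large enough
that all 15 base-case families occur, small enough that the full suite
(including an exhaustive 256-configuration sweep against an external
reference) runs in seconds. Fixture centers are slightly offset from the
grid so no sample lies exactly on the isosurface; grid-aligned spheres are
kept as a separate fixture precisely to exercise the tie/degenerate path.

These fields emulate the geometry of reconstruction — closed surfaces,
varying curvature, topology of genus 0 and 1, anisotropic spacing — but
not the statistics of real reflectance-confocal data: no speckle, no
depth-dependent attenuation, no motion artefacts. Passing tests therefore
establish algorithmic correctness of the reconstruction, not robustness to
acquisition noise.

## The clinical calculus

Severity scores E, I, D are integers in 0..4 and the area score P is an
integer in 0..6 per region; PASI is the weighted sum
`(E+I+D)·P·w` with weights 0.1/0.2/0.3/0.4 for head/upper/trunk/lower,
bounded by 72. The area-score bins follow the standard convention
(0 → 0; (0,10) → 1; then 20-point bins up to [90,100] → 6) and are
overridable, since variant bin tables exist. Efficacy categories cut
ΔPASI% closed-below at 90/60/30 — the conventional lesion-regression
thresholds — also overridable; closed-below means a patient exactly at a
threshold gets the better category.

ΔPASI% is undefined for a zero baseline and raises an error rather than
returning NaN. Reported percentages use half-up rounding to 2 decimals
(`round_half_up()`), matching clinical reporting style rather than R's
round-half-even.

The group tests work from summary statistics because that is what studies
print: Welch's unequal-variance t with Welch–Satterthwaite degrees of
freedom (chosen over the pooled Student form for robustness; the pooled
form is available via `pooled = TRUE`), and Pearson's chi-square without
continuity correction via `stats::chisq.test` (df = k − 1 for a 2 × k
table). Tests validate both against independent routes: `t.test` on raw
data with matching summaries, and the direct Σ(O−E)²/E formula.

One caution for users reproducing published arm summaries: a
mean-of-differences is not the difference-of-means when the cohort
changes, and printed tables sometimes mix the two. The package computes
exactly what it is given and reports unrounded p-values; it does not try
to reconcile inconsistent inputs.

## Numerical choices, in one place

* Inside rule `>=`; ties inside. Case index bit k set iff corner k inside.
* Linear t clamped to [0,1]; `v_a = v_b = Q` → midpoint.
* Dedup tolerance `1e-9 ×` bbox diagonal; 0 = exact matching.
* Boundary gradients one-sided; zero gradients fall back to face normals.
* Degenerate (vertex-coincident) triangles dropped and counted.
* Half-up rounding, 2 decimals, for all reported percentages.
* Smooth-noise generator: seed-fixed `rnorm` grid, 3 box-blur passes/axis.

## Known limitations

* Classic-table face ambiguities can, on adversarial data, produce
  non-watertight patches; no topological disambiguation is attempted.
* The DICOM subset excludes multi-frame/enhanced objects, compressed
  transfer syntaxes and big-endian files.
* JPEG export is not provided (no installed codec); PNG and BMP are.
* The CLI's config file is JSON.
* PASI inputs are operator-provided scores; the package does not segment
  lesions from images.
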