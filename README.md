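# dermamesh

Surface reconstruction of stacked skin-imaging slices by marching cubes —
with a division-free *midpoint* ("median") edge-interpolation variant — plus
the clinical evaluation calculus used in psoriasis treatment studies (PASI,
ΔPASI, ΔPASI%, itching scale, efficacy categories, group statistics).

## Who this is for

Researchers working with volumetric skin imaging (in-vivo confocal
microscopy, often called "skin CT", or any stack of grayscale slices) who
want to reconstruct the lesion surface as a triangle mesh, and who need the
standard severity/efficacy arithmetic of a psoriasis trial computed
reproducibly from per-patient scores and per-arm count tables.

## The algorithms

**Marching cubes.** A scalar volume f(X,Y,Z) sampled on a grid with spacing
(ΔX, ΔY, ΔZ) is swept cell by cell. Each cell's 8 corners are classified
against an isovalue Q (corner *inside* iff f ≥ Q), giving one of 256
configurations; a fixed lookup table derived from the 15 classic base cases
emits up to 5 triangles per cell, one vertex per crossed edge. Vertices are
placed either by

- **linear** interpolation, t = (Q − v_a)/(v_b − v_a) along the crossed
  edge — the classic placement, sub-voxel accurate; or
- **midpoint** placement at the geometric middle of the edge, e.g.
  (x + 1/2, y, z) for an x-edge — independent of the sample values and free
  of per-vertex divisions, which is what makes it fast. At slice spacings of
  a few millimetres the two placements differ by at most half an edge.

Per-vertex normals come from central differences,
qX = (f(x+1,y,z) − f(x−1,y,z)) / (2ΔX) (one-sided at the grid boundary),
interpolated along the crossed edge and oriented toward decreasing field
values. The two modes share classification and connectivity exactly: same
triangle count, same vertex count, same face graph — only vertex positions
move.

**PASI.** Four body regions (head, upper limbs, trunk, lower limbs) each
get severity scores E (erythema), I (infiltration), D (desquamation) in
0..4 and an area score P in 0..6; then

    PASI = (E+I+D)·P·0.1 |head + (E+I+D)·P·0.2 |upper
         + (E+I+D)·P·0.3 |trunk + (E+I+D)·P·0.4 |lower     ∈ [0, 72]

with ΔPASI = PASI_before − PASI_after and
ΔPASI% = 100·ΔPASI/PASI_before. Efficacy categories cut ΔPASI% closed-below
at 90/60/30 (cured / markedly effective / effective / ineffective), and an
arm's *total effective rate* is the percentage in the top three categories.
Group comparisons use Welch's t from summary statistics and Pearson's
chi-square without continuity correction.

## Worked example

```r
library(dermamesh)

# a synthetic sphere standing in for a scanned volume
vol <- generate_volume(field_spec("sphere", center = c(8.5, 8.3, 8.1),
                                  radius = 4.7), dims = c(17, 17, 17))
mesh <- deduplicate(extract_isosurface(vol, isosurface_spec(0, mode = "midpoint")))
mesh_report(mesh)
#> mesh_report: V=416 E=1242 F=828 (chi=2)
#>   area 299.618, boundary edges 0, watertight TRUE, degenerate dropped 0

# linear vs midpoint: identical topology, shifted vertices, no divisions
benchmark_modes(vol, 0)
#> mc_benchmark at isovalue 0
#>   triangles: linear 828, midpoint 828; vertices: 416 / 416
#>   seconds (informational): linear 0.0020, midpoint 0.0020
#>   interpolation divisions: linear 416, midpoint 0
#>   vertex displacement: max 0.484579, mean 0.26278

# the clinical calculus on an arm's printed summaries
delta_pasi(pasi_pair(28.25, 5.61))                  # 22.64
round_half_up(delta_pasi_percent(pasi_pair(28.25, 5.61)), 2)  # 80.14
total_effective_rate(group_outcome(71, 213, 32, 40))          # 88.76
welch_t_from_summary(3.03, 1.01, 356, 3.71, 1.06, 356)$p_value < 0.05  # TRUE
```

The report says the reconstructed sphere is a closed (watertight) surface
of genus 0 (Euler characteristic 2) with 828 triangles on 416 vertices; the
benchmark confirms the midpoint path placed every one of those vertices
without a single division while reproducing the linear mode's topology
exactly, each vertex moving less than half an edge.

A command-line wrapper ships in `inst/cli/dermamesh`
(`dermamesh simulate|extract|report|benchmark|pasi|efficacy`), installed
under `system.file("cli", "dermamesh", package = "dermamesh")`.

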