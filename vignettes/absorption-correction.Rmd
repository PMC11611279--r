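---
title: "Analytical absorption corrections by voxel ray tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical absorption corrections by voxel ray tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(voxtrace)
```

## The problem and the model

At wavelengths beyond about 3 Å, X-ray absorption by the sample becomes a
dominant systematic error in macromolecular crystallography. Spherical
harmonics corrections, the default in scaling programs, lean on data
multiplicity and fail for radiation-sensitive crystals in low-symmetry
space groups. The analytical alternative needs no multiplicity: given a 3D
model of the sample in which every voxel is labelled crystal, mother
liquor, loop or background (vacuum), the transmission of each reflection is
computed directly from Beer–Lambert attenuation.

For a reflection $\mathbf{h}$ the (inverse) absorption factor is the mean
transmission over the $N$ crystal voxels,

$$
A_\mathbf{h} \;=\; \frac{1}{N} \sum_{n=1}^{N}
  \exp\!\Big( -\sum_m \mu_m \,\big(L^{(1)}_{m,n} + L^{(2)}_{m,n}\big) \Big),
$$

where $\mu_m$ is the linear absorption coefficient of material $m$ (in
µm^-1^ here) and $L^{(1)}_{m,n}$, $L^{(2)}_{m,n}$ are the distances the
incident and diffracted beams travel through material $m$ on their way to
and from voxel $n$. Only crystal voxels diffract, so only they enter the
sum, but the path lengths accumulate over every material the rays cross.

The package computes the path lengths by ray tracing on the voxel grid,
with three interchangeable back-ends and optional subsampling of the
crystal voxels.

## Conventions

* Arrays are indexed `(z, y, x)` with `z` the slice-stacking axis; all
  direction vectors passed to geometry functions use this component order.
  Reflection tables use laboratory `(x, y, z)` columns (`ix..dz`), matching
  how direction tables are exported by processing pipelines; the package
  converts internally.
* Voxel centers sit at integer coordinates, 0-based; the cuboid occupies
  $[0, \mathrm{dim}-1]$ per axis. Whether the model bounds are taken at
  voxel centers or outer voxel edges is a free choice that shifts every
  path by at most one voxel; centers keep all arithmetic integer-exact at
  the start voxel.
* Default label codes are background 0, liquor 1, loop 2, crystal 3,
  overridable via `label_map`. Background always has $\mu = 0$.

## Standard back-end: driving-axis traversal

A ray from a crystal voxel is discretized along a single *driving axis*:
the axis of the face through which the ray exits the volume. One voxel is
recorded per integer step along that axis; the other two coordinates are
rounded to the nearest integer (half away from zero). Choosing the exit
face's axis guarantees every recorded coordinate stays inside the array
and that no interval is skipped; choosing a non-driving axis would
duplicate coordinates and corrupt lengths.

```{r}
vol <- segmented_volume(array(3L, dim = c(1, 3, 6)), voxel_size_um = 1)
rec <- traverse(vol, c(0, 0, 0), c(0, 2, 5), record_path = TRUE)
rec$path
rec$euclidean_length_voxels  # sqrt(29): distance start -> end voxel
```

The recorded path zigzags, so raw voxel counts overestimate oblique
lengths. `path_lengths()` corrects this by giving each material its
*proportion* of recorded voxels times the Euclidean start-to-end distance;
the per-material lengths then sum exactly to the geometric ray length.

Exit faces come from a slab-style ray–cuboid intersection: for each
outgoing face plane, $t_i = \hat n_i\cdot(x_i - P_0)\,/\,\hat n_i\cdot d$,
and the minimal non-negative $t_i$ names the exit face. Planes parallel to
the ray contribute no candidate. Ties at an edge or corner resolve to the
lowest face index in the fixed order `x-`, `x+`, `y-`, `y+`, `z-`, `z+`;
putting `x` first makes a corner-exiting ray split along the axis with the
finer stepping, which is what reproduces the worked single-slice example
above (`n = 5` intervals, not 2).

Traversal never stops early at vacuum: material beyond a vacuum gap (the
far side of a loop, for instance) still absorbs, so rays always run to the
model boundary. The incident path is traced from the diffracting voxel
*backwards* along the reversed incident direction; starting voxels are
counted in both rays, which affects lengths by at most one voxel.

Arithmetic is double precision by default; `precision = "single"` mirrors
FP32 GPU-style accumulation for speed/accuracy studies and typically
agrees to ~1e-6 relative.

## Bisection back-end

On samples whose materials are layered along each ray — crystal, then
liquor, then loop, then vacuum, with no vacuum pockets inside the sample —
stepping every voxel is wasteful: the label sequence is a handful of runs.
`bisection_path_lengths()` finds the run boundaries by bisection on the
same discretized ray (`label_at()` uses the identical rounding rule), at
$O(\log_2 n)$ label queries per boundary instead of $O(n)$ steps:

1. crystal outer boundary (the ray starts inside the crystal, so only the
   outer limit exists);
2. air boundary, separating the sample from the surrounding vacuum;
3. loop inner and outer boundaries, bracketed between the two.

The mother liquor is deliberately *not* searched: liquor pockets between
crystal and loop vary in size and position, so its length is obtained by
subtracting crystal, loop and vacuum from the total — which also makes the
per-material lengths sum exactly to the ray length. A material absent
along a ray (e.g. no loop through the mount's opening) is flagged and gets
length zero. If vacuum does occur inside the bracketed sample region the
run structure is not monotone, boundaries can land a few steps off, and
the routine warns; this is the method's documented inaccuracy, not an
error.

## Gridding back-end

When many reflections (or several datasets on the same model) are
processed, many rays point in nearly identical directions. For each
sampled crystal voxel the package precomputes a (360, 180) grid of
*one-way* exponents $\sum_m \mu_m L_m(\theta, \varphi)$ at 1° spacing
($\theta$ azimuth about z, $\varphi$ polar from +z), using the standard
traversal for every node. A reflection then costs two nearest-neighbour
lookups per voxel — reversed incident plus diffracted — and an
exponential.

To keep nearest-neighbour queries safe at the seam ($\theta = 0/360$) and
the poles, grids are padded to (420, 210): 30 azimuth columns per side
wrap modulo 360°, and 15 polar rows per side mirror across the poles with
a 180° azimuth shift. The printed padded shape forces those widths. At the
south pole the exact mirror of row $\varphi = 180°$ would be the
nonexistent row 180 itself, so it clamps to 179 — a ≤ 1° approximation at
a point where all azimuths converge anyway.

Queries landing exactly on a node return the node value unchanged, so
node-aligned reflections reproduce the standard back-end bit for bit; the
off-node error is bounded by the variation of the exponent across one grid
cell. That variation is small for smooth, sphere-like samples and largest
where a 1° rotation swings the ray across a long edge (elongated rods) —
the known failure mode of nearest-neighbour gridding. One grid is 360 ×
180 doubles ≈ 0.5 MB; at full sampling on realistic models this is
unfeasible memory, which is why gridding is paired with sampling, and the
builder refuses plans above a configurable memory budget (default 2 GiB).

## Sampling strategies

`sampling_plan()` subsamples the row-major-sorted crystal-voxel list:

* **systematic** — every k-th voxel, $k = \mathrm{round}(1/\mathrm{ratio})$
  (a 0.05% ratio strides every 2000th voxel). Deterministic, spatially
  even; the default at ratio 0.5%.
* **randomized systematic** — one uniform draw per interval; same plan
  size, seedable.
* **random** — uniform without replacement.
* **stratified** — k-means over the features (z, y, x, distance to the
  crystal centroid), one selected voxel per cluster (the one nearest its
  centre). Single initialization from the seed, at most 300 iterations;
  clusters are recomputed once per dataset, not per reflection. Distance
  to centroid is kept in voxel units with unit weight — no feature
  weighting is assumed.

Random and randomized-systematic are retained for comparison studies even
though systematic (and stratified, for compact near-spherical crystals)
are the practical choices. Ratio 1 reproduces the unsampled factors
bitwise for every strategy, because selections are kept in the same sorted
order the full enumeration uses.

`sample_report()` quantifies fidelity the same way the method was
validated: per-voxel linear factors $\exp(-\text{exponent})$ for one
reflection at 100% sampling are compared with each sampled subset by the
two-sample Kolmogorov–Smirnov test. The statistic falls (and the p-value
rises) with the sampling ratio:

```{r, fig.width = 6, fig.height = 4}
vol <- make_phantom("sphere", 8, shells = c(3, 2), volume_dims = c(32, 32, 32))
mu <- material_coefficients(preset = "thaumatin")
rep <- sample_report(vol, mu, random_reflections(1, seed = 1),
                     ratios = c(0.02, 0.05, 0.1, 0.25, 0.5), seeds = 1:10)
autoplot(rep)
```

## The phantom generator

Real inputs are segmented tomograms (~10^9 voxels at 0.3 µm); tests and
examples use synthetic phantoms that keep their essential structure at
desk scale: a crystal body — sphere (insulin-like), rod
(thermolysin-like) or bipyramid (thaumatin-like habit) — a concentric
liquor shell, a loop shell open on the +y side with the liquor drop
bulging through the opening, vacuum elsewhere, and ≥ 1 voxel of background
margin at every face. The bulging-drop choice is deliberate: it keeps the
sample's outer surface convex, so no ray from a crystal voxel meets vacuum
strictly between crystal and loop, and the bisection back-end's layering
assumption holds exactly on noiseless phantoms. An optional
label-flip noise rate emulates segmentation errors (and deliberately
breaks that assumption).

What phantoms do **not** emulate: segmentation artefacts with spatial
structure (rings, streaks), anisotropic voxels, partial illumination, and
the sheer voxel counts of real reconstructions. Passing tests on phantoms
therefore validate the geometry and the numerics of the engine, not the
segmentation quality of any particular experiment.

Default phantom conditions used throughout the tests: 32³ voxels at
0.3 µm, crystal radius 8, shells 3 (liquor) and 2 (loop) voxels — large
enough that all four materials appear on typical rays, small enough that
brute-force oracles (dense 10^-3^-voxel marching, full linear scans, full
enumeration over all crystal voxels) run in seconds. Absorption
coefficients come from the measured presets (`insulin`, `thermolysin`,
`thaumatin`, in µm^-1^ at their collection wavelengths).

## Numerical choices and degenerate inputs

* Rounding of non-driving coordinates is half-away-from-zero, fixed, so
  recorded paths are platform-stable and reproduce the worked example's
  pixel pattern.
* On-face tolerance for exit tests is 10^-9^ voxels; rays parallel to a
  face simply contribute no candidate plane.
* A backscattering reflection (diffracted antiparallel to incident) is
  legal and needs no special casing — the two traversals simply retrace
  the same line.
* Zero-length selections, zero direction vectors, non-crystal start
  voxels, unknown label codes and out-of-range ratios all error early
  with the offending value named; direction norms in [0.99, 1.01] are
  renormalized, anything else is rejected.
* Worker parallelism chunks reflections; each reflection's factor is
  computed independently, so results are bitwise identical for any worker
  count.

## Known limitations

* The bisection back-end is only as good as the layering assumption;
  internal vacuum bubbles degrade it by design.
* Nearest-neighbour interpolation (no bilinear/spline option) can be
  biased for elongated crystals where the exponent varies steeply between
  adjacent nodes.
* "Exposed to the beam" is taken as *all* crystal voxels; beam-profile
  weighting and partial illumination masks are out of scope.
* HDF5 volumes are not read directly; convert to NPY or a TIFF stack.
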