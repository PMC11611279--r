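# voxtrace

Analytical absorption corrections for long-wavelength macromolecular
crystallography, computed by ray tracing through a segmented voxel model of
the sample.

At wavelengths beyond ~3 Å, absorption by the crystal, its mother liquor
and the mounting loop is a dominant systematic error, and the usual
spherical-harmonics correction breaks down when data multiplicity is low
(radiation-sensitive crystals, low-symmetry space groups). Given a
tomographic reconstruction in which every voxel is labelled
crystal / liquor / loop / background, plus per-material linear absorption
coefficients, voxtrace computes the per-reflection (inverse) absorption
factor

    A_h = (1/N) * sum_n exp( - sum_m mu_m * (L1_{m,n} + L2_{m,n}) )

— the mean Beer–Lambert transmission over the N crystal voxels, where
L1/L2 are the incident and diffracted path lengths through each material m
and mu_m its coefficient (µm⁻¹). The factors are written as an ordered JSON
array for use by downstream scaling programs.

Three interchangeable path-length back-ends are provided:

* **standard** — per-voxel traversal along each ray's driving axis, with a
  zigzag correction scaling per-material voxel counts to the Euclidean ray
  length;
* **bisection** — O(log n) boundary search per ray for layered samples
  (crystal / liquor / loop / vacuum), liquor by subtraction;
* **gridding** — per-voxel (360, 180) grids of one-way attenuation
  exponents at 1° spacing, padded to (420, 210), answered by
  nearest-neighbour lookup; build cost amortized over many reflections.

Crystal voxels can be subsampled (systematic, randomized-systematic,
random, or stratified k-means plans), with two-sample Kolmogorov–Smirnov
diagnostics of sampling fidelity. A phantom generator produces synthetic
segmented volumes (sphere / rod / bipyramid crystal, liquor shell,
half-open loop) for validation; the ray-tracing core is compiled (Rcpp).

## Worked example

```r
library(voxtrace)

vol  <- make_phantom("sphere", 8, shells = c(3, 2), volume_dims = c(32, 32, 32))
vol
#> <segmented_volume> 32 x 32 x 32 voxels (z, y, x) @ 0.3 um
#>   background code 0: 23440 voxels
#>   liquor     code 1: 5296 voxels
#>   loop       code 2: 1856 voxels
#>   crystal    code 3: 2176 voxels

mu   <- material_coefficients(preset = "thaumatin")  # µm^-1 at 4.13 Å
refl <- random_reflections(100, seed = 42)
plan <- sampling_plan(vol, "systematic", ratio = 0.05)
plan
#> <sampling_plan> systematic, ratio 0.05: 109 of 2176 crystal voxels

res <- refl |> absorb(vol, mu, method = "standard", plan = plan)
glance(res)
#> # A tibble: 1 × 8
#>   n_reflections method   sampling_method ratio n_voxels A_min A_mean A_max
#>           <int> <chr>    <chr>           <dbl>    <int> <dbl>  <dbl> <dbl>
#> 1           100 standard systematic       0.05      109 0.864  0.871 0.879
```

Each row of `res` is one reflection in input order; `A` is its transmission
factor (here ≈ 0.87: this phantom absorbs ~13% of the diffracted
intensity, varying by a little over 1% with direction). Sampling 5% of the
crystal voxels reproduces the fully enumerated factors to better than 1%
(`max |A_sampled - A_full| / A_full = 0.0094` on this example).
`write_factors(res, "factors.json")` emits the ordered JSON array plus a
metadata block (back-end, sampling settings, volume checksum) that makes
the run reproducible.

The other back-ends are drop-in replacements
(`method = "bisection"`, `method = "gridding"`), `autoplot(res)` draws the
factor histogram, and `sample_report()` + `autoplot()` produce the
KS-vs-ratio fidelity diagnostic. A thin command-line front end with
`correct`, `phantom` and `sample-report` subcommands is installed under
`inst/cli/voxtrace`.

## Layout

* `R/`, `src/` — implementation (R API over an Rcpp ray-tracing core)
* `tests/testthat/` — unit, property and acceptance tests with independent
  oracles (dense marching, linear scans, brute-force ECDF)
* `vignettes/absorption-correction.Rmd` — the methods vignette: model,
  conventions, back-ends, sampling, numerical choices, limitations
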