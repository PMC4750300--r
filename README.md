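# ciliometry

Measure primary cilium length in confocal Z-stacks — without the
projection bias.

Primary cilia (1–9 µm microtubule-based protrusions) are usually measured
on the maximum intensity projection (MIP) of a fluorescence Z-stack. That
works for cilia lying in the imaging plane, but most cilia are tilted out
of it, and a projection measures only `L·cos(elevation)` — angled cilia
are systematically underestimated, and restricting analysis to flat cilia
trades that bias for a selection bias. `ciliometry` implements and
cross-validates the three measurement strategies for straight cilia, for
cell biologists quantifying cilium length and for method developers who
need a ground-truthed testbed:

* **MIP** — polyline length on the projection: `a` (µm).
* **PyT** — Pythagorean estimate `c = √(a² + b²)`, with
  `b = (z_last − z_first)·dz` the axial extent from the first/last slice
  showing signal. High-throughput; reduces exactly to MIP for
  single-slice cilia.
* **DAAS** — length measured directly on a vertical reslice of the volume
  along the cilium's in-plane direction (bilinear interpolation, original
  resolution), with automatic sub-pixel endpoint detection.

Around these sit a flat/angled classifier (flat = entire signal within 4
Z-slices), a synthetic-stack generator that renders straight cilia of
known 3D geometry under an anisotropic Gaussian PSF (the validation
oracle), and the method-agreement toolkit: two-way absolute-agreement
intraclass correlation ICC(A,1) with Landis–Koch interpretation,
Bland–Altman bias and 95% limits of agreement, and flat-vs-angled
t-tests.

## Worked example

Render a known cilium (3 µm at 60° elevation) and measure it three ways:

```r
library(ciliometry)

r <- render_cilium_stack("cil001", length_um = 3, elevation_deg = 60,
  azimuth_deg = 30, cfg = render_config(noise_sd = 0))
m <- measure_cilia(r$stack, r$annotations, replicates = 3)
average_replicates(m)
#> # A tibble: 3 × 6
#>   cilium_id method length_um length_range_um n_replicates classification
#>   <chr>     <chr>      <dbl>           <dbl>        <int> <chr>
#> 1 cil001    DAAS        2.96               0            3 ANGLED
#> 2 cil001    MIP         1.5                0            3 ANGLED
#> 3 cil001    PYT         2.92               0            3 ANGLED
```

MIP reports 1.5 µm — exactly `3·cos 60°`, the projection artefact — while
PyT and DAAS recover the true 3 µm within a few percent. The replicate
range is 0 because automatic endpoint detection is deterministic.

The full comparison protocol on a simulated cohort (31 flat + 31 angled
cilia with *identical* true lengths in both populations):

```r
co <- simulate_cohort(n_flat = 31, n_angled = 31, paired_lengths = TRUE, seed = 42)
meas <- dplyr::bind_rows(lapply(names(co$stacks), function(id) {
  measure_cilia(co$stacks[[id]], subset(co$annotations, cilium_id == id))
}))
compare_methods(average_replicates(meas))
#> Population summary (mean ± SD, um):
#>  classification method  n  mean_um     sd_um       label
#>          ANGLED   DAAS 31 3.374294 0.7081171 3.37 ± 0.71
#>          ANGLED    MIP 31 1.940861 0.6182100 1.94 ± 0.62
#>          ANGLED    PYT 31 3.413741 0.7036379 3.41 ± 0.70
#>            FLAT   DAAS 31 3.390283 0.7155305 3.39 ± 0.72
#>            FLAT    MIP 31 3.403512 0.7200522 3.40 ± 0.72
#>            FLAT    PYT 31 3.411835 0.7213009 3.41 ± 0.72
#>
#> Flat vs angled t-tests:
#>  method        t df   p_value  label_flat label_angled
#>    DAAS  0.08843 60 9.298e-01 3.39 ± 0.72  3.37 ± 0.71
#>     MIP  8.58107 60 5.034e-12 3.40 ± 0.72  1.94 ± 0.62
#>     PYT -0.01053 60 9.916e-01 3.41 ± 0.72  3.41 ± 0.70
```

Although both populations share the same true lengths, MIP reports angled
cilia as 1.4 µm shorter (p ≈ 5·10⁻¹²) while DAAS and PyT correctly find
no difference — the projection bias, reproduced end to end. The agreement
table of the same object shows the matching ICC pattern: PyT–DAAS is
almost perfect on angled cilia (0.99) where MIP–DAAS drops to 0.22.

## Command line

A thin launcher over the same functions lives at `inst/cli/ciliometry`:

```sh
ciliometry simulate --seed 1 --out run1
ciliometry measure  --stack run1/stack.tif --annotations run1/annotations.csv --out run1
ciliometry compare  --measurements run1/measurements.csv --out-prefix run1/comparison
ciliometry pipeline --seed 1 --out run1      # all three chained
```

Every output CSV records the package version, seed and a configuration
hash in `#` header lines; a run is byte-identical given the same seed.

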