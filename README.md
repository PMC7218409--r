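# fretmap

Acceptor-photobleaching FRET analysis and protein proximity mapping for
multiprotein assemblies, built around the clathrin-mediated endocytic coat
of budding yeast.

Wide-field acceptor-photobleaching FRET reports whether two fluorescently
tagged protein termini sit within ~10 nm: destroying the acceptor
fluorophore with a laser pulse de-quenches the donor, and the fractional
rise in donor fluorescence measures the transfer efficiency,

    e_pre  = 100 · (D_post − D_pre) / D_pre      (increase over pre-bleach)
    e_post = 100 · (D_post − D_pre) / D_post     (classical efficiency)

computed per pixel over patch ROIs above a per-cell cytoplasm-level
threshold, averaged, and corrected by subtracting the apparent FRET of
donor-only cells acquired in parallel. Pairs are screened with the
positivity rule *mean > 0 and both 95 % CI bounds > 0*; positive pairs
become edges of a terminus-level proximity graph that is decomposed into
proximity networks and embedded on the membrane-normal axis under anchor
and molecular-ruler (truncation) constraints. Per-patch FRET sorted by an
Abp1 marker channel resolves rearrangements across endocytic stages, and
FRAP recovery fits `F(t) = F0 + M(1−F0)(1−exp(−t/τ))` report binding
dynamics (mobile fraction `M`, exchange time `τ`).

Everything is testable without microscope data: the package includes a
synthetic two-channel EMCCD microscopy simulator (Poisson shot noise with
excess-noise factor, Gaussian read noise, structural photobleaching,
partial acceptor bleach) with exact ground truth.

## Worked example

Simulate a 20-cell batch of a weakly FRET-positive pair (true efficiency
2.5 %), correct it against a donor-only batch, and classify it:

```r
library(fretmap)
library(dplyr)

donor_only <- simulate_pair_batch(20, E_true = 0,     seed = 101)
pair       <- simulate_pair_batch(20, E_true = 0.025, seed = 102)

baseline <- donor_only_baseline(donor_only)
baseline
#> # A tibble: 1 × 4
#>   batch_id  b_pct n_cells ci95_halfwidth_pct
#>   <chr>     <dbl>   <int>              <dbl>
#> 1 batch1   -0.524      20              0.350

screen <- pair |>
  apply_donor_only_correction(baseline) |>
  mutate(pair_id = "Syp1-C~Ede1-C", compartment = "endocytic_sites") |>
  aggregate_screen()
screen
#> # A tibble: 1 × 6
#>   pair_id       compartment     n_cells mean_E_pct ci95_halfwidth_pct verdict
#>   <chr>         <chr>             <int>      <dbl>              <dbl> <chr>
#> 1 Syp1-C~Ede1-C endocytic_sites      20       2.21              0.321 positive
```

The donor-only baseline is slightly **negative** (structural
photobleaching dims the donor over the acquisition), so the correction adds
about half a point; the corrected mean lands within its CI of the true
2.5 % (here 2.21 ± 0.32 with 20 cells), and the pair is called
FRET-positive.

Build the published-record proximity map (curated from the printed values;
Sla2's termini anchored at 1.5 and 33 nm):

```r
pm <- published_coat_map()
tidy(pm)
#> # A tibble: 21 × 4
#>    node    x_nm layer            anchored
#>    <chr>  <dbl> <chr>            <lgl>
#>  1 Sla2-N  1.5  membrane_binding TRUE
#>  2 Pan1-N  8.79 adaptor          FALSE
#>  3 Gts1-N 11.7  adaptor          FALSE
#>  ...
#>    Chc1-C 16.0  lattice          FALSE
#>    Clc1-C 21.0  lattice          FALSE
#>  ...
#>    Sla2-C 33.0  actin_regulatory TRUE
#>    Pan1-C 43.0  actin_regulatory FALSE
```

The adaptor-layer termini fall below the clathrin heavy-chain marker, the
light-chain marker sits above the heavy chain, the second ("cytoplasmic")
network lies beyond both lattice markers, and Pan1's C-terminus — pushed
past the light chain by the truncation-ruler bounds — is the most distal
terminus, the published architecture.

Other entry points: `simulate_apb_experiment()` / `quantify_apb()` for the
imaging pipeline, `detect_patches()` + `stage_resolved_fret()` for
marker-sorted per-patch analysis, `simulate_frap_cell()` /
`fit_recovery()` for FRAP (all with `tidy()`/`glance()`/`autoplot()`
methods), and `write_image_series()` / `read_roi_set()` for TIFF/YAML/CSV
interchange.

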