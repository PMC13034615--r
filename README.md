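# vasomap

Layer-resolved (laminar) analysis of digit representations in human
somatosensory cortex from interleaved blood-nulled (VASO) and BOLD fMRI —
implemented as a reusable R pipeline, validated end to end against a
synthetic cortical phantom with analytically known ground truth.

## The problem and who this is for

Vascular space occupancy (VASO) imaging interleaves blood-nulled and
not-nulled (BOLD) volume pairs: the nulled signal *drops* when cerebral blood
volume rises, and — unlike BOLD, which is biased toward pial draining veins —
localises activity to the cortical depth where the microvasculature responds.
Mapping individual fingertip representations across cortical depth at 7 T
requires a long chain of specialised steps, each easy to get subtly wrong:

- **Preprocessing** — separate the interleaved contrasts, replace
  non-steady-state volumes, upsample the time axis by 2 (7th-order
  polynomial interpolation), temporally align the two contrasts, and remove
  the BOLD contamination of the nulled series by *dynamic division*
  `vaso(t) = nulled(t) / bold(t)`, which under the multiplicative model
  `nulled = N0 (1 - v)(1 + b)`, `bold = B0 (1 + b)` recovers the
  blood-volume response `1 - v(t)` exactly.
- **Cortical geometry** — normalised *equivolume* cortical depth (equal depth
  steps enclose equal tissue volume; for a locally cylindrical patch of
  curvature radius `r`, depth `alpha(r) = (r_p^2 - r^2) / (r_p^2 - r_w^2)`
  between the pial radius `r_p` and white-matter radius `r_w`), layer bins,
  geodesic gray-matter disks and Euclidean distance bins.
- **Statistics** — voxelwise GLM with a gamma haemodynamic response
  (mean lag 6 s, sd 3 s), 0.01 Hz discrete-cosine high-pass, motion and
  outlier confounds, winner-take-all contrasts (digit > other digits, e.g.
  `[D2: +1, D3: -0.5, D4: -0.5]`), fixed-effects combination across runs and
  Benjamini–Hochberg FDR at q = 0.001.
- **Digit ROIs** — the five-step construction: threshold, intersect with a
  12 mm geodesic disk, keep the largest cluster, propagate across cortical
  depth with a 0.45 mm columnar max filter, and remove voxels claimed by
  more than one digit.
- **Model-free dynamics** — event-related averages (15 volumes before to 70
  after onset, percent change of the run mean) in layer-by-ROI and
  layer-by-distance-bin compartments, and the *triphasic* surround response:
  initial peak (highest deflection during stimulation), trough (lowest after
  the peak, before stimulus end) and post-stimulus peak (highest within 8
  volumes ≈ 15.4 s after offset).

Because almost none of these stages can be verified on real data, the package
ships a first-class synthetic phantom: a quarter-cylinder cortical ribbon
whose equivolume depth has an exact closed form, three digit patches with
laminar amplitude profiles, distance-dependent triphasic surround responses,
and an interleaved nulled/BOLD acquisition with multiplicative contamination
and calibrated noise. Every stage of the pipeline is tested against this
ground truth.

## Worked example

Simulate the default study (three runs, four 30 s blocks per digit and run,
pair repetition time 3.85 s) and run the full analysis:

```r
library(vasomap)

spec  <- phantom_spec(seed = 7)
study <- simulate_study(spec)
res   <- analyze_study(study)

res$rois$summary
#> # A tibble: 3 × 3
#>   digit n_voxels volume_mm3
#>   <chr>    <int>      <dbl>
#> 1 D2         299       32.3
#> 2 D3         238       25.7
#> 3 D4         280       30.2
```

Three disjoint digit ROIs of a few tens of mm³ each — the same order of
magnitude as published per-digit ROI volumes. The triphasic features of the
digit-pooled distance analysis (middle layer, bins 3–7, i.e. 4–14 mm from
each digit's peak voxel):

```r
res$features[res$features$layer == 2 & res$features$region >= 3,
             c("region", "ttp_initial_s", "amp_initial_pct",
               "ttp_trough_s", "amp_trough_pct", "ttp_post_s")]
#> # A tibble: 5 × 6
#>   region ttp_initial_s amp_initial_pct ttp_trough_s amp_trough_pct ttp_post_s
#>    <dbl>         <dbl>           <dbl>        <dbl>          <dbl>      <dbl>
#> 1      3          9.62           0.393         25.0         -0.166      10.4
#> 2      4          9.62           0.340         23.1         -0.217       4.65
#> 3      5          7.7            0.256         23.1         -0.301       6.58
#> 4      6          7.7            0.205         21.2         -0.374       6.58
#> 5      7          5.78           0.134         21.2         -0.398       8.5
```

With increasing distance from the activation peak the initial peak weakens
(0.39 % → 0.13 %) and arrives earlier (9.6 s → 5.8 s), while the trough
deepens (−0.17 % → −0.40 %) — the injected distance trends, read back by the
model-free extraction. Laminar profiles (11 depth bins, 1 = most superficial)
show the expected BOLD increase toward the surface:

```r
head(dplyr::filter(res$profiles, contrast == "bold", digit == "D3"), 4)
#> # A tibble: 4 × 5
#>   layer n_voxels mean_z contrast digit
#>   <dbl>    <int>  <dbl> <chr>    <chr>
#> 1     1       26   6.91 bold     D3
#> 2     2       27   6.27 bold     D3
#> 3     3       18   6.17 bold     D3
#> 4     4       16   6.31 bold     D3
```

`autoplot(res$era_roi)` draws the event-related averages,
`plot_layer_profile(res$profiles)` the laminar profiles, and
`run_pipeline(pipeline_config(seed = 7), "out/")` writes the complete
artifact set (NIfTI maps, TSV tables, resolved configuration, provenance) to
disk.

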