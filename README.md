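# adipomorph

Automated morphometry of adipose tissue from brightfield images of
elastic-stained sections. On such sections adipocyte lumina are unstained
(near-white), collagen septa are pink, and elastin fibers are black, so one
stain yields three readouts: the cross-sectional area (CSA, in µm²) of
every adipocyte on the section, collagen/elastin area fractions of the
tissue, and per-mm² densities for counted objects (mast cells, macrophages,
vessels). The package is aimed at image-analysis and metabolism labs that
need per-cell adipocyte sizing at whole-section scale, where manual sizing
of a few hundred cells is slow and field-biased.

## Method

Segmentation runs in two steps per slide:

1. **Seeding.** Pixels are classified as lumen / collagen / elastin by
   luminance–saturation thresholds; the Euclidean distance transform of the
   lumen class is computed, and its regional maxima (one per connected
   lumen component, relocated to the component centroid, minimum separation
   25 µm) become seeds — one near the geometric center of each adipocyte.
   An optional random-forest stage rescoring candidate seeds from image
   patches is included.
2. **Gradient-vector-flow (GVF) contours.** An edge map is built from the
   per-channel maximum of Gaussian-smoothed color-gradient magnitudes, and
   the GVF field *(u, v)* is obtained by the explicit diffusion
   `u ← u + dt·(µ∇²u − (f_x²+f_y²)(u−f_x))` from `(u,v) = (f_x,f_y)`
   (µ = 0.2, dt at half the stability limit, 2000 iterations, compiled
   inner loop). A closed snake per seed — implicit internal forces
   (elasticity α = 0.1, rigidity β = 0.05), explicit external force —
   inflates on the normalized field and then converges on the raw field at
   the edge crest. Overlaps resolve to the nearest seed; regions are
   trimmed to their unstained pixels; areas are pixel counts × (µm/px)².

Slide summaries (cell counts, mean CSA, CSA histograms, ECM fractions)
feed paired pre/post statistics (two-sided paired t on per-subject means)
and a manual-vs-automated Pearson correlation. A synthetic slide generator
with exact ground truth (power-diagram cell packing, planted elastin,
illumination gradient, sensor noise) makes the whole pipeline testable
without real slides.

## Worked example

```r
library(adipomorph)

# a synthetic elastic-stained slide with known ground truth
slide <- generate_slide(slide_recipe(width_px = 384, height_px = 384,
                                     n_cells = 28, rng_seed = 7))
seg <- segment_slide(slide$image)
seg
#> <slide_segmentation 'synthetic'> 28 seeds, 27 cells (27 included), 0.147 mm2 tissue

summarize_segmentation(seg)[, c("slide_id", "n_cells_included",
                                "mean_csa_um2", "pct_collagen", "pct_elastin")]
#> # A tibble: 1 × 5
#>   slide_id  n_cells_included mean_csa_um2 pct_collagen pct_elastin
#>   <chr>                <int>        <dbl>        <dbl>       <dbl>
#> 1 synthetic               27        4408.         14.5        3.00
```

28 seeds are found for the 28 planted cells; one small cell merges into a
neighbor during overlap resolution, leaving 27 measured cells whose mean
CSA (4408 µm²) is within ~1.5% of the generator's ground truth
(4345 µm²). The ECM readout recovers the planted 3% elastin exactly and
reports the collagen septum fraction.

Density normalization and paired comparisons work on plain tibbles:

```r
counts <- data.frame(category = "mast_cell", count = 48)
to_density(counts, tissue_mask(slide$image))
#>   slide_id  category count tissue_area_mm2 density_per_mm2
#> 1    slide mast_cell    48           0.147            326.
```

A thin command-line front end over the same functions ships in
`inst/cli/adipomorph.R` with subcommands
`simulate | segment | ecm | density | compare | validate`.

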