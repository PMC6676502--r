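# fluorquant

Headless quantification of nuclear immunofluorescence with automatic
background subtraction.

A common design in neuro- and cell-biology imaging is the two-channel
immunostain: one *marker* channel identifies the objects of interest (e.g.
Elav labelling motor-neuron nuclei in the larval *Drosophila* ventral
ganglion) and one *query* channel carries the signal whose abundance is the
question (e.g. pMad, the phosphorylated BMP-pathway transcription factor).
`fluorquant` turns such RGB TIFF images into tidy per-nucleus intensity
tables:

1. **Segment** the marker channel: clear outside a polygonal selection,
   threshold (isodata or Otsu on the in-selection histogram, or a manual
   window), optionally dilate and watershed-split the binary mask, then run
   an ImageJ-style particle analysis (8-connected components filtered by
   area and circularity `4πA/P²`).
2. **Measure** the query channel inside the marker-derived ROIs; estimate
   background as the mean query intensity of the in-selection pixels *not*
   claimed by any ROI; report the background-subtracted mean per nucleus,

   `mean_corrected = mean_raw − mean_bg`.
3. **Compare** groups: per-image summaries, fold-change of an experimental
   group over controls (with the SD of per-image folds), agreement
   regression between paired readings, and coefficients of variation.

Everything is scriptable and deterministic — the package is aimed at batch
quantification (genetic screens, genotype comparisons) where a GUI in the
loop is the bottleneck and the audit trail matters. A synthetic-image
generator with exact ground truth ships with the package so the whole
pipeline is testable without microscope data.

## Worked example

Generate a noiseless synthetic image with ten nuclei of known query-channel
means 60–240 over a uniform background of 20, then quantify it:

```r
library(fluorquant)

spec <- synth_spec(n_nuclei = 10, query_means = seq(60, 240, by = 20),
                   background_level = 20, noise_sd = 0, seed = 42)
syn <- generate_image(spec)
ch  <- split_channels(syn$stack)          # red = marker, green = query
res <- quantify_image(ch$red, ch$green, image_id = "demo")
res
#> # A tibble: 10 × 8
#>   image roi_id area_px mean_raw mean_bg mean_corrected centroid_x centroid_y
#> 1 demo       1     150      120      20            100       89.2       23.7
#> 2 demo       2      81      180      20            160      111.        36.7
#> 3 demo       3     189      100      20             80       79.0       65.6
#> 4 demo       4     123      220      20            200       18         65.1
#> # ℹ 6 more rows
glance(res)
#> # A tibble: 1 × 4
#>   image n_rois mean_corrected_mean mean_bg
#> 1 demo      10                 130      20
```

Every `mean_corrected` equals its nucleus's true query mean minus the
background, exactly: the noiseless image is recovered with zero error
(`120 − 20 = 100`, and the image-level summary is the unweighted ROI mean,
`130`).

A two-group experiment — eight control images (true corrected mean 30) and
eight experimental images (true corrected mean 120, i.e. a 4-fold
difference) with Gaussian noise — run as a batch:

```r
man <- generate_experiment(
  synth_spec(query_mean = c(mu = 50, sd = 4.5), noise_sd = 5),
  synth_spec(query_mean = c(mu = 140, sd = 18), noise_sd = 5),
  n_images_per_group = 8, out_dir = "demo_exp", base_seed = 1
)
cfg <- run_config(groups = setNames(man$group, man$file),
                  out_dir = "demo_exp/out")
batch <- run_batch(cfg, file.path("demo_exp", man$file))
batch$group_stats
#> # A tibble: 2 × 5
#>   group            n  mean    sd     cv
#> 1 control          8  31.8 0.823 0.0259
#> 2 experimental     8 118.  8.73  0.0737
batch$fold
#> # A tibble: 1 × 6
#>   control_group group        n_control     n  fold    sd
#> 1 control       experimental         8     8  3.73 0.275
```

The estimated fold-change (3.73 ± 0.28 for this seed) recovers the
generating ratio of 4 within sampling error. `run_batch()` also writes one
CSV per image, `summary.csv`, `groups.csv`, `fold.csv` and a `run_log.txt`
that records every effective parameter.

A thin command-line front end with `quantify`, `synth` and `stats`
subcommands is installed at `inst/cli/fluorquant` (run it with `Rscript`);
it persists its last-used parameters to a JSON config file.

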