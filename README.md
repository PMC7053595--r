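# vesicoloc

Quantification of endocytic vesicles and object-based colocalization in
multi-channel confocal fluorescence z-stacks.

Internalized protein cargo shows up in confocal images as diffraction-limited
bright spots (vesicles/endosomes). Given calibrated z-stacks with a cargo
channel, an endosome-marker channel (e.g. EEA1 for early endosomes, LAMP1 for
late endosomes/lysosomes) and a nuclear stain, `vesicoloc` computes, per
field:

- **vesicles per cell** and per-vesicle **integrated density**, and
- the **object-based colocalization percentage**

  $$\mathrm{coloc} = 100 \cdot \frac{\#\{\text{cargo objects overlapping marker foreground}\}}{\#\{\text{cargo objects}\}}$$

The detection chain per channel is: maximum-intensity projection of three
consecutive optical sections → subtraction of a disk-median-filtered image
(radius 6 px cargo / 10 px marker) → binarization (Otsu with a robust noise
floor, or a fixed threshold) → connected-component particle analysis keeping
objects with calibrated area strictly greater than 20 000 nm² → measurement
on the original projection. Group results are summarized as boxplot
statistics (median, IQR, min, max) and compared with the Mann–Whitney U
test. A seeded simulator generates fields of cells with vesicles of known
position, count and colocalization state, so the whole pipeline is validated
by parameter recovery against ground truth. See the methods vignette
(`vignettes/vesicle-quantification.Rmd`) for the model, parameters and
validation design.

## Worked example

```r
library(vesicoloc)

# a simulated 2-cell field: ~28 cargo vesicles per cell, half of them
# carrying a coincident marker vesicle
p <- update_sim_params(sim_params(), list(
  seed = 42, field_shape = c(256L, 256L), n_cells = 2L,
  cell_radius_um = 9, vesicles_per_cell_mean = 28, coloc_fraction = 0.5))
sim <- simulate_field(p)

res <- analyze_field(sim$stack, field_id = "demo")
res$field[, c("n_vesicles", "n_cells", "vesicles_per_cell", "threshold_cargo")]
#>   n_vesicles n_cells vesicles_per_cell threshold_cargo
#> 1         51       2              25.5        37.05469
res$coloc[, c("n_objects_a", "n_overlapping", "percent_coloc")]
#>   n_objects_a n_overlapping percent_coloc
#> 1          51            23      45.09804

# ground truth for comparison
sum(sim$truth$vesicles$channel == "cargo")                       # 52 vesicles
100 * mean(sim$truth$vesicles$coloc[sim$truth$vesicles$channel == "cargo"])
#> 44.23077
```

The field carried 52 true cargo vesicles, 44.2 % of them genuinely
colocalized; the pipeline detected 51 objects (one close pair merged) and
reported 45.1 % colocalization, with the automatically chosen cargo
threshold logged alongside.

Config-driven batch runs (`run_pipeline("config.yaml")`) write `fields.csv`,
`rois.csv`, `coloc.csv`, `group_summary.csv`, `comparisons.csv` and a JSON
run manifest; reruns are byte-identical. A thin CLI wrapper lives at
`inst/cli/vesicoloc.R` (`simulate` / `run` / `compare` subcommands).

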