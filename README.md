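# vdcyto

Image-analysis toolkit for **viscoelastic deformability cytometry**: the
label-free mechanical phenotyping of single cells flowing through parallel
microfluidic deformation channels. Cells focused and deformed by a
viscoelastic carrier fluid adopt bullet-like shapes; a high-speed camera
images the deformation region (a 1024 × 80 px region of interest spanning
ten channels at 1000–10,000 frames/s), and each detected cell contour is
reduced to its projected area *A*, perimeter *l*, and **deformability**

> *D* = 1 − 2√(π·*A*) / *l*,

the isoperimetric deficit: 0 for a circle, growing as the outline departs
from circularity. Populations are summarised in the (area, deformability)
plane, compared with Mann-Whitney / ANOVA + Tukey statistics, and gated by
50 %-of-maximum density contours — including the quantification of rare
subpopulations (e.g. tumour cells spiked into blood at 1:10,000) with exact
binomial confidence intervals.

The package is aimed at people building or validating deformability-cytometry
analysis: it contains both the **analysis pipeline** (background estimation,
segmentation with sub-pixel contour extraction, per-cell features, gating,
statistics, a bounded-buffer streaming emulation) and a **synthetic frame
generator** that renders bullet-shaped cells with *exact* geometric ground
truth, so every stage is testable end-to-end without an acquisition system.
A small utility layer covers Carreau shear-thinning viscosity fits and the
Reynolds/Weissenberg/elasticity numbers used to describe viscoelastic
focusing conditions.

## Worked example

Simulate a PBMC-like population (deformability 0.05 ± 0.01, area
28.1 ± 4.9 µm²), render it at the default imaging configuration, run the
full detection pipeline, and compare the measured means with the generator
truth:

```r
library(vdcyto)

pops <- calibrated_populations()
rec <- recover_population(pops$pbmc, n = 800, seed = 7)
print(rec$summary, digits = 4)
#>   population n_true n_accepted mean_D_measured mean_D_true mean_area_measured
#> 1       pbmc    800        800         0.05487     0.05028               28.6
#>   mean_area_true
#> 1          28.08
```

All 800 rendered cells were detected and accepted; the pipeline-measured
mean deformability (0.055) and area (28.6 µm²) sit within 0.005 and 2 % of
the exact truth of the very cells that were rendered — the residual is the
systematic bias of contour estimation under blur and noise, which is what
the acceptance suite bounds. Population summaries and comparisons follow the
field's conventions:

```r
summarize_populations(transform(rec$records, sample = "pbmc"), "sample")
#>   group   n mean_deformability sd_deformability mean_area_um2 sd_area_um2
#> 1  pbmc 800            0.05487         0.009983          28.6       4.989
#>   size_to_deformability n_replicates   mode
#> 1                 521.2            1 pooled

rbc <- recover_population(pops$rbc, n = 800, seed = 8)
mann_whitney_u(rbc$records$deformability, rec$records$deformability,
               labels = c("rbc", "pbmc"))
#> Mann-Whitney U [rbc vs pbmc]: statistic = 6.399e+05, P = 1.453e-262 (****)
```

Red blood cells and PBMCs have similar sizes but are cleanly separated by
deformability — the two-tailed Mann-Whitney U test is significant at the
strictest star level (`****`, *P* < 0.0001).

Lower-level entry points: `simulate_stream()` (Poisson arrivals, mixture
weights, spiking ratios), `open_sequence()` / `write_results()` (TIFF, PNG
directories, a documented raw stream format, schema-stamped CSV),
`process_sequence()` (batch) and `run_stream()` (staged streaming with a
bounded buffer), `density_map()` / `derive_gate()` / `apply_gate()` /
`rare_cell_ratio()` (gating), and `fit_carreau()` /
`dimensionless_numbers()` (flow characterisation). A thin command-line
front end lives at `inst/cli/vdc.R` with `simulate`, `process`, `gate`,
`stats` and `flow` subcommands.

See the methods vignette (`vignettes/vdcyto-methods.Rmd`) for the shape
family, the forward imaging model, the sub-pixel contour estimator, and the
reasoning behind every default.

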