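---
title: "Measuring single-cell deformability from bright-field frames: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell deformability from bright-field frames: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdcyto)
```

## The measurement

In viscoelastic deformability cytometry, cells carried by a polymer-laden
(viscoelastic) fluid are focused to the centreline of narrow parallel
microchannels and deformed by the shear and normal stresses of the
constricted flow, adopting a characteristic bullet-like shape. A high-speed
camera images the end of the deformation region (a 1024 x 80 px region of
interest spanning ten channels at 1000 or 10,000 frames/s, 1-2 us exposure),
and each cell's projected contour is reduced to a single dimensionless
number, the deformability

$$D = 1 - \frac{2\sqrt{\pi A}}{l},$$

where $A$ is the projected area and $l$ the contour perimeter. $D$ is the
isoperimetric deficit: 0 for a circle, and increasing as the outline departs
from circularity. Populations are then summarised in the
(area, deformability) plane, compared statistically, and gated by density
contours.

`vdcyto` implements this pipeline end-to-end, together with a synthetic frame
generator whose geometric ground truth is exact. Every stage of the analysis
can therefore be validated against known answers without an acquisition
system.

## The synthetic bullet family

The deformed outline is modelled as a one-parameter polar family with an
axial stretch along the flow axis:

$$r(\theta) = r_0\,\bigl(1 + p\,(0.30\cos 2\theta +
  0.25\cos\theta\,|\cos\theta|)\bigr), \qquad
  (u, v) = \bigl((1 + 0.40\,p)\,r\cos\theta,\; r\sin\theta\bigr),$$

with $u$ the flow axis. The $\cos 2\theta$ harmonic elongates the shape, the
asymmetric $\cos\theta|\cos\theta|$ term rounds the nose and flattens the
rear, and the stretch factor extends the reachable deformability range
without pinching the waist ($r > 0$ everywhere on $p \in [0, 3]$, so the
polar curve is always simple). Deformability is strictly monotone in $p$
(asserted on a dense grid in the test suite) and spans $[0, 0.357]$, so a
target deformability can be solved for by monotone bisection
(`contour_for_deformability()`), with the inverse accurate to $10^{-4}$.

```{r family, fig.width = 6, fig.height = 3, eval = FALSE}
op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
for (D in c(0.03, 0.10, 0.20)) {
  poly <- attr(contour_for_deformability(D)$truth, "polygon")
  plot(poly, type = "l", asp = 1, axes = FALSE, xlab = "", ylab = "",
       main = sprintf("D = %.2f", D))
}
par(op)
```

Ground truth ($A$, $l$, $D$, centroid) is recorded from 4096-vertex
quadrature, where doubling the vertex count changes area and perimeter by
less than $1.5\times10^{-6}$ relative. At 1024 vertices the doubling delta is
below $10^{-5}$ for $p \le 1.3$ and reaches $2\times10^{-5}$ at the
sharp-nosed end of the family; rendered polygons therefore use the 4096-based
truth values rather than their own resolution.

A population (`population_spec()`) is described by normal distributions of
deformability and area, truncated to the physical ranges ($D$ to
$[0, \min(0.5, D_{\max})]$, area to positive values); the analytic truncation
bias is recorded and a warning is raised if it exceeds 10 % of the mean.
Areas are imposed exactly by scaling $r_0$, so sampled truth records carry
their exact geometry.

## The forward imaging model

`render_frame()` composites cells onto a bright background (default 200
counts at 8 bit) as a dark rim (contrast 0.94 of background) with a slightly
lighter interior (contrast 0.85), then applies, in order: a per-cell box
motion blur along the flow axis of length $v\,t_{\mathrm{exp}}/s_{\mathrm{px}}$
(2.8 px at the 0.7 m/s average transit velocity, 2 us exposure and
0.5 um/px), a global Gaussian point-spread blur ($\sigma = 0.7$ px), Poisson
shot noise, Gaussian read noise (SD 2 counts), and quantisation. Cell
rasterisation is supersampled 4x in a band around the outline, so the clean
transmission image is area-exact to well under a percent.

The interior contrast is deliberately deep: with it, the default detection
threshold (six noise SDs, about 86 counts at the default background) falls at
half the edge amplitude, and the half-amplitude crossing of a blurred step
edge is the true edge position. Optics are otherwise not modelled (no
diffraction, no defocus rings); the generator's purpose is a controllable,
exactly known geometry under realistic sampling, blur and noise, not
photorealism. Accordingly, passing the recovery suites demonstrates the
correctness of the measurement chain, not performance on any particular
camera's real data.

Streams are assembled either as Poisson arrivals per channel with mixture
weights (`simulate_stream()`, supporting spiking ratios such as 1:10,000) or
as a deterministic round-robin layout with exactly `n` cells
(`simulate_cells()`). The round-robin layout fills channel/frame slots at a
duty cycle chosen so that no pixel is covered by cells in more than roughly a
third of frames: the background estimator (below) is a temporal median, which
needs the cell-free state to be the per-pixel majority. Large cells sweep
most of their placement band in an 80-px-tall ROI, so they are automatically
spread over proportionally more frames. All randomness is seeded; a manifest
and its frames are byte-identical across re-runs.

## Detection and the contour estimator

Processing follows the classical chain: background estimation, background
subtraction, median filtering, thresholding, connected components, contour
extraction, feature measurement, presence filtering.

**Background.** The default is a per-pixel temporal *median* over up to 100
frames sampled evenly across the sequence, with a mean offered as the
classical alternative. At the package's default contrast a transiting cell
darkens a pixel by ~170 counts, so even 5 % occupancy would bias a plain mean
by ~8 counts; the median is unbiased as long as the cell-free state is the
majority. The temporal noise SD is estimated from pooled absolute deviations
with the median interpolated across integer count bins — a plain MAD of
integer data is biased at small SDs because the deviations quantise.

**Threshold.** Default $6\sigma$ of the estimated noise on the
background-subtracted image, overridable as an absolute value. At this level
isolated noise pixels are essentially impossible, and the median step (the
binary mask of a median-filtered image is exactly a window-majority count of
above-threshold neighbours, which is how it is computed) removes any that
remain before component labelling (8-connectivity).

**Sub-pixel contours.** Deformability is quadratically sensitive to
perimeter error, and the estimator is where most of the design effort went:

* the iso-level contour at the threshold is traced by marching squares with
  linear interpolation on the *unfiltered* subtracted image — tracing on the
  median-filtered image erodes high-curvature edges and biased $D$ by about
  $-0.008$ at red-blood-cell scale in development experiments;
* the traced polyline is projected onto a truncated Fourier basis (8
  harmonics, least squares on an arc-length-resampled closed curve). Unlike
  kernel smoothing of the vertices, the projection removes pixel-noise
  jitter (which otherwise inflates the perimeter and $D$ by up to $+0.007$
  at the low-deformability end) with no first-order shrinkage;
* each vertex is then re-localised at the crossing of the *local*
  half-amplitude along the edge normal. This removes the inward bias that a
  fixed global threshold has wherever curvature lowers the local plateau;
* finally the second-order smearing bias of a blurred curved edge is undone
  by displacing each vertex outward by $\hat\sigma^2\kappa/2$, where
  $\kappa$ is the local curvature of the regularised contour and
  $\hat\sigma$ the edge blur measured from the pooled normal profile
  (quartile width of the erf edge). Because the correction moves the polygon
  itself, area, perimeter and deformability remain mutually consistent.

With all four elements the pipeline recovers population mean deformability to
within $\pm 0.005$ and mean area to within $\pm 2$ % across the calibrated
populations (verified at $n = 5000$ in the acceptance suite). The refinement
steps apply only to detected contours; `measure_cell()` computes shoelace
area, polyline perimeter, deformability, brightness (mean original-frame
intensity of enclosed pixel centres — holes are implicitly filled), moment
aspect ratio, convex-hull area ratio, pixel-set centroid and channel
assignment from whatever polygon it is given, without smoothing, so
closed-form oracles (circle, square, 2:1 ellipse) apply to it directly.

**Presence filter.** Records are rejected for area outside
$[10, 700]\ \mu m^2$, for a convex-hull/contour area ratio above 1.25, or
for contours within 3 px of the ROI border (clipped cells), with
machine-readable reasons. The area-ratio default is deliberately looser than
the $\approx 1$ of an idealised convex cell: the bullet family itself is
rear-concave at higher deformability (true hull ratio up to $\approx 1.07$
at $D = 0.26$), and a tight 1.05 cut-off would silently discard the most
deformed part of a red-blood-cell-like population and bias its mean. Concave
debris of the crescent kind sits at ratios of 1.3 and above and is still
rejected.

**Velocity.** Per-cell velocities come from nearest-centroid matching across
consecutive frames within a channel, gated along and across the flow axis;
ambiguous matches (two candidates in the gate) yield no estimate. At 1000
frames/s a cell transits the ROI in well under a frame interval, so each
cell normally appears once and no cross-frame deduplication is applied.

## Density maps, contours and gates

`density_map()` builds the (area, deformability) density either as a 64 x 64
histogram over robust 1st-99th percentile ranges (out-of-range points are
clamped to edge bins, so the density integrates to one exactly — and the
streaming accumulator reproduces it update-by-update), or as a Gaussian
product-kernel KDE with per-axis Scott bandwidths
($\hat\sigma_i n^{-1/6}$) on a finer 128-point grid extended four bandwidths
beyond the 0.1-99.9 percentile range (trapezoid integral within $10^{-3}$
of one).

"50 % density" is read as 50 % *of the maximum* density — the convention of
a contour line attached to a linear colour scale — not as the 50 %
probability-mass region. `half_max_contour()` traces that level set by
marching squares; disjoint regions yield multiple polygons, and
`derive_gate()` takes the largest-area polygon of a reference population's
density as the gate. Both the method (histogram or KDE) and the level are
recorded in the gate provenance.

A consequence worth stating explicitly: for a roughly Gaussian reference,
the half-maximum region contains only about half the population
($1 - 0.5^{(\sigma^2+h^2)/\sigma^2}$ for a KDE with bandwidth $h$).
`derive_gate()` therefore measures and stores the *gate efficiency* (the
fraction of its own reference inside the gate), and `rare_cell_ratio()`
accepts it to rescale an abundance estimate and its Clopper-Pearson interval
to the full population. With the default efficiency of 1 the function
reports the raw gated fraction. In the rare-cell acceptance test
(a 1:10,000 spike in $10^6$ records, populations separated by at least four
SDs on both axes), the efficiency-corrected estimate recovers the spiked
count within $3\sqrt{\mathrm{expected}}$ and the interval covers the true
ratio in at least 90 of 100 seeded replicates.

Points on a gate boundary count as inside (documented convention), and
gating is invariant to point order and to consistent axis rescaling.

## Statistics

Group comparisons follow the field's conventions: two-tailed Mann-Whitney U
for two-sample comparisons (exact permutation distribution when both
samples are small, `min(n) <= 8`, and tie-free; the normal approximation
with midrank ties, tie-corrected variance and continuity correction
otherwise), one-way ANOVA with Tukey's HSD (Tukey-Kramer standard errors
for unequal group sizes) for dose-response panels, and the strict star
convention `* P < 0.033`, `** P < 0.0021`, `*** P < 0.0002`,
`**** P < 0.0001`. The U statistic is computed from midrank sums in the
package; p-values delegate to the reference implementations in base R, and
the test suite checks the exact path against complete enumeration for all
sample sizes up to six, the two-group ANOVA against the squared pooled-t
identity, and the null rejection rate at $\alpha = 0.05$ over 10,000
simulated pairs.

`summarize_populations()` reports per-group mean/SD/n of deformability,
area, and the size-to-deformability ratio (defined as mean area over mean
deformability, flagged as undefined when the mean deformability is zero).
When replicate identifiers are supplied, summaries are computed per
replicate and then averaged — the bar-equals-mean-of-three-measurements
convention of dose-response figures — and the mode used is stamped in the
output, since pooled and replicate-mean analyses answer different questions.

## Streaming emulation

The real-time architecture — an acquisition stage depositing frames into a
bounded circular buffer and an analysis stage consuming them — is emulated
as a deterministic single-threaded virtual-time event loop: frames arrive at
the acquisition rate, analysis costs a configurable virtual time per frame,
and a full buffer either blocks acquisition (`"block"`) or discards the
oldest unprocessed frame (`"drop-oldest"`; the real system's overload
behaviour is not documented, so the drop policy is an explicit emulation
choice). This keeps two properties exactly testable: results are
bit-identical to batch processing whenever nothing is dropped, and
`frames_in = frames_processed + frames_dropped` holds in every run,
including error-injected ones. Wall-clock throughput (frames/s, cells/s) is
reported in the metrics but never asserted in tests, since it is
hardware-dependent.

## Flow characterisation

The small `flow` layer evaluates the Carreau shear-thinning model
$\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
[1 + (\lambda_c\dot\gamma)^2]^{(n-1)/2}$, fits its parameters to rheology
data by bounded Levenberg-Marquardt least squares in log-viscosity space
(at least six points spanning two decades of shear rate; effectively
constant data short-circuit to a Newtonian fluid), and computes the
dimensionless numbers used to describe viscoelastic focusing with the
conventions $Re = \rho U H / \eta$, $Wi = \lambda U / H$ (characteristic
shear rate $U/H$) and $El = Wi/Re$, with a default fluid density of
1080 kg/m^3. These conventions are documented constants of this package;
no flow field or fluid-structure interaction is computed.

## Calibrated populations and what the recovery runs mean

`calibrated_populations()` encodes the reference phenotypes the package's
recovery experiments target: red blood cells ($D = 0.16 \pm 0.03$,
$35.4 \pm 2.3\ \mu m^2$), PBMCs ($0.05 \pm 0.01$, $28.1 \pm 4.9\ \mu m^2$),
BT474 ($0.08 \pm 0.02$, $170 \pm 22.4\ \mu m^2$), MDA-MB468
($0.06 \pm 0.02$, $103 \pm 16.5\ \mu m^2$), Jurkat cells at four driving
pressures (mean $D$ 0.030/0.050/0.065/0.085, 11-um cells), and CLL cells
(mean $D$ 0.09). Values not part of those reported phenotypes are synthetic
stand-ins fixed once: Jurkat sd($D$) 0.012 and area $95 \pm 12\ \mu m^2$,
CLL area $38 \pm 7\ \mu m^2$, transit velocities 0.7 m/s (0.35-1.4 m/s
across the Jurkat pressure series). `recover_population()` samples 5000
cells, renders them, runs the full pipeline, and reports measured against
true means; the acceptance script (`scripts/acceptance.R`) writes the
measured means of the six target populations as JSON. The problem size of
5000 cells per population (500-1500 frames depending on cell size) was
chosen to make the Monte-Carlo error of a population mean (~$10^{-4}$ in
$D$) negligible against the tolerances of interest.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based, (x, y) = (column, row), physical units in
  um from the ROI's top-left corner; one convention everywhere.
* Iso-contours that touch a window edge are closed through a padded border
  below the threshold; such cells are then caught by the border filter.
* The largest-area closed loop is taken when a component yields several
  (noise loops inside a window); holes are ignored by construction.
* Degenerate contours (area <= 0, fewer than 8 vertices) yield rejected
  records with reason `"degenerate"` rather than errors; saturated frames
  (>= 99 % of pixels at the maximum count) are skipped with a logged reason.
* A single-frame sequence used for background estimation warns and returns
  that frame; a zero-variance axis is an error for the KDE (the bandwidth is
  undefined, and the message names the offending axis) while the histogram
  falls back to unit-width bins so degenerate point clouds still bin.
* Bisection on the shape family is seeded by inverse interpolation of a
  481-point lookup table and polished to $10^{-6}$; ties in arc-length
  resampling are removed before the Fourier projection.
* The curvature correction is clamped to half a pixel and the estimated
  edge blur to $[0.3, 3]$ px, so pathological profiles cannot displace a
  contour unboundedly.

## Known limitations

* The generator's bullet family is a geometric idealisation; real deformed
  cells show richer texture (internal granularity, membrane fluctuations,
  diffraction fringes) that the dark-rim model does not emulate. Passing
  recovery tests validates the measurement chain, not robustness to optical
  artefacts absent from the model.
* Absolute deformability values from any pipeline of this kind depend on the
  contour estimator; the package's estimator is documented above precisely
  because a pixel-chain perimeter would give systematically higher $D$.
* The rare-cell gate efficiency is estimated on the same reference sample
  that defines the gate; for very small references this induces a small
  optimism that the minimum-reference-size check only partially guards.
* Throughput numbers from the streaming emulation reflect this
  implementation on the host machine, not the acquisition hardware of a
  real instrument.
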