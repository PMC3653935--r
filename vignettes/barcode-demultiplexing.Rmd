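---
title: "Ratiometric nuclear bar-code demultiplexing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric nuclear bar-code demultiplexing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbarcode)
```

## The measurement model

Cell lines carrying a dual fluorescent-protein nuclear marker (two red
FPs fused around an SV40 nuclear localization signal, "FP_NLS_FP") are
excited at a single wavelength band (560–590 nm) and imaged in two red
emission passbands, em1 (635–675 nm) and em2 (608–648 nm). Different FP
pairs partition their emission differently between the two bands, so
each line has a characteristic per-nucleus ratio

$$R \;=\; \frac{F_{\mathrm{em1}}}{F_{\mathrm{em2}}},$$

where $F_c$ is the background-subtracted fluorescence of the nucleus
summed over its segmented mask in channel $c$. Because both channels
integrate over the identical mask, $R$ is invariant to expression level
(up to photon noise), to the illumination profile (which multiplies
both channels identically) and to nucleus size. This is what makes $R$
usable as a per-cell bar-code across the >10-fold expression
heterogeneity typical of stable lines.

We compute $R$ from *summed* rather than mean intensities. Over a fixed
mask the two definitions are proportional and yield the same ratio;
sums behave better for nuclei with dim sub-regions (nucleoli), where
per-pixel means are noisier.

## Two-stage background correction

Accurate ratios require accurate removal of all fluorescence not
originating from the marker. The model is

$$I_c(x,y) \;=\; B_c(x,y) + \delta_{c,\mathrm{field}} + S_c(x,y) + \varepsilon,$$

with $B_c$ a per-channel **reference background image** and
$\delta_{c,\mathrm{field}}$ a small per-field scalar offset.

1. $B_c$ is the pixel-wise mean of media-only (no-cell) well fields —
   it captures camera offset, media fluorescence and the smooth
   illumination bowl (vignetting). Candidate fields are screened for
   debris: a field is rejected when its all-object mask covers more
   than 0.5% of pixels. The reference is kept real-valued; all
   downstream arithmetic is floating point.
2. $\delta$ absorbs the residual well-to-well variation (typically
   ±1–3 counts on the 12-bit scale, e.g. compound fluorescence). It is
   the mean of `field − reference` over pixels outside an all-object
   mask: every detectable object, however faint, is found with a low
   robust threshold (background median + 2 robust sd) and dilated by
   3 px with an exact Euclidean disk, and the same mask is applied to
   both grids so both are sampled in the same cell-free area.

Corrected grids are `field − reference − δ`; negative values are
preserved so that object sums stay unbiased. The offset matters most
for dim nuclei: a 3-count offset over a ~150 px mask shifts a low-signal
em2 sum by hundreds of counts and can bias $R$ by far more than 5%,
while after correction the bias is below 1% (this is asserted by the
test suite).

One numerical subtlety: if the offset mask flags *isolated single
pixels* above the 2-sd threshold, the surviving background sample is
truncated from above and $\delta$ is biased low by ~0.05σ (≈0.1–0.2
counts at read noise 2). Real objects are spatially coherent, so the
pipeline's offset mask requires connected components of at least 3 px
before dilation; this removes the truncation bias without unmasking any
genuine object. `permissive_mask()` itself keeps no area floor — its
definition is "everything detectable".

## Segmentation

Nuclei are segmented in the corrected em1 channel. The threshold is
Otsu's method computed in a log-compressed domain: intensities are
first divided by the robust background scale (MAD) and passed through
`log1p`. On the linear scale the log-normal expression distribution
makes the foreground so long-tailed that Otsu separates dim from bright
nuclei instead of background from foreground; the log domain restores a
two-class histogram, and the MAD normalization makes the resulting mask
exactly invariant under multiplying the image by any positive constant.
The pipeline additionally floors the threshold at 6 background MADs —
with very few nuclei in a field a bimodality-seeking threshold can
otherwise descend into the noise. Holes are filled before area
filtering (nucleoli are dimmer than the nucleoplasm and must not
fragment objects), touching blobs are split by watershed on the
distance transform, and objects below the area floor (default 40 px)
or mean-intensity floor (default 10 counts above background) are
discarded; both floors also reject most sub-nuclear debris.

## Calibration windows and classification

Each line's ratio distribution is calibrated from monocultures: the
sample mean $\mu$ and sample sd $\sigma$ (n−1 denominator) of all
unflagged objects, requiring at least 500 objects by default.
Classification windows are $[\mu - k\sigma,\; \mu + k\sigma]$ with a
single global $k$ (default 3; 5 is used for two well-separated lines).
Windows must be pairwise disjoint — overlapping windows are a
construction error that reports the offending pair and the largest
disjoint $k$ — because the bar-code is only meaningful when windows are
separable. A deliberate override (`allow_overlap = TRUE`) classifies
straddling objects as `ambiguous` instead.

Objects with any saturated (4095) pixel in em1/em2, or with an em2 sum
below the low-signal floor, are `excluded` outright; objects whose
ratio falls in no window are `other` (debris). The low-signal floor is
$5 \cdot \sigma_{\mathrm{noise}} \sqrt{\mathrm{area}}$ — five times the
expected noise sd of the object's summed em2 — since a near-zero
denominator makes $R$ arbitrarily unreliable; the choice of 5 keeps
false exclusions negligible while bounding the ratio's noise
contribution from the denominator.

For Gaussian ratio distributions the expected own-window fraction at
$k=3$ is $2\Phi(3)-1 = 99.73\%$, and cross-window misassignment between
lines ≥10 pooled sd apart is essentially zero at $k=5$; both are
checked by simulation in the test suite.

## Spectral prediction

The theoretical ratio of one FP is
$R = d \cdot \int S(\lambda) T_{\mathrm{em1}}(\lambda)\,d\lambda \;/\;
\int S(\lambda) T_{\mathrm{em2}}(\lambda)\,d\lambda$, integrated by the
trapezoid rule with the integration range clipped exactly at top-hat
band edges (interpolated endpoints), which keeps the quadrature error
second-order in the grid step. The detector factor $d = 0.893$ models
an instrument that detects em1 at 89.3% the efficiency of em2. For a
two-FP fusion the no-FRET expectation combines each FP's channel
emissions weighted by excitation efficiency × brightness:
$e_{i,\mathrm{em1}} = w_i R_i/(1+R_i)$,
$e_{i,\mathrm{em2}} = w_i/(1+R_i)$, and the fusion ratio is the ratio
of summed parts — a weighted mediant, always strictly between the two
homogeneous ratios. Excitation efficiencies default to 1: they cancel
for homogeneous markers and only reweight mixtures. Predicting real FP
ratios requires measured emission spectra and filter curves; the
package validates its quadrature against closed-form integrals of
synthetic spectra instead of shipping third-party spectra.

## Plate-level statistics

* **Longitudinal growth**: $G = N_{\mathrm{day}\,t}/N_{\mathrm{day}\,0}$
  within the same well, cancelling plating variability.
* **False-negative scoring**: a treated well is scored "no growth" when
  its measurement does not exceed mean + 3 sd of a reference sample —
  either the day-0 distribution or the later-day vehicle distribution.
  Whenever plating variability exceeds per-well measurement noise,
  longitudinal scoring strictly dominates cross-well scoring; the test
  suite demonstrates this with a Monte-Carlo of 10⁴ wells (day-0 counts
  at 15% CV, 1.5-fold growth, 5% measurement noise).
* **Z'-factor**: $Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$,
  with $Z' > 0.5$ the usual screening-quality bar.
* **Reporter summaries**: per-nucleus mean reporter intensity is
  averaged per field and line first, then summarized as mean ± sd
  across fields per condition; a (field, line) cell with no objects is
  missing, never zero.
* **Culture-mode equivalence**: a two-way fixed-effects ANOVA (factors:
  treatment, culture mode; type-II sums of squares for unbalanced
  designs) on per-well or per-field measurements. A large culture-mode
  p-value supports that mono- and co-cultured assays respond alike.
  Under the null the p-value is uniform, which the suite verifies with
  1000 simulated replicates.

## The synthetic plate generator

The simulator exists so that every stage is testable against known
ground truth. Per field it renders:

* nuclei as isotropic 2-D Gaussian blobs (σ = radius/2, truncated at
  3σ) placed without footprint overlap by rejection sampling; each
  nucleus draws its line's Gaussian ratio, a log-normal total red
  signal, and a radius;
* the em1/em2 split of each blob satisfies the drawn ratio *exactly*
  before noise, so noise-free fields (`quantize = FALSE`) recover every
  ratio to ≤1e-6 end-to-end;
* a radially symmetric multiplicative illumination bowl
  $1 - a\,r^2/r_{\max}^2$ applied to background and signal alike;
* an additive per-well, per-day, per-channel offset (Gaussian, sd 1.5
  counts by default, emulating the ±1–3 count regime);
* Poisson shot noise, Gaussian read noise (sd 2), rounding and clipping
  at 4095; an optional fraction of nuclei forced to contain a saturated
  pixel;
* small dim debris blobs (≤ quarter nucleus area, random ratio) at a
  Poisson rate per field;
* optional nuclear YFP reporter signal (treatment-dependent amplitude ×
  log-normal cell factor) and a Hoechst-like counterstain channel.

Default brightness (log-normal, median 10⁵ total counts, log-sd 0.35,
radius 5 px) follows the stated exposure practice of setting bright
cells to average ~1000 counts in em1 with no saturation. Per-line
ratio distributions default to the published three-line monoculture
calibrations (0.560 ± 0.025, 0.737 ± 0.031, 1.067 ± 0.045). Note that
*measured* monoculture sds on simulated images exceed the generator sds
slightly (shot noise contributes ~0.5–1% of $R$); the printed values
were themselves measurements, so this is the faithful reading, and it
is why the default plate's calibrated k = 3 windows are disjoint by a
small margin, exactly as in the original three-line panel
(0.635 < 0.644).

A master seed drives documented per-field sub-seeds
(`field_seed(seed, well, field, day)`), so any single field is
reproducible in isolation and a fixed seed reproduces the whole plate
bit-identically.

What the generator does **not** emulate: nucleolar holes and chromatin
texture, cell clumping and confluent monolayers (nuclei are placed
disjoint, so segmentation-splitting is exercised only on constructed
fixtures), FRET between fusion partners, photobleaching and FP
maturation, autofluorescence, plate-wall reflections (only a warning
heuristic exists, `check_edge_background()`), focus drift, and mitotic
or dying-cell morphology. Passing tests therefore certify the analysis
chain under the stated statistical model of the data, not segmentation
robustness on difficult real images.

## Problem sizes and runtime choices

The test suite runs everything at desk scale: the default synthetic
plate is 256 × 256 px fields, 4 media-only wells, 5 monoculture wells
per line (≈550 calibration objects per line) and 3 three-line mixed
wells at 2 fields per well; ratio-level simulations use 10⁵ draws per
line (k = 3 coverage) and 10⁶ draws (k = 5 misassignment); the
false-negative Monte-Carlo uses 10⁴ replicate wells; the ANOVA null
calibration uses 1000 replicates. These sizes give sampling error well
inside every asserted tolerance while keeping the whole suite under a
minute on one CPU.

## Degenerate inputs and tie-breaks

* Constant images segment to zero objects (Otsu is undefined there).
* A calibration with σ = 0 cannot support windows and errors.
* Z' is undefined for equal control means; growth folds are undefined
  (NA, with a warning) for zero baselines.
* `counterstain_fraction` with no objects returns `NA`, distinct from
  an observed 0.
* Pixel values above 4095 are rejected at load, never clipped, to
  surface acquisition problems.
* Pixel coordinates follow R conventions: (row, col) with 1-based
  indices, origin top-left (field indices in file names count from 0);
  centroids are intensity-unweighted centroids of the label mask.
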