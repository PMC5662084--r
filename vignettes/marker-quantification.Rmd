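---
title: "Quantifying marker expression on circulating tumor cell thumbnails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker expression on circulating tumor cell thumbnails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circulating tumor cells (CTCs) enriched from peripheral blood can be probed
for treatment-target expression — here HER-2 — by adding a fourth
fluorescence channel to the standard DAPI / cytokeratin / CD45 panel.
Visual scoring of the exported per-event thumbnail images is poorly
reproducible: display scaling makes dim signals look bright, and readers
disagree on a large fraction of events. `markerquant` replaces the visual
call with a measured one: it restores the archived images to their native
intensity scale, finds each event's outline in every channel, measures the
marker intensity inside the outline, and classifies expression as negative,
dim or bright against fixed intensity cut-offs. Patient-level
heterogeneity summaries and inter-reader concordance statistics sit on
top of the per-event measurements.

```{r}
library(markerquant)
```

## Intensity restoration

Analyzers acquire 12-bit images (full scale 4095) but archive 8-bit
thumbnails whose brightness was stretched to the brightest pixel of each
channel, recording the original minimum and maximum. `rescale_frame()`
inverts the stretch with the affine map

$$ I = \mathrm{min} + p \cdot \frac{\mathrm{max} - \mathrm{min}}{255}, $$

keeping non-integer values (no re-quantization), so every downstream
statistic operates on instrument units. The reconstruction error is
bounded by half a quantization step, $(\mathrm{max}-\mathrm{min})/510$,
per pixel.

Because no public convention exists for where the original range is
stored, the loader takes a pluggable header parser. The default accepts
an ImageDescription string `min=<int>;max=<int>` when the TIFF carries
one, and otherwise a sidecar `<file>.hdr.json`; the fixture writer emits
the sidecar (the TIFF writer used here does not emit ImageDescription
tags). Channel order is configuration (`channel_map`), never a positional
assumption. Coordinates are 0-based row/column pixel centers; the default
pixel pitch is 0.64 µm and is configurable.

## Segmentation

`segment_multiscale()` is deliberately parameter-free: every cut-off
derives from a robust background model, $\hat\mu = \mathrm{median}$,
$\hat\sigma = 1.4826\,\mathrm{MAD}$, of the rescaled frame. The procedure:

1. Smooth the frame at a monotone sequence of Gaussian scales
   ($\sigma = 3, 2, 1, 0$ px, coarse to fine).
2. At every scale, threshold at $\hat\mu + 3\hat\sigma$ (the conventional
   noise floor), label 8-connected components, and drop components below
   4 px or without at least 4 raw-frame pixels above the same level (the
   raw-support requirement keeps smoothing-induced noise clusters out).
3. Refine each candidate at half maximum above background,
   $\hat\mu + (\mathrm{peak}-\hat\mu)/2$, floored at the background
   threshold. A Gaussian-blurred edge keeps its half-maximum crossing at
   the edge position, so this contour is approximately invariant across
   smoothing scales — which is what makes the next step meaningful.
4. Merge across scales: candidates that overlap between consecutive
   scales form tracks; each track reports the finest-scale contour whose
   area is stable (relative change below 20% against the next coarser
   scale), falling back to the coarsest when none is stable. Nested
   duplicates are dropped.

Two consequences matter downstream. First, a frame that is pure
background returns no object at all, so the measured mean intensity of an
undetectable marker channel is exactly 0 — negativity is encoded by a
separating gap, not by a threshold on a noisy mean, and no background
subtraction is ever applied. Second, the 3σ floor means objects whose
amplitude is below roughly three background standard deviations are
invisible by construction; the dim class therefore starts strictly above
zero signal.

When a channel contains several objects, `select_event_object()` keeps
the one with the largest overlap with the DAPI nucleus mask (ties: larger
area, then distance to the thumbnail center). Each channel is segmented
independently and then reconciled against the nucleus; this choice — as
opposed to restricting the marker search to the cell region up front — is
documented here because either reading is defensible; independent
segmentation keeps the per-channel contract testable in isolation.

## Measurements

`measure_channel()` computes, per object and channel: eccentricity
(moment-based, $\sqrt{1-\lambda_2/\lambda_1}$ with a 1/12 pixel-extent
correction), perimeter, mean / maximum / standard deviation of intensity,
size (px), mass (intensity sum) and `perimeter2area`
$= P^2 / (4\pi A)$, normalized so a perfect disk gives 1. The contour is
the 0.5-level mid-crack polygon of the mask (vertices at pixel-boundary
midpoints, counter-clockwise), which makes perimeters bit-reproducible;
a digital disk of radius 5 measures $P^2/(4\pi A) \approx 1.26$.
Discretization allows values marginally below 1 only for masks of a few
pixels (e.g. a 2×2 square, 0.93); fixture-scale blobs always sit at or
above 1. `relative_overlay()` reports $|A \cap B| / |A|$ with the DAPI
mask as denominator. The displayed marker statistic is the mean inside
the contour; the median is carried alongside because display tools
commonly show it.

`intensity_difference_test()` is a two-sided Welch test on the in-contour
pixel samples of two events. Pixels are treated as independent draws; the
spatial correlation introduced by optics and smoothing makes the stated
p-values anti-conservative, which is acceptable for its screening role
here and is flagged as a caveat.

`fit_antigen_calibration()` converts intensity to antigens per cell by
ordinary least squares against bead-calibrated reference counts; it
reports slope, intercept, and $r^2$ computed from residuals.

## Classification and cohort summaries

`classify_her2()` applies two cut-offs on the restored scale, default
`t_dim = 0` and `t_bright = 100`: a mean of exactly 0 (the no-object
encoding) is negative, the open interval (0, 100) is dim, and means
$\ge 100$ are bright. The boundary semantics are fixed this way because
the dim band is elsewhere restated as 1–99 with ≥ 100 bright.
`summarize_patient()` labels a patient `all_positive` when no event is
negative, `none_positive` when none is dim or bright, `mixed` otherwise;
single-event patients follow the same rule. `cohort_breakdown()` pools
events, reports class percentages and patient counts, and sorts patients
by decreasing positive fraction. Manual ordinal scores (0, 1+, 2+, 3+)
map to binary positivity at 2+ and above.

`concordance_histogram()` categorizes each event by its vote split among
R reviewers: unanimity (split by direction), one dissenter, two or more
dissenters short of a tie, and the exact tie (even R only). For the
six-reviewer design these are the familiar 6-0, 5-1, 4-2 and 3-3
categories; the majority direction of each non-unanimous category is
recorded rather than collapsed. `manual_auto_correlation()` reports
Pearson's r with a Fisher-z 95% interval (the interval is an addition;
bare r is what is usually quoted).

## Synthetic fixtures: what they emulate and what they do not

`generate_thumbnail()` renders each channel as a flat-top disk whose
in-disk noise-free value equals the requested `plateau` (background
included), with a Gaussian edge skirt of standard deviation `softness`,
over Gaussian background noise (defaults: background mean 20, standard
deviation 6.6 — the background level typical of archived thumbnails —
80×80 px at 0.64 µm). Rendering is at the 12-bit integer grid, then
archived to 8 bit with recorded min/max headers exactly as the loader
expects; generation is byte-identical per seed and each image carries a
JSON truth manifest.

Design notes:

* Flat-top disks (not Gaussians) make the in-mask truth mean equal the
  plateau, so the quantification oracle is exact. The default softness of
  0.25 px keeps the half-maximum contour inside the true disk; with
  softer edges (≥ 1 px) the contour sits partway down the skirt and the
  measured mean is diluted by a few percent — tests that check exact
  plateau recovery use near-hard edges, tests of detection and centroid
  accuracy use softer ones.
* `generate_population()` samples per-event marker means directly:
  negative exactly 0, dim and bright from zero-truncated normals. The
  defaults (class sizes 373/496/361, dim N(86.5, 15), bright
  N(113.5, 15)) put the expected accuracy of the 0/100 cut-offs at about
  0.87, a regime with genuine spill across the bright boundary; the
  closed-form expected accuracy is returned alongside as the oracle.
* `generate_cohort()` draws per-patient event counts as 1 + negative
  binomial (mean 30, size 0.35 — CTC counts are strongly overdispersed)
  and a latent positive fraction from Beta(1.2, 1.9) (pooled positive
  fraction ≈ 0.39, bright ≈ 6% of positives). All-positive / none-positive
  patient counts are emergent, not parameters.
* `generate_reader_scores()` flips the true status independently per
  reviewer. Unanimity under a common flip probability p is
  $(1-p)^6 + p^6$; the defaults used in the reproduction script (0.18
  for scaled display, 0.105 for quantitative) invert that expression for
  unanimity rates of roughly 30% and 50%.

What the fixtures do **not** emulate: point-spread functions, vignetting,
channel bleed-through, touching cells, debris, or autofluorescence
gradients. Passing tests therefore demonstrate correctness of the
measurement chain on well-formed events, not robustness to every artifact
of real cartridges; the segmentation contract (no detection without
signal above the noise floor) is the part most directly transferable.

## Numerical choices and degenerate inputs

* Quantization distorts MAD-based scale estimates when a bright object
  stretches a channel's archived range (step sizes of several intensity
  units); the threshold then errs low by up to ~30%, which widens masks
  slightly but never manufactures detections on signal-free channels,
  where the archived range — and hence the step — is small.
* Constant frames yield a background model of (constant, 0) and no
  objects. Already-rescaled frames, non-congruent masks, empty
  populations, zero-variance correlation inputs and incomplete reader
  matrices raise errors rather than guessing.
* Ties in event-object selection break deterministically (overlap, then
  area, then center distance); contours are traced counter-clockwise;
  all generators restore the caller's RNG state.
* Problem sizes in the test-suite and reproduction script (200 detection
  fixtures, 1230-cell populations, 132-patient cohorts, 1000 random
  reader panels) were chosen as the smallest sizes at which the binomial
  or sampling error of each checked quantity is well inside the asserted
  tolerance.

## Worked example

```{r, eval = FALSE}
dir <- tempfile(); dir.create(dir)
spec <- event_spec(blobs = list(
  DAPI = list(radius = 5, plateau = 900),
  CK = list(radius = 7, plateau = 500),
  MARKER1 = list(radius = 6, plateau = 150)), seed = 1)
generate_thumbnail(spec, file.path(dir, "event.tif"))

rec <- measure_event(load_thumbnail(file.path(dir, "event.tif")))
rec$measurements$MARKER1$mean_intensity  # ~150, the generator truth
classify_her2(rec$measurements$MARKER1$mean_intensity)  # "bright"
```

## Known limitations

* The multi-scale segmentation implements an observable contract (empty
  result on pure background, background-derived cut-offs, scale-stability
  merging) with Gaussian smoothing and half-maximum refinement; it is not
  a nonlinear-spectral multi-scale formulation, and the module boundary
  is designed so such an implementation could be dropped in.
* Mean intensities are reported in instrument units; absolute antigen
  densities require the calibration line and inherit its assumptions
  (linearity through the measured range).
* Touching cells are not split; the nucleus-overlap selection picks one
  object per channel per event.
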