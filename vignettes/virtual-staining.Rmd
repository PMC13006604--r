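---
title: "Virtual brightfield staining: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual brightfield staining: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualstain)
```

## The problem

Multiplex imaging modalities — imaging mass cytometry (IMC), cyclic
immunofluorescence, CODEX, multiplex IF — record dozens of molecular marker
channels per tissue section, each a nonnegative intensity plane. Pathology
practice, however, is built on transmitted-light brightfield images of
chemically stained tissue (H&E, IHC, special stains), where a bright
background is darkened by light-absorbing dyes. `virtualstain` synthesizes
such brightfield images directly from multiplex channels, deterministically
and without any learned generator, so the output can be trusted for
quantitative downstream use: what appears in the image is exactly what the
markers measured.

## The stain model

Each virtual stain is a set of *stain classes* $i = 1 \dots n$ (for H&E:
nuclei, eosinophilic stroma/cytoplasm, purple epithelial tissue,
erythrocytes). A class has a reference transmission color
$(S_{i,R}, S_{i,G}, S_{i,B}) \in [0,1]^3$, a scaling constant $k_i \ge 0$,
and a marker list. Its intensity image is the average of the normalized
marker channels $\tilde M_{i,m}$ assigned to it:

$$I_i = \frac{1}{N_i} \sum_{m=1}^{N_i} \tilde M_{i,m}.$$

Two renderers map intensities to RGB, per color channel
$c \in \{R, G, B\}$ with background (maximum) transmission $c_c$ and floor
(minimum) transmission $d_c$:

* **additive** (linear subtractive):
  $\mathrm{out}_c = c_c - \sum_i k_i I_i\,(c_c - S_{i,c})$, clipped to
  $[0,1]$;
* **physical** (Beer–Lambert):
  $\mathrm{out}_c = d_c + (c_c - d_c)\exp\!\big(-\sum_i k_i I_i\,(c_c -
  S_{i,c})\big)$.

The physical method models transmitted light decaying exponentially with
the amount of absorber along the optical path; it therefore saturates
gracefully toward the floor instead of clipping, and for white background /
black floor it dominates the additive output pixelwise
($e^{-x} \ge 1 - x$), with the gap bounded by $x^2/2$ for summed exponent
$x$. The additive method is retained as the cheap first-order
approximation.

Numerical conventions:

* All internal values are floats in $[0,1]$; conversion to 8-bit happens
  only at export, rounding half away from zero.
* Additive output is clipped to $[0,1]$ (the formula goes negative for
  large exponents). Whether to clip or rescale here was an open choice; we
  clip, because rescaling would make a pixel's color depend on unrelated
  image content.
* If a stain color exceeds the background in some channel
  ($S_{i,c} > c_c$), the attenuation coefficient would be negative and the
  stain would *brighten* the image above its background — physically
  implausible for an absorbing dye. The renderer clamps the coefficient at
  zero and warns.
* A class whose marker list matches no channel contributes zero absorption
  rather than raising an error: real panels frequently lack markers for
  some class (e.g. no mucin channel for a PAS polysaccharide class), and
  the correct rendering of an absent stain is simply no staining.
* 3D volumes are rendered slice-wise; slices are independent under the
  model, and slice spacing is passed through as metadata.

Default colors: no published numeric RGB values exist for these stains (in
real slides the color is an emergent property of dye chemistry), so the
shipped palettes are package constants chosen to look like routine H&E,
DAB, trichrome, PAS, silver and toluidine slides. They live in editable
YAML files under `inst/profiles/`, each with optional named palette
variants emulating different scanner color responses, and $k_i = 1$
throughout; users are expected to tune colors and scalings against their
own reference material.

## Channel selection

Channels are mapped to classes by name. Channel names in the wild are
messy — `DNA1_Ir191`, `aSMA (Pt196)`, `141Pr-Col1A1` — so matching operates
on canonical tokens: case-folded, metal-isotope tags removed, Greek letters
transliterated, punctuation stripped. Isotope tags are only removed when
they are delimited by separators and carry a 3-digit mass, which keeps
markers like `CD103` (which merely *looks* like a cadmium tag) intact.

Each shipped stain preset carries a curated alias lexicon per class.
`assign_by_lexicon()` is the default route; an LLM route builds a
deterministic prompt (task, stain, classes with description and display
color, the complete channel list, and a strict JSON output schema) and
parses the response back into an assignment. The package ships an *offline
mock provider* that answers prompts from the lexicon, so the whole LLM path
— prompt construction, response parsing, error handling — is testable with
no network; remote providers plug in behind the same one-function
interface. A channel may legitimately belong to several classes (one marker
can drive two custom colors); each class averages its own set
independently.

Agreement between several selectors is summarized by the consensus Jaccard
index. The consensus rule is not uniquely determined by "determined a
consensus", so we document our interpretation: a channel enters the
consensus set of a class when a *strict majority* of models chose it. Each
model is scored as the mean over classes of the Jaccard similarity between
its set and the consensus set, with $J(\emptyset, \emptyset) = 1$ (perfect
agreement on absence), and the statistic is the mean of per-model scores.

## Pre- and post-processing

The fixed pipeline order is: normalize → optional per-channel median /
unsharp filtering → optional CLAHE on the nuclear class intensity → render
→ resample.

* **Normalization**: linear mapping of the 1st–99th percentile window to
  $[0,1]$, then clipping. The percentile window (rather than the global
  maximum) is deliberate: IMC hot pixels would otherwise compress the
  entire dynamic range. A constant plane maps to zero. The exact
  normalization used upstream of the model is a degree of freedom of the
  method; percentile normalization is our default and is configurable.
* **Median filter** (default radius 1, i.e. 3×3): removes isolated IMC hot
  pixels. Symmetric-reflection borders.
* **Unsharp masking** (default amount 1, Gaussian sigma 1 px):
  $x + a\,(x - G_\sigma x)$, for deblurring diffuse fluorescence signal.
* **CLAHE** (default tile 64 px, clip limit 0.01 of the tile histogram):
  applied to the *nuclear intensity plane before rendering*, not to the
  rendered RGB, so that all nuclei reach a similar staining strength
  without shifting the stain colors. Planes smaller than one tile fall
  back to global equalization with a warning.
* **Spline resampling** (orders 0/1/3): pixel-center convention with no
  half-pixel shift; cubic interpolation reproduces smooth ramps to within
  interpolation error, and downscaling applies a Gaussian anti-alias
  prefilter with $\sigma = (f-1)/2$ for reduction factor $f$.
* Large images are processed in tiles (default 2048²) with overlap margins
  equal to the filter kernel radius, which makes tiled output bit-identical
  to untiled output; this is asserted in the test suite on 256² images.

## Degradation simulator

Restoration models are trained on synthetic corruption of clean images;
this package provides the corruption half. `make_training_pair()` applies,
in order: a dihedral geometric transform (shared by input and target), a
resolution stair-step artifact (downscale then nearest-neighbor upscale),
Gaussian blur, noise, and color jitter. Noise can be applied in RGB, HSV,
or hematoxylin/eosin/DAB-deconvolved (HED) space; the HED route models the
fact that noise in IMC- or fluorescence-derived virtual stains lives in
stain concentration, not in display RGB. The stain basis defaults to the
classic published H/E/DAB absorbance vectors used throughout brightfield
color deconvolution, stored in the package rather than hard-coded at call
sites; optical densities are floored at $\varepsilon = 10^{-6}$ before the
logarithm. Every stochastic operation is a pure function of (input, spec,
seed). Hot pixels default to salt (channel maximum). The ranges of random
downscale factors, blur widths and noise magnitudes appropriate for a given
training corpus are not prescribed; the defaults are conservative and all
are settable. Network architecture and training are out of scope — the
output is paired `degraded/` and `clean/` directories plus a JSON manifest
of seeds and specs that any trainer can consume. Trained restorers are
applied with `sliding_window_apply()`, which feathers overlapping tile
outputs with triangular weights; identical tile outputs blend exactly.

## Metrics

`enhancement_efficiency()` implements

$$E = \frac{\mathrm{edge}_f / \mathrm{edge}_u}
           {\mathrm{noise}_f / \mathrm{noise}_u},$$

where `edge` is the mean Sobel gradient magnitude of the luminance
($0.299R + 0.587G + 0.114B$) and `noise` is the standard deviation of
high-frequency residuals. "High-frequency residual" is not uniquely
defined; we use luminance minus its Gaussian blur with $\sigma = 1$ px and
document this as an interpretation. $E$ is invariant to constant offsets
and to joint contrast scaling; $E > 1$ means the filter removed
proportionally more noise than edge signal.

`paired_quality_metrics()` reports PCC over flattened pixels, MSE on the
8-bit scale, PSNR from that MSE (capped at 100 dB for a perfect pair),
MS-SSIM on luminance (standard five-scale weights, scales reduced and
weights renormalized when the image is too small for the 11-px window), and
EMD as the mean over R, G, B of the 1-D Wasserstein distance between
256-bin channel histograms, in 8-bit gray-level units. Whole-slide pairs
are evaluated region-wise (`paired_quality_metrics_regions()`), reporting
the mean of per-region metrics — deliberately *not* the metric of the
concatenation, so that each region contributes equally regardless of
content. A constant pair has undefined correlation; it is reported as NaN
with a warning rather than silently dropped.

## Synthetic fixtures

`generate_fixture()` builds a multiplex image with known ground truth:
soft-disc nuclei at non-overlapping dart-thrown centers (at most 100×
`n_cells` attempts before erroring), smooth random ECM fields, thresholded
epithelial regions, small erythrocyte clusters, a sinusoidal vessel ribbon,
and modality noise (hot pixels for IMC-style, optical blur for IF-style).
Per-cell intensities are drawn from a beta(5, 1.5) distribution scaled into
[0.6, 1]. Channel names use isotope-tagged aliases (`DNA1_Ir191`,
`Col1A1_Tm169`, …) so channel selection is exercised end to end. The
generator emulates the *statistical* features the pipeline must handle —
nonnegative structured signal, per-structure markers, modality noise,
realistic naming — and none of the biological ones (no cell morphology
variation, no marker co-expression structure, no spatial biology). Tests
passing on fixtures therefore validate the computational contract, not
biological fidelity on real panels.

The default test and acceptance problem sizes are 128²–256² images with
25–60 nuclei at 1 µm pixels, upsampled 1 µm → 0.5 µm where the enhancement
scenario calls for it; these sizes were chosen as the smallest at which the
spatial statistics (percentiles, block artifacts, binomial hot-pixel
counts) are stable.

## Known limitations

* Spectral simulation is limited to the three display wavelengths; real
  dye spectra and microscope filters are not modeled.
* Stain colors are transmission constants per class; co-localized stains
  interact only through the summed exponent, not chemically.
* The lexicons cover common marker aliases, not every panel's naming;
  unknown names are ignored (and visible in `unassigned`), or can be
  routed through the LLM path.
* The OME-TIFF writer emits uncompressed baseline files (one strip per
  plane); pyramidal or compressed output is out of scope.
* Real-slide stain normalization, registration to real H&E, and stain
  unmixing of real brightfield input are out of scope.
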