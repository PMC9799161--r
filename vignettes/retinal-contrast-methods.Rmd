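---
title: "Simulating retinal contrast: model, stimuli, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating retinal contrast: model, stimuli, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinaglare)
```

## The problem

Before any neural processing happens, the optics of the eye have already
transformed the stimulus. Light scattered inside the cornea, lens and
vitreous — intraocular veiling glare — redistributes a small fraction of
every scene point's luminance across the whole retina. Because every pixel
receives a sum of tiny contributions from every other pixel, the pattern of
light on the receptors (the *retinal contrast*) depends on the content of
the entire scene: equal scene luminances become unequal retinal values,
uniform patches become shallow gradients, and the global dynamic range
shrinks.

This matters most for lightness illusions. These stimuli are built around a
"null experiment": two regions of interest (ROIs) with *identical* scene
luminance that nonetheless look different. Quantifying what glare does to
those equal luminances is a precondition for interpreting the illusions,
and it produces a striking regularity — in simultaneous-contrast
configurations the ROI that *looks darker* is the one that *receives more
light* after glare ("glare's paradox"), so neural processing must not only
cancel the optical veil but overcompensate it. In assimilation
configurations the redistribution goes the other way and no paradox
arises. This package computes the optical transformation and the analyses
around it; it deliberately does **not** model appearance.

## The model

### Glare spread function

The point-by-point redistribution is governed by the CIE disability-glare
standard: the equivalent veiling luminance per unit glare illuminance,
$L_{eq}/E_{gl}$, as a function of the angular separation $\theta$ (degrees)
between the donor and the receiving location, the observer's age $A$
(years) and an iris-pigmentation factor $p$:

$$
\frac{L_{eq}}{E_{gl}}(\theta) =
\left[1 - 0.08\left(\tfrac{A}{70}\right)^4\right]
\left[\frac{9.2\times10^{6}}{\bigl(1+(\theta/0.0046)^2\bigr)^{1.5}}
     +\frac{1.5\times10^{5}}{\bigl(1+(\theta/0.045)^2\bigr)^{1.5}}\right]
$$
$$
\quad+\;\left[1 + 1.6\left(\tfrac{A}{70}\right)^4\right]
\left[\frac{400}{1+(\theta/0.1)^2}
     + p\!\left(\frac{1300}{\bigl(1+(\theta/0.1)^2\bigr)^{1.5}}
     +\frac{0.8}{\bigl(1+(\theta/0.1)^2\bigr)^{0.5}}\right)\right]
\;+\;2.5\times10^{-3}\,p .
$$

Defaults are $A = 25$, $p = 0.5$ (a young observer with brown eyes —
minimal-glare vision). Between 1 arcmin and 60° the function falls by
$10^{7.98}$, i.e. about 8 log$_{10}$ units, without ever reaching zero or a
constant asymptote; this is why no truncated-kernel shortcut is acceptable.

One deliberate choice: the full published standard contains an additional
wide-angle stray-light term proportional to $\theta^4$ that becomes
dominant beyond roughly 10–30°, making the function non-monotone and
shrinking the 1-arcmin-to-60° span to about 6 log units. The simulation
this package reproduces treats the glare spread as strictly decreasing
across its whole 60° field with an 8-log-unit span, so `gsf_value()` omits
that term. All kernels are normalized afterwards, so only the *shape*
matters.

```{r gsf}
log10(gsf_value(1/60) / gsf_value(60))
```

### Kernel construction

`build_kernel()` evaluates the GSF on the full offset grid. Choices a
maintainer should know about:

* **Radius.** The kernel radius is `max(rows, cols) + 1` pixels (one extra
  for symmetry), so a kernel centered on any image pixel covers the entire
  image: every pixel affects every other.
* **Angle at zero offset.** The GSF diverges at $\theta = 0$. The center
  weight is evaluated at half a pixel pitch
  ($\theta = \text{arcmin/px} / 120$ degrees): finite,
  resolution-consistent, and absorbed by the normalization.
* **Sphere-to-plane mapping.** The standard describes light on the sphere
  of visual directions; images are planar. A pixel at planar distance $d$
  maps to $\theta = \arctan(d\tan(\text{pitch}))$. No additional
  solid-angle Jacobian is applied, since the unity normalization absorbs
  the global scale; the mapping is isolated in one internal function
  (`pixel_angle_deg`) so alternatives can be swapped.
* **Normalization.** Weights are divided by their total sum so they add to
  1 (checked to $10^{-12}$); convolution then redistributes light without
  creating or destroying it.
* **Angular calibration.** The default pitch is 10°/2048 px =
  0.293 arcmin/px, derived from the reference viewing geometry (a 2048-px
  target spanning 10° at 24 inches). The stimulus descriptions also quote
  0.24 arcmin/px, which is inconsistent with 10°/2048; the field-of-view
  derivation is used and the discrepancy simply noted.

### Convolution

`convolve_glare()` computes a wrap-free linear convolution: the scene is
padded by the kernel radius on every side, transformed at a composite FFT
size at least as large as the padded image, multiplied with the kernel
spectrum, inverse-transformed and cropped. Padding width equal to the
kernel radius means circular wrap-around can only contaminate the padding
margin, never the cropped interior — the result is exactly the convolution
of the infinite padded scene.

* **Replicate padding** (the reproduction mode) repeats the outer rim: a
  stimulus with a max-luminance rim behaves as if displayed on a uniform
  white surround nine times its area; a black rim as if in a darkroom.
  **Constant padding** is provided for idealized tests.
* All arithmetic is 64-bit. The transforms run in compiled code (FFTW)
  over three preallocated buffers; because the kernel is even about its
  center its spectrum is purely real and is stored at half size. This
  keeps peak memory near 3.5 GB for the largest built-in target
  (2048 × 4096 scene, 8195² kernel) instead of the several-fold larger
  footprint of generic R-level FFT calls.
* Because the kernel is positive with unit sum, the convolution is an
  averaging operator: output values nest strictly inside the input range,
  and a uniform scene is reproduced to $10^{-9}$.

**Energy accounting.** For a uniform image the output sum equals the input
sum to $10^{-9}$. For structured images under replicate padding, light
flows across the image boundary: a white outer band imports glare from its
virtual white surround, a black band exports it. Measured on the built-in
targets this flux is up to about ±1.5% of total energy (e.g. +0.9% for the
white-banded target A, −1.4% for the black-banded C and D, +0.1% for the
Mondrian). The package reports the ratio in `energy_ratio` rather than
forcing it to 1; a tolerance tighter than ~2% on that ratio is not
physically meaningful for boundary-dominated stimuli, because the GSF's
long tails genuinely carry that much light across the rim.

## The stimuli

All generators return a `target_bundle`: digit map, display calibration,
ROI masks, declared appearance order, geometry and every chosen dimension
in metadata. The equal-luminance ROI pairs share a single 8-bit digit, so
their scene luminances are *exactly* equal before convolution.

### Display calibration

The reference display table is three photometer points — White digit
255 → 450 cd/m², Gray 145 → 136, Black 21 → 2.24 — giving a 200:1
(2.3 log) range. Between measured digits the calibration interpolates
piecewise-linearly (a fully sampled 256-entry table bypasses
interpolation); digits below the calibrated black point clamp with a
warning to tolerate antialiased edges. One source note: the Gray is quoted
both as 136 cd/m² (calibration paragraph) and as 30 cd/m² in a one-line
summary; the generators use 136.

### Contrast + Assimilation targets A–D

The published geometry consists of figures plus printed constraints: Gray
segments occupy 14% of the area in all variants at identical locations;
White/Black occupy 57%/29% in A–B and 29%/57% in C–D; A and C have large
uniform Contrast surrounds while B and D have reduced surrounds on a
striped ground; the outer band is White in A–B and Black in C–D. The
generator derives its dimensions from these constraints once:

* With equal-size White and Black Contrast surrounds and a balanced
  stripe pattern, the entire White-minus-Black surplus (57 − 29 = 28% of
  the area) must be carried by the outer band, fixing its half-width at
  155 px at the 2048 scale.
* The constant gray frame and half-field divider take ~9.6% of the area;
  the remaining gray budget (14% total) fixes the assimilation bar width
  given the 380 × 120 px contrast ROIs.

The generator verifies the realized fractions and refuses sizes where they
cannot hold within 1%. Declared appearances: contrast gray-in-white is
darker; assimilation gray-in-black (black flankers) is darker.

At full scale the computed retinal ranges are ~67% of the 2.3-log input
range for A and ~95% for C, matching the published analysis; target D
comes out at ~92% against a published 100%. Under the printed area
fractions, a black-banded target with *reduced* surrounds necessarily
brings striped Whites closer to the darkest corner pixels than the
large-surround C does, so its minimum cannot drop below C's; a 100% range
would require an essentially glare-free black region that these
constraints do not permit. The reconstruction keeps the printed fractions
(which are stated as measurements) over the printed range figure (which
the published analysis reads off an 8-bit log-mapped image), and reports
the discrepancy rather than adjusting geometry to chase it.

### Todorović circles and crosses

A 2048 × 4096 panorama (20° × 10°): four identical gray disks along the
top, four identical gray crosses along the bottom; the left half shows
them on the uniform light-gray background (controls), the right half the
illusions. The four illusion panels fill the right-half quadrants edge to
edge: a Black and a White contrast surround behind the disks, and a solid
White and a solid Black foreground with a cross-shaped slit cut into each,
behind which the crosses sit with ~14 px (≈ 4 arcmin) of background
clearance around every 380 × 25 px arm. Disk radius is 157 px
(≈ 46 arcmin), so contrast edges sit roughly ten times farther from their
gray than the assimilation slit edges — which is exactly why the two
illusions receive such different glare. The background is the one stimulus
luminance the published description leaves unstated; digit 200 (≈ 293
cd/m², a light gray well separated from the 136 cd/m² elements) is used.
Scan rows through the disk and cross centers are recorded in the bundle.
With this layout the 200:1 scene compresses to a ~73:1 global retinal
range (published: 62:1, agreement within ~18%); the per-scan log spans match the published ones qualitatively (the
contrast row compresses far less than the assimilation row) but not
numerically, which points at remaining foreground details the figures do
not fix.

### Black-and-white Mondrian

A seeded random tiling of ~110 achromatic papers of varying sizes and
shapes under a vertical illumination gradient (bright at the bottom), with
two circular ROIs: a high-reflectance paper near the top and a
low-reflectance paper near the bottom whose luminances are identical. The
display table is log-linear in digits (digit ∝ log luminance), so the
multiplicative gradient is an additive digit ramp and the equality and the
80%-of-log-range anchor hold *exactly* by construction: both disks carry
digit 184 and the map maximum is forced to digit 235 = 184 + 51, where 51
digits correspond to 20% of the 2.3-log range. This satisfies the
gradient-tuning contract deterministically instead of by iterative
re-drawing. `invert_target()` produces the photographic negative; since
both circles share one digit they remain equal under any calibration, and
the caller re-declares which appears darker.

### What the generators do not emulate

Real displays add spatial non-uniformity, inter-pixel light spread and
ambient reflections; the generators produce ideal piecewise-constant
digit maps. Passing tests on them shows the *optical model and analyses*
behave correctly, not that any particular physical display was
reproduced. External artwork (e.g. checkerboard-and-shadow scenes) is
deliberately not generated — the pipeline accepts any user-supplied
calibrated image and calibration CSV instead.

## Analysis conventions

* **Log mapping.** `log_map()` scales a linear image to 8 bits over a
  chosen log range (default 2.3):
  digit = ⌊255(1 + log₁₀(v/v_max)/range) + 0.5⌋, clipped to [0, 255].
  Rounding is half-away-from-zero, applied once. v_max is per-image: the
  scene and the retina are each anchored to their own maximum.
* **Percent of range.** The same convention on a 0–100 scale; 100% is the
  image maximum, 0% is 10^−range below it.
* **ROI statistics** are reported over the full mask and over its
  interior (mask eroded by 2 px), because after glare the outermost 1–2
  region pixels carry extreme edge-gradient values; printed per-region
  ranges describe region interiors better than mask edges.
* **Histograms** use 256 bins, peak-normalized; "linear" bins linear
  values on [0, max], "log" bins log₁₀ relative values on [−range, 0] —
  both are emitted since either reading of "linear histogram" is useful.
* **Paradox reports** compare *linear mean* retinal contrast between the
  declared darker and lighter ROI of each pair; the paradox flag is
  mean(darker) > mean(lighter). Appearance is an input (declared), never
  predicted.
* **Pseudocolor.** The `cmap` table has 64 bands of 4 digits (8 hue
  progressions × 8 steps) running black → white so lightness order
  survives; its band covering digits 194–197 is pinned to the green
  triplet [192, 255, 64], the published anchor, and the remaining bands
  are this package's construction — the table is CSV-replaceable should
  the original table become available. The `3-3-2 RGB` table is the
  standard bit-partition LUT (blue peaks at 192, entry 255 is yellow); it
  cycles quickly and reveals shallow gradients at the cost of lightness
  order. `superposition()` composites four quarter-images and paints a
  mask red to locate an input edge inside a post-glare gradient.

## Numerical choices and degenerate inputs

* FFT sizes are the smallest 7-smooth integers ≥ the padded size; the
  identity of the FFT path with a brute-force spatial convolution is
  tested to 10⁻¹⁰ on small instances for both padding modes.
* `gsf_value()` rejects non-positive or non-finite angles naming the
  offending value; kernels refuse degenerate geometries (any dimension
  < 2) and estimate their memory before allocating, failing with an
  explicit resource error over the configured cap.
* Kernels are cached per (geometry, observer) within a session; kernels
  with side > 5000 px are rebuilt on demand rather than cached.
* Scene values of exactly 0 are admitted by the container but log-based
  analyses require strictly positive images; calibrations with positive
  black points guarantee this.
* Tiny negative FFT round-off (~10⁻¹⁶, only possible in all-zero regions
  under constant padding) is clipped to 0.

## Problem sizes

The test suite exercises the full published conditions: the 2048² targets
with their 4099² kernel and the 2048 × 4096 panorama with its 8195²
kernel, plus reduced 512-px renderings of the same 10° geometry for the
fast unit tests (the physics is set by angles, not pixels, so the small
renderings track the full-scale values within a few percent). A full
2048² target runs in well under a minute on one CPU; the panorama in a
few minutes.

## Known limitations

* No wavelength dependence, pupil-size model, or pre-retinal absorption:
  the output is normalized relative light on the retina, not retinal
  luminance.
* No appearance or neural model; paradox reports rely on declared
  orderings.
* The A–D surround geometry is a constrained reconstruction from figure
  descriptions; quantities that depend on exact surround placement (most
  visibly target D's global range, and B's, published as 52% vs ~62%
  here) inherit that uncertainty, while fraction-constrained and
  ROI-level results (A, C, the paradox pattern, the Mondrian anchors) are
  robust to it.
* Boundary energy flux under replicate padding is real physics of the
  long-tailed GSF (±1.5% on the extreme targets); treat `energy_ratio`
  as a diagnostic, not an error to be zeroed.
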