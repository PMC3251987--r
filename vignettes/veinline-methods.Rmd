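---
title: "Finger-vein verification with local line binary patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finger-vein verification with local line binary patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinline)
```

## The problem

Finger-vein verification decides whether two near-infrared finger images show
the same finger. Vein patterns sit under the skin, which makes them hard to
forge and insensitive to surface condition, but the raw captures are low
contrast, blurred by skin scattering, and displaced between placements of the
finger on the device. A practical pipeline therefore needs four stages:
locate and normalize the finger region, enhance the vein contrast, align the
pair, and compare a texture code extracted from both images.

`veinline` implements that pipeline around the **Local Line Binary Pattern
(LLBP)** descriptor. Unlike the classic circular LBP, whose neighborhood is a
ring of radius $R$, LLBP compares pixels along a straight line of length $N$
through each pixel — a shape matched to the elongated, curvilinear structure
of veins.

## Pipeline stages

### Preprocessing

1. **Binarization.** The finger is bright on a dark background; the
   threshold is chosen by Otsu's criterion, i.e. the level $L$ maximizing the
   between-class variance of the 256-bin histogram, with foreground defined
   as intensity $\ge L$. The implementation searches all 255 split levels
   exhaustively; a constant image has no meaningful split and is an error.
2. **ROI crop.** The centroid of the foreground (mean row/column of
   foreground pixels, rounded half-up) centers a fixed $480 \times 160$
   (width $\times$ height) window. Near a border the window is shifted to
   lie fully inside the image rather than padded, so every ROI pixel is
   measured data.
3. **Downscaling.** The ROI is resized by ratio $0.4$ (bilinear, output
   dimensions `round(dim * ratio)`), giving $192 \times 64$ and suppressing
   pixel noise.
4. **Enhancement.** A symmetric modified Gaussian high-pass mask
   $$H(x,y) = a\left(1 - e^{-D^2(x,y) / 2 D_0^2}\right) + b,$$
   with $D(x,y)$ the Euclidean distance to the mask center, is convolved
   with the image (reflected-border padding). The center weight is $b$ and
   the weights saturate to $a+b$ with distance, so with $b<0$ the local mean
   is subtracted and vein edges are amplified.

Parameters, with units and defaults: mask side $S$ (pixels, odd; default 15,
the value tuning selects), amplitude $a$ (dimensionless, default 12.53) and
DC level $b$ (default $-4$) — the classic example values for this filter —
and the Gaussian width $D_0$ (pixels). $D_0$ has no established numeric
value; we default to $D_0 = S/2$, which ties the transition scale of the
profile to the mask extent so that the single parameter $S$ controls the
filter's spatial scale. All are exposed as `enhance.*` config keys.

The convolution output is mapped back to 8 bits by a linear min–max rescale
(a constant result maps to mid-gray 128 by convention). Only the *ordering*
of intensities matters downstream — every descriptor bit is a comparison —
so any strictly monotone mapping would give identical codes; min–max is the
simplest one that preserves full dynamic range for visual inspection.

### Alignment by phase-only correlation

Residual translation between two enhanced images $f, g$ is estimated from
the peak of the phase-only correlation (POC) surface, the inverse FFT of
$F\,\overline{G}/|F\,\overline{G}|$. The estimate is integer-pixel: the
subsequent crop takes whole-pixel windows, so sub-pixel refinement would be
discarded anyway. Spectral bins with vanishing magnitude carry no phase
information and are treated as unit magnitude rather than amplified. A Hann
window before the FFT is available (`align.window: hann`) but off by
default.

Pairs with $|t_x| \ge 20$ or $|t_y| \ge 10$ pixels (strict inequalities to
pass) are **rejected**: displacement that large is taken as evidence of two
different fingers, and the evaluation scores such pairs with the maximal
distance 1.0. Otherwise the two overlapping windows of size
$(W - |t_x|) \times (H - |t_y|)$ are extracted and all further processing
happens on this common region, so the code length varies per pair.

### LLBP codes

With line length $N$ (odd) and center position $c = (N+1)/2$, the
horizontal operator compares each of the $N-1$ non-center pixels on the
horizontal line against the center: bit = 1 iff neighbor $\ge$ center. The
vertical operator does the same on the vertical line, and the full LLBP
code concatenates horizontal then vertical bits, $2(N-1)$ bits per pixel.
Two conventions deserve a note:

* **Center index.** For odd $N$ the only well-defined integer center is
  $(N+1)/2$; the operator is sometimes written with $c = N/2$, which is
  fractional for every odd $N$ in practical use.
* **Bit order.** Bits are stored in pixel order along the line (left to
  right, top to bottom, center excluded). Hamming matching only requires a
  consistent order; the weighted binary expansion (most significant bit at
  the line's outer ends) is used when a decimal value is needed — the
  magnitude $\sqrt{h^2+v^2}$ and the grayscale visualization
  (`code_to_grayscale()`), where per-pixel values are min–max normalized to
  0–255.

A margin of $(N-1)/2$ pixels is trimmed on **all four** sides for every
line variant, including the single-direction ones. This keeps the
horizontal and vertical maps co-registered for concatenation and is the
rule consistent with the standard template sizes: on a $192 \times 64$
enhanced image, LLBP with $N=21$ gives $172 \times 44$ valid pixels
$\times\,40$ bits $= 302{,}720$ bits, and vertical-only LLBP with $N=17$
gives $176 \times 48 \times 16 = 135{,}168$ bits.

The circular LBP$(P,R)$ baseline samples $P$ neighbors on a circle of
radius $R$ (first neighbor at angle 0, counter-clockwise, bilinear
interpolation at non-integer positions, margin $\lceil R \rceil$);
LBP$(8,1)$ on $192 \times 64$ gives $190 \times 62 \times 8 = 94{,}240$
bits.

### Matching and evaluation

Two codes are compared by normalized Hamming distance,
$HD = \lVert \mathrm{code}_A \otimes \mathrm{code}_B \rVert / \mathrm{CodeLength}$,
in $[0,1]$; both codes are recomputed on the pair's common region, the only
reading consistent with cropping *enhanced images* before feature
extraction. The batch scorer counts differing bits offset-by-offset without
materializing code maps; a unit test pins it exactly equal to the
`extract_code()` + `hamming_distance()` reference route.

Evaluation enumerates all unordered image pairs — same-finger pairs are
genuine, the rest imposters — and sweeps an acceptance threshold $t$ over a
grid of 1001 points in $[0,1]$ (accept iff $HD \le t$). FAR is the percent
of imposters accepted, FRR the percent of genuines rejected; the EER is
read off at the FAR/FRR crossing with linear interpolation between the two
bracketing grid points. The grid density and interpolation are estimator
choices: the EER definition itself says nothing about discretization, and
at 1001 points the discretization error is below the two-decimal reporting
precision. `grid_search()` reruns the whole pipeline per $(N, S)$ cell with
cell-level failure isolation, reproducing the usual tuning protocol
(choose the cell with the lowest EER on a tuning subset).

## The synthetic generator

Real vein databases are not generally redistributable, so the package
ships a deterministic generator (`finger_model()`,
`generate_finger_image()`, `generate_dataset()`) that emulates the capture
conditions the pipeline is designed for: a $640 \times 480$, 8-bit capture
with a bright finger band (elliptical profile) on a dark background,
carrying 3–6 dark veins drawn as random cubic splines of width 3–8 px and
depth 45–75 intensity units — curvilinear structures at the scale the
line-shaped neighborhood targets. Finger anatomy is a pure function of the
finger seed; samples vary by integer translation jitter (±10 px horizontal,
±5 px vertical at capture scale, i.e. roughly ±4/±2 after the 0.4 resize,
well inside the alignment limits), a global brightness offset (sd 5), a
Gaussian blur (σ = 2 px) standing in for optical blur and skin scattering,
and per-pixel Gaussian noise (sd 6). These values were fixed once as a
plausible emulation of a constrained-placement NIR device; they are
arguments of `capture_params()` for users who want harder or easier
conditions.

What the generator does **not** model: irregular shading from finger
profile variation, rotation, skin texture, vein branching topology, or
sensor artifacts. Passing tests on synthetic data therefore demonstrate
that the pipeline's stages compose correctly and separate stable anatomy
from capture noise — not that any particular EER carries over to real
captures. Published EERs on real databases (around 1.8–1.9% for the line
descriptors on a private 2040-image set) require that data and are out of
reach of a self-contained test suite.

## Numerical choices and degenerate inputs

* Rounding is half-up everywhere a tie is possible (centroid, resize
  dimensions, 8-bit quantization) — deterministic and independent of the
  platform's banker's rounding.
* `step_bit(0) = 1`: the comparison is $\ge$, so equal neighbors code as 1
  and a constant image codes as all-ones, not an error.
* Constant images: Otsu thresholding errors (no split exists); enhancement
  and visualization map constants to mid-gray 128.
* Rejected alignments score exactly 1.0 so they fall on the far end of the
  distance axis and can never be accepted at any threshold below 1.
* The concatenated code's decimal value can exceed $2^{53}$ for large $N$;
  it is used only for min–max visualization, where the resulting loss of
  low-order bits is immaterial.
* Problem sizes in the test suite: oracle cross-checks run on 32×32 images,
  and the end-to-end benchmark uses 20 fingers × 10 samples (19,900 pairs),
  the standard size for a tuning subset and comfortably separable under the
  default capture parameters.

## Known limitations

* Translation-only registration: rotation and scale are assumed fixed by
  the capture geometry.
* Single-template verification; no enrollment fusion or score
  normalization across fingers.
* The comparison baselines include only circular LBP; derivative and
  ternary pattern variants are out of scope.
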