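# veinline

Finger-vein verification in R, built around the **Local Line Binary
Pattern (LLBP)** texture descriptor.

Vein patterns are an attractive biometric: they sit under the skin, are
hard to forge, and are insensitive to surface condition. But near-infrared
finger captures are low contrast and displaced between placements, so a
verification system needs a full pipeline, all of which this package
implements:

1. **Preprocessing** — Otsu binarization, finger centroid, fixed
   480 × 160 ROI crop, bilinear downscale by 0.4 (to 192 × 64), and
   contrast enhancement with a modified Gaussian high-pass mask
   `H(x, y) = a (1 − e^{−D²(x,y)/2D₀²}) + b`.
2. **Alignment** — integer translation between two enhanced images from
   the peak of the phase-only correlation (POC) surface; pairs shifted by
   ≥ 20 px horizontally or ≥ 10 px vertically are rejected as different
   fingers, otherwise the common region is cropped from both.
3. **Feature extraction** — the LLBP family: horizontal and vertical line
   codes (`llbp_h()`, `llbp_v()`; bit = 1 iff neighbor ≥ line center,
   `N − 1` bits each), their concatenation (`llbp()`, `2(N − 1)` bits per
   pixel), the magnitude `√(h² + v²)`, plus a circular `lbp(P, R)`
   baseline; code maps can be rendered to grayscale and serialized as
   packed templates.
4. **Matching** — normalized Hamming distance
   `HD = |codeA ⊗ codeB| / CodeLength` on the pair's common region.
5. **Evaluation** — genuine/imposter pair enumeration, FAR/FRR curves,
   equal error rate (EER) with linear interpolation at the crossing, and
   the `(N, S)` parameter grid search used for tuning.

Because real vein databases are rarely redistributable, the package also
ships a deterministic, seeded **synthetic generator** that emulates the
standard database layout (subjects × fingers × samples, 640 × 480 8-bit
captures with spline-drawn veins, translation jitter, brightness drift,
blur and noise), so every stage is testable end to end.

## Worked example

```r
library(veinline)

# a small synthetic database: 2 subjects x 4 fingers x 5 samples
idx <- generate_dataset(2, 4, 5, root_seed = 11, out_dir = "data")

# verify two samples of the same finger, and two different fingers
a1 <- load_image(idx$path[1]); a2 <- load_image(idx$path[2])
b1 <- load_image(idx$path[6])
verify_pair(a1, a2)
verify_pair(a1, b1)

# score all pairs and evaluate
scores <- score_pairs(idx)
report <- evaluate_scores(scores)
glance(report)
autoplot(report)

# template geometry of the standard descriptors on a 192 x 64 image
code_geometry(64, 192, "llbp", N = 21)
```

Output (abridged):

```
#> <match_score> hd = 0.2469 (t_x = 0, t_y = 0, peak = 0.333)
#> <match_score> hd = 0.5087 (t_x = 0, t_y = 1, peak = 0.125)
#> # A tibble: 1 × 4
#>     eer eer_threshold n_genuine n_imposter
#>   <dbl>         <dbl>     <int>      <int>
#> 1     0         0.247        80        700
#> # A tibble: 1 × 4
#>   valid_height valid_width bits_per_pixel total_bits
#>          <dbl>       <dbl>          <int>      <dbl>
#> 1           44         172             40     302720
```

The first Hamming distance (same finger, 0.25) is well below the second
(different fingers, 0.51); with fully separated score distributions the
EER is 0% at an operating threshold of about 0.25. The LLBP template with
`N = 21` on a 192 × 64 enhanced image has 172 × 44 valid pixels × 40 bits
= 302,720 bits.

A thin CLI wrapping the same functions is installed at
`system.file("cli", "veinline", package = "veinline")`, with subcommands
`synthesize`, `verify`, `evaluate`, `gridsearch` and `describe`.

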