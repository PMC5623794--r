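---
title: "Spectral position recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral position recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radiopos` classifies a digital radiograph into one of six radiographic
positions from a 1-D low-frequency signature of its 2-D spectrum, and
localizes it on an annotated whole-body phantom template. This vignette
documents the model, every tunable parameter, the numerical choices,
what the synthetic data generator does and does not emulate, and the
design decisions that were genuinely open.

## The pipeline

1. **Preprocess**: linear histogram stretch to 16 bit, 5×5 median
   filter, optional CLAHE.
2. **Signature**: centred, `1/(MN)`-normalized magnitude spectrum,
   reduced to a fixed-length radial curve over the lowest fraction of
   the radial frequency range, plus its AUC.
3. **Classify**: mean-variance (RMS) distance to six library curves;
   cosine similarity breaks near-ties.
4. **Localize**: sliding-window matrix-product and Pearson-correlation
   score maps over the downscaled phantom; the recognized region is
   the intersection of the two argmax rectangles.
5. **Annotate**: overlap fractions against the atlas's named
   anatomical bounding boxes.

## Preprocessing

The stretch maps `[min, max]` linearly onto `[0, 65535]`; the constant
65535 fixes all downstream stages to 16 bit. Rounding is half-up
(`floor(x + 0.5)`), chosen over R's round-half-even so the mapping is
monotone in the obvious way and hand-checkable. A constant image cannot
be stretched and maps to zeros with a warning. With CLAHE off the chain
is *exactly* invariant to positive affine intensity maps of the input
(gain and offset cancel in the stretch) — the property that makes the
signatures exposure-tolerant without any learned normalization.

The median filter uses the centred `w`×`w` neighbourhood (`w` = 5) with
edge-replicated borders. Replication preserves constant images exactly
and keeps the filter total on the smallest admissible (5×5) inputs; it
is implemented in the package rather than delegated because the border
policy and exact order-statistic semantics are part of the contract the
tests pin against a brute-force neighbourhood-sort oracle.

CLAHE is delegated to `EBImage::clahe`. Two conventions to know:
EBImage needs the image extent to be a multiple of the tile grid, so
the wrapper pads by edge replication and crops back; and its `limit`
argument is a contrast-slope multiple (default 2 here), *not* the
clip fraction used by some other libraries — sub-1 values are
degenerate in EBImage's redistribution loop. Tiles default to 8×8.

## The frequency signature

For an `M`×`N` image the spectrum is `|F(u,v)|/(MN)`, zero frequency
centred, so the centre cell equals the image mean. The radial
coordinate is `r(u,v) = sqrt((u/M)² + (v/N)²)`. Cells with
`0 < r ≤ fraction · r_max` are binned into `n_bins` equal-width rings;
each curve entry is the ring's mean magnitude. The DC cell is excluded
so the exposure offset never dominates similarity. Rings with no grid
cell (inevitable for small images, where few integer frequencies fall
in the band) are filled by linear interpolation between populated
neighbours, endpoints replicated — this keeps the curve length fixed at
`n_bins` (default 256) so curves from images of different sizes are
comparable. The AUC is the trapezoidal integral at unit bin spacing.

**The fraction scales with resolution.** The band that carries
anatomical contours is physical — cycles per body length — so its
extent as a fraction of the digital frequency range grows as the pixel
grid shrinks. The reference setting is 0.02 on a 2000-row template;
`fraction_for_scale(rows)` returns `0.02 · 2000 / rows`, giving 0.08 at
the package's 500-row working scale. Using 0.02 directly on small
working-scale crops leaves fewer than two populated rings and is
rejected with a validation error advising a larger fraction.

Butterworth band-pass texture extraction multiplies the centred
spectrum by
`H(r) = [1/(1+(low/r)^{2k})] · [1/(1+(r/high)^{2k})]` (order `k` = 2 by
default), always zeroing DC, then inverse-transforms, clips to the
intensity range and rounds. Suggested bands at working scale: lung
texture (0.02, 0.15], trabecular bone (0.05, 0.25]. Note that a
band-passed non-negative image is zero-mean before clipping, so
clipping at 0 discards the negative half-waves; the operator is for
texture visualization and band-energy measurements, not for invertible
filtering.

## Classification

`a(f, F) = sqrt(Σ(fᵢ − Fᵢ)²/n)` is the mean-variance similarity;
smaller is more similar, and it is a metric up to the `1/sqrt(n)`
factor. The 0.02 decision threshold is only meaningful on a fixed
scale, so both curves are divided by the library's shared normalization
constant — the maximum amplitude over the six reference curves, stored
in the library file. Ranking sorts ascending with exact ties broken by
the canonical position order (head, lungs, lumbar, pelvis, joint,
limbs).

The tie-break rule is read as: when **both** of the two smallest `a`
values fall below the threshold, the cosine similarity between the
input curve and the two candidates decides, larger winning. The
alternative reading — trigger when the *gap* between the two smallest
is below the threshold — is available as `tiebreak = "gap_below"`.
Cosine is computed on raw (unnormalized) curves; it is scale-invariant
so the choice is immaterial.

## Template matching

The scalar product and correlation scores are operationalized as maps
over every valid top-left offset of the (downscaled) input on the
(downscaled) template: a maximum needs a search domain. `M` is the
window–input product normalized by the input's energy only, so it is
**not** bounded above by 1 and systematically favours bright windows;
`R` is the Pearson correlation, affine-exposure-invariant and bounded
in [−1, 1]. This asymmetry is exactly why the method intersects the two
argmax rectangles instead of trusting either alone: `M` carries
absolute-intensity evidence, `R` carries structure. When the rectangles
do not intersect the correlation rectangle is used and the fallback is
recorded in the result.

Numerics: the cross-correlation term is computed in the frequency
domain; window sums and sums of squares come from integral images
(exact for integer data in double precision); windows with zero
variance get `r = 0` by convention, keeping the map total; `r` is
clamped to [−1, 1] against rounding; argmax ties resolve to the first
occurrence in row-major order. The default downscale factor is 0.25
(bilinear, aspect-preserving), a speed/accuracy compromise exposed as a
parameter; downscaled inputs below 8×8 are rejected.

One caution for exactness arguments: because `M` is unbounded off-match,
on i.i.d. full-contrast random templates its argmax can land away from
the true offset of an exact crop with small but nonzero probability,
shrinking the intersected box. On high-contrast binary templates a
Cauchy–Schwarz argument bounds every off-match `M` well below the
aligned value 1, which is why the exact-recovery sweeps in the test
suite use such templates: the property then holds for any seed, with a
provable margin rather than a lucky draw.

## The synthetic phantom generator

No radiograph set is distributed with the method, so the generator is
the package's only data source. It emulates, at a working scale of
500×200 (the shipped full-size atlas is 2000×800), a stitched
whole-body phantom radiograph with six structurally distinct zones:
skull ellipse with smooth interior; bright thorax holding two dark
lung fields carrying band-limited texture; vertically periodic lumbar
vertebrae; a bright pelvic ring; a knee joint of two bright rods with
fine high-frequency trabecular texture; and thin limb rods with the
least projected mass of the six. Per-position images are zone-sized
crops with sub-window jitter up to 10% of the zone size, multiplicative
exposure gain drawn from [0.8, 1.2], additive Gaussian noise
(σ = 0.05 of the 16-bit range) and optional salt-and-pepper impulses;
everything is reproducible from `(seed, position, index)`.

Two geometric choices make the signatures stable by design rather than
by chance. Structures are *inset* 12% per side within their zone, so
the jitter translates them instead of truncating them — the magnitude
spectrum is translation-invariant, so a translated structure leaves the
signature unchanged while a truncated one does not. And each zone's
base intensity is painted as an *apron* 12% beyond its bounding box, so
a jittered crop window sees the zone's own soft-tissue level instead of
dark canvas background; without the apron, the background strip dragged
in by the jitter adds a large draw-dependent low-frequency component
that destabilizes the curve's lowest bins.

`impulse_fraction` defaults to 0: calibrated flat-panel detectors show
negligible residual impulse noise, and because the histogram stretch
precedes the median filter, even a handful of 0/65535 impulses pins the
stretch endpoints and lets the exposure gain leak straight into curve
amplitudes. The knob exists (up to 0.1) to stress the median filter,
and the tests exercise it at nonzero settings.

What the generator does **not** emulate: real anatomical variation
between patients, X-ray scatter and beam-hardening, detector response
and saturation clipping, collimation borders and markers, or
non-frontal views. Passing tests therefore demonstrate that the
pipeline's operators behave as specified and that the method separates
structurally distinct content under exposure variation and noise — not
that the headline clinical accuracy transfers to real archives.

## Working problem sizes

The test suite and the acceptance script run at the 500×200 working
scale with 10 library + 20 evaluation images per position (120
evaluated cases), signature fraction 0.08, matching scale 0.25. These
sizes are the package's chosen working conditions; the full-size
2000×800 atlas with fraction 0.02 behaves identically in structure and
can be generated with `synth_config(template_shape = c(2000, 800))`.

## File formats

16-bit images are written as uncompressed 16-bit TIFF (the PNG codec
available to the package writes 8-bit only, so PNG is supported for
reading 8/16-bit and writing 8-bit overlays). The signature library is
JSON ({fraction, n_bins, norm, positions: {name: {curve, auc}}}); the
atlas regions config is YAML with `[column, row]`, 1-based, inclusive
corner pairs — the convention in which the reference head box runs from
[260, 1] to [540, 285] on the 2000×800 template. Note the reference
head and lung boxes genuinely overlap (rows 130–285); overlap fractions
in annotations are reported per region, so this is visible, not hidden.

## Known limitations

- No rejection class: an out-of-library position (e.g. a hand or a
  lateral view) is forced onto the nearest of the six curves.
- Matching searches translation only; rotation or scale mismatch
  between input and template degrades both scores.
- The product score `M` is exposure-sensitive by construction; its
  argmax alone should never be used for localization.
- DICOM pixel data is not read directly; convert to 16-bit TIFF/PNG
  first.
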