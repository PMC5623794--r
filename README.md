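# radiopos

Automatic radiographic position recognition and body-region
localization for digital X-ray images.

PACS/RIS archives accumulate thousands of radiographs whose acquisition
metadata (which body part, which view) is missing or unreliable.
`radiopos` recognizes the radiographic position of a single-channel
radiograph — one of **head, lungs, lumbar, pelvis, joint, limbs** — from
a one-dimensional low-frequency signature of its two-dimensional Fourier
spectrum, and then localizes the imaged region on an anatomically
annotated whole-body phantom template. It is aimed at medical-imaging
informaticians who need a fast, transparent, training-free classifier
for archive curation, and at methodologists studying spectral-signature
classification.

## Method

**Preprocessing.** Linear histogram stretching onto the 16-bit range,
`F_H = round(65535 · (f − A)/(B − A))` with `A = min f`, `B = max f`,
followed by a 5×5 median filter (edge-replicated borders); optional
CLAHE compensates exposure variation.

**Frequency signature.** The centred magnitude spectrum
`|F(u,v)| / (MN)` is reduced to a 256-bin radial curve over the lowest
fraction of the radial frequency range (2% at full 2000-row template
resolution; the fraction scales inversely with linear resolution — see
`fraction_for_scale()`). The curve's trapezoidal area (AUC) is kept as
an auxiliary feature; it separates positions, such as lungs and limbs,
whose curve shapes are similar.

**Classification.** The input curve `f(w)` is compared with the six
library curves `F(w)` (each position's curve is the mean over its
library images) using the mean-variance similarity

    a = sqrt( Σᵢ (fᵢ − Fᵢ)² / n )

after both curves are divided by the library's shared normalization
constant. The smallest `a` wins; when the two smallest are both below
0.02, the cosine similarity `cos θ = (f·F)/(‖f‖‖F‖)` between the input
and the two candidates decides, larger cosine winning.

**Localization.** The preprocessed input slides over the downscaled
phantom template (default factor 0.25). At every offset two scores are
evaluated: the energy-normalized matrix product
`M = Σ(input · window)/Σ(input²)` and the Pearson correlation `R`
(invariant to affine exposure changes). The recognized region `T` is
the intersection of the input-sized rectangles at the two score maxima
(falling back to the correlation rectangle when they do not intersect),
and is annotated with every overlapping anatomical region of the atlas.

Because no public radiograph set accompanies the method, the package
ships a synthetic whole-body phantom generator (`make_phantom()`,
`make_dataset()`) producing six structurally distinct anatomical zones
and noisy, exposure-varied, jittered crops of each — the data every
test and the acceptance script run on.

## Worked example

```r
library(radiopos)

cfg     <- synth_config(seed = 1)            # 500 x 200 working-scale phantom
phantom <- make_phantom(cfg)
frac    <- fraction_for_scale(500)           # 0.08 at this resolution

lib_imgs <- lapply(radiopos_positions(), function(pos)
  lapply(1:10, function(i) make_position_image(phantom$template, pos, cfg, i)))
names(lib_imgs) <- radiopos_positions()
lib <- build_library(lib_imgs, fraction = frac)
lib
#> <signature_library> 256 bins, fraction 0.08, norm 8623
#>   head    AUC 8.351e+05
#>   lungs   AUC 4.631e+05
#>   ...
#>   limbs   AUC 1.797e+05

img <- make_position_image(phantom$template, "lungs", cfg, index = 15)
res <- recognize(img, lib, phantom$template, scale = 0.25)
res
#> <match_result> position=lungs (by mean_variance), box [93,37 76x153]
#>   region lungs   overlap 0.89
res$classification
#> <classification> lungs (by mean_variance)
#>   lungs   a=0.00925 cos=0.99996
#>   joint   a=0.11225 cos=0.93415
#>   ...
```

The classification block shows the six mean-variance scores `a`
(smaller = more similar) and cosines: the noisy lungs crop sits at
`a = 0.009` from the lungs reference curve, an order of magnitude
closer than any other position, and its matched box covers the lung
zone of the atlas with overlap 0.89. Note the head/limbs AUC contrast
in the library (8.4e5 vs 1.8e5): the auxiliary scalar that separates
positions with similar curve shapes.

A command-line interface wraps the same workflow:

```sh
Rscript inst/cli/radiopos.R simulate --out-dir work --seed 1
Rscript inst/cli/radiopos.R build-library \
    --manifest work/images/manifest.csv --out work/library.json --fraction 0.08
Rscript inst/cli/radiopos.R recognize --image work/images/lungs_015.tif \
    --library work/library.json --template work/atlas.tif \
    --regions work/regions.yaml --render overlay.png
```

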