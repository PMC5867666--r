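---
title: "Automated drusen segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated drusen segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druscan)
```

## The problem

Drusen are small yellowish deposits beneath the retinal pigment epithelium
and the hallmark lesion of early age-related macular degeneration (AMD).
Grading them by eye on colour fundus photographs is slow and poorly
reproducible, so `druscan` automates the measurement: given an 8-bit RGB
fundus image it returns a binary drusen mask restricted to a macular region
of interest, together with every intermediate product needed to audit the
decision.

The pipeline is classical image analysis — no learned components — and
consists of five stages.

## Stage by stage

### 1. Green channel

Drusen and vessels have their highest contrast in the green plane of an RGB
fundus photograph; red is dominated by illumination, blue by noise. All
processing happens on the green channel (`green_channel()`).

### 2. Optic disc and macular ROI

The optic disc is the brightest structure in the image, so binarising at
intensity `> 200` and keeping the largest 8-connected component finds it
reliably (`detect_optic_disc()`). The disc centre is the component centroid
rounded half-up to a pixel.

The fovea is estimated purely geometrically: it lies roughly midway between
the disc and the image border on the side away from the disc. The ROI
(`compute_roi()`) is therefore the circle centred at the midpoint of the
horizontal segment from the disc centroid to the opposite image edge (at
the centroid's row, fractional midpoints floored), with radius equal to the
distance from that centre back to the disc centroid — the fovea-to-disc
distance. Drusen detection happens only inside this circle.

### 3. Candidate detection by dual-scale median filtering

A median filter with a mask larger than any druse (default 30 × 30) erases
drusen while following the background and any smooth illumination gradient;
a small mask (5 × 5) removes salt-type impulse noise but leaves drusen
intact. The clamped difference

```
subtract = max(median_5(I) - median_30(I), 0)
```

is bright exactly where drusen-scale structure stood and near zero
elsewhere (`subtract_candidates()`). A min–max histogram stretch
(`histogram_stretch()`) then spreads the compressed contrast over the full
8-bit range. Dark structure (vessels) produces negative residuals and is
clamped away; structures wider than the large mask (the disc interior, the
background, gradients) cancel exactly.

### 4. Vessel removal

Vessels and the disc leave bright rims in the subtract image. Because every
retinal vessel emerges from the disc and is the darkest structure in the
green channel, seeds are taken as the darkest pixel in each of 8 angular
sectors of the annulus just outside the disc (radii between one and two
disc radii), and grown by breadth-first flooding that admits a neighbour
when its intensity is within a tolerance (default 15) of the *seed*
intensity (`region_grow()`). The union of the grown regions and the disc
mask, dilated by 2 px, forms the non-drusen exclusion mask
(`nondrusen_mask()`).

### 5. Renyi-entropy thresholding

A cut `t` splits the ROI histogram `P_0 … P_255` into classes
`A1 = {0..t}` and `A2 = {t+1..255}` with masses `P_A1`, `P_A2`. The Renyi
entropy of order `a != 1` of a class is

```
H^a(t) = 1/(1 - a) * ln( sum_i (P_i / P_class)^a ),
```

which converges to the Shannon entropy as `a -> 1`. Each order yields a
component threshold `t(a) = argmax_t [H^a_A1(t) + H^a_A2(t)]`; orders below
1 emphasise the tails, orders above 1 the modes, and the limit `a -> 1` is
the classic maximum-entropy-sum cut. Three components are computed (orders
0.5, 1, 2 by default), sorted ascending into `t[1] <= t[2] <= t[3]`, and
combined:

```
t_c = t[1] * (P(t[1]) + w*b1/4) + t[2] * w*b2/4 + t[3] * (1 - P(t[3]) + w*b3/4)
```

with `P(t)` the cumulative mass up to `t`, `w = P(t[3]) - P(t[1])`, and the
weights `(b1, b2, b3)` picked by the spacings of the sorted components:
`(1,2,1)` when both `|t[1]-t[2]|` and `|t[2]-t[3]|` are at most 5 or both
exceed 5, `(0,1,3)` when only the upper spacing exceeds 5, and `(3,1,0)`
when only the lower one does. The blend weights sum to one, so `t_c` always
lies between `t[1]` and `t[3]`. Pixels strictly above `t_c` inside the ROI
are drusen candidates; the exclusion mask is subtracted and components
smaller than `min_drusen_area` (default 4 px) dropped.

`otsu_threshold()` and the pure maximum-entropy component are available as
baselines via `druscan_config(threshold_method = ...)`.

## Parameters that matter

| key | default | unit | role |
|---|---|---|---|
| `disc$intensity_threshold` | 200 | gray level | disc binarisation (strictly greater) |
| `median$small_mask` | 5 | px | impulse-noise scale |
| `median$large_mask` | 30 | px | must exceed the largest druse |
| `vessel$tolerance` | 15 | gray levels | region-grow similarity to seed |
| `vessel$max_region_fraction` | 0.25 | fraction | flood-overflow guard |
| `vessel$dilation_radius` | 2 | px | rim absorption around vessels/disc |
| `vessel$n_seeds` | 8 | sectors | annulus seeds around the disc |
| `renyi$alpha_low`, `renyi$alpha_high` | 0.5, 2 | – | Renyi orders |
| `min_drusen_area` | 4 | px | single-pixel residue filter |

The entropy orders are not dictated by the method itself; 0.5 and 2 are the
conventional choices for the three-threshold scheme and are exposed in the
configuration.

## Numerical choices

* **Even median windows.** A 30 × 30 window has no centre pixel; the output
  pixel sits at offset (14, 14) within the window and the lower median (the
  450th of 900 sorted values) is taken, keeping the filter deterministic
  and integer-valued. Borders use replicate padding; border artefacts fall
  outside the ROI.
* **Canonical orientation.** Because an even window has no
  mirror-symmetric anchor, `segment_drusen()` mirrors right-disc images
  into a canonical disc-on-the-left orientation and mirrors the result
  back. Output masks are therefore exactly equivariant under horizontal
  reflection of the input — left and right eyes are treated identically.
* **Histogram region.** The ROI circle reaches back to the disc centroid,
  so the disc's bright rim in the subtract image lies inside the ROI. The
  rim would dominate the upper histogram tail and drag the entropy cut
  above the drusen band, so the threshold histogram is computed over the
  ROI *minus* the exclusion mask; binarisation is applied over the full ROI
  and the exclusion subtracted afterwards.
* **Degenerate inputs.** A druse-free image yields a single-level ROI after
  stretching; `segment_drusen()` returns an empty mask (`threshold =
  NULL`) instead of failing. Cuts that leave a class empty are excluded
  from every argmax; a single-level histogram raises a classed error in the
  low-level functions. All argmax ties resolve to the smallest threshold;
  `t_c` is rounded half-up.
* **Flood-overflow seeds.** With 8 annulus sectors some seeds inevitably
  fall on vessel-free background and flood it; such seeds are discarded
  (the region they grew is not a vessel) rather than failing the pipeline.
  The exported `region_grow()` still raises `druscan_region_overflow` so
  parameter problems stay visible.
* **Entropy cuts on long flat tails.** For histograms with a long
  near-uniform tail the order-2 component can legitimately sit at the tail
  edge rather than between modes (the exhaustive-search oracle agrees);
  the three-component blend is what stabilises the final cut.

## The phantom generator

Clinical fundus images cannot be redistributed, so the package ships a
seeded generator (`generate_phantom()`, `phantom_suite()`) that renders the
structural features the pipeline depends on, at half clinical resolution
(768 × 512) by default:

* a bright anti-aliased disc (intensity 230, radius 40 px) on a 120-level
  background with a seeded-direction linear illumination ramp;
* dark vessels (intensity 40, width 3 px, flat core with a 0.75-px
  anti-alias taper) following random-walk polylines that leave the disc rim
  outward — they start at the rim because dark paths across the disc
  interior would fragment the thresholded disc component, which neither
  clinical discs nor the detection rule exhibit;
* soft-edged drusen (diameters 4–14 px, contrast +40 by default) placed
  around the geometric fovea in the half opposite the disc, never touching
  vessels or disc; the ground-truth mask records pixels at or above half
  the peak contrast;
* salt impulses (density 0.001) kept off planted structures.

The difficulty suites fix contrast/gradient/noise at +60/0/0.0005 (easy),
+40/20/0.001 (medium) and +20/40/0.005 (hard).

What the phantoms do *not* model: vessel branching statistics and calibre
variation, soft confluent drusen with truly ambiguous boundaries, other AMD
lesions (haemorrhage, exudate, atrophy), camera vignetting and colour
balance. Passing the phantom battery shows the algorithm implements its
stated contracts and recovers lesions under the modelled conditions; it
does not certify clinical accuracy.

## Evaluation statistics

Agreement with a reference grading is reported at two levels inside the
ROI: pixel-by-pixel confusion counts (sensitivity, specificity, accuracy as
percentages, Dice coefficient `2TP/(2TP+FP+FN)`), and region-by-region
counts where a true lesion touched by at least one predicted pixel is a
true positive (true negatives are undefined at this level, so specificity
and accuracy are omitted). Paired area measurements get Pearson
correlation, the two-way random-effects absolute-agreement single-measures
ICC with its 95% confidence interval, and Bland–Altman limits of agreement
(mean ± 1.96 SD of the differences).

One phantom-specific caveat: the threshold accepts part of each druse's
soft taper below the half-contrast truth contour, so automatic areas run
systematically ~20% high. Pearson correlation is insensitive to such a
proportional bias (r ≈ 0.98 on phantom suites) while the
absolute-agreement ICC is heavily penalised by it — a useful reminder that
the two statistics answer different questions.

## Worked example

```{r example}
bundle <- generate_phantom(phantom_spec(seed = 42))
result <- segment_drusen(bundle)
result

roi <- roi_mask(result$roi, ncol(bundle$green), nrow(bundle$green))
conditional_probabilities(
  confusion_regionwise(result$drusen_mask, bundle$drusen_mask, roi))
conditional_probabilities(
  confusion_pixelwise(result$drusen_mask, bundle$drusen_mask, roi))
```

## Problem sizes

Tests and the acceptance script run on 768 × 512 phantoms (20 for disc/ROI
placement, 5-seed suites end-to-end), 64 × 64 images for region-growing
oracle comparisons, and 10 seeded sparse random histograms per entropy
oracle check — sizes chosen so the whole battery completes in about a
minute while still exercising every code path at realistic scale.

## Known limitations

* The ROI radius construction is geometric; eyes with an unusually
  displaced fovea are not handled.
* Soft drusen with genuinely ambiguous boundaries are segmented at the
  entropy cut, which need not match a clinician's contour; only relative
  area change should be interpreted longitudinally.
* Vessel removal by seed-fixed region growing assumes vessels darker than
  every other structure near the disc; images with severe peripapillary
  atrophy may violate this.
* The fixed 200 disc threshold assumes standard exposure; over- or
  under-exposed images need the `disc$intensity_threshold` configuration.
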