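# druscan

Automated segmentation of **drusen** — the small bright sub-retinal
deposits that mark early age-related macular degeneration — in colour
fundus photographs, with a two-level validation toolkit and a synthetic
fundus phantom generator for fully reproducible testing.

`druscan` is aimed at ophthalmic image-analysis researchers who need an
auditable, classical (non-learned) drusen quantification: every
intermediate product of the pipeline is returned, every parameter is
exposed with its published default, and every stage is testable against
exact ground truth on seeded phantoms.

## Method

Given an 8-bit RGB fundus image, the pipeline:

1. takes the **green channel** (highest lesion/vessel contrast);
2. finds the **optic disc** by thresholding at intensity > 200 and keeping
   the largest 8-connected component, then builds the circular **macular
   ROI**: centre at the midpoint between the disc centroid and the opposite
   image edge, radius equal to the centre-to-disc distance;
3. isolates drusen-scale bright structure with a **dual-scale
   median-filter difference image**, `max(median_5(I) − median_30(I), 0)`,
   stretched to the full gray range — the 30 × 30 filter erases drusen and
   follows the background, the 5 × 5 filter only removes impulse noise;
4. segments the **vessel tree** by region growing from the darkest pixels
   in an annulus around the disc, and dilates vessels ∪ disc into an
   exclusion mask;
5. binarises with **Renyi-entropy automatic thresholding**: component
   thresholds `t(α)` maximising the class-entropy sum
   `H^α_A1(t) + H^α_A2(t)` for α = 0.5, the Shannon limit α → 1, and
   α = 2 are sorted and blended,

   `t_c = t₁(P(t₁) + ¼ωβ₁) + ¼t₂ωβ₂ + t₃(1 − P(t₃) + ¼ωβ₃)`,

   with `ω = P(t₃) − P(t₁)` and the β-triple chosen from the component
   spacings; pixels above `t_c` inside the ROI, minus the exclusion mask,
   are drusen.

Validation follows the two-level scheme used for clinical gradings:
pixel-by-pixel and region-by-region confusion counts (sensitivity,
specificity, accuracy, Dice), plus Pearson correlation, absolute-agreement
ICC, and Bland–Altman limits on paired area measurements.

## Worked example

```r
library(druscan)

bundle <- generate_phantom(phantom_spec(seed = 42))   # synthetic fundus + truth
result <- segment_drusen(bundle)
result
#> <drusen_segmentation>
#> <optic_disc> centroid (245, 653), 5007 px, right half
#> <roi_circle> center (245, 327), radius 326 px
#> <renyi_threshold> components (2, 2, 2) -> sorted (2, 2, 2), beta (1,2,1), omega 0.0000, t_c = 2
#>   10 drusen component(s), 976 foreground pixel(s)

roi <- roi_mask(result$roi, ncol(bundle$green), nrow(bundle$green))
conditional_probabilities(
  confusion_regionwise(result$drusen_mask, bundle$drusen_mask, roi))
#> <conditional_probabilities> [region] sensitivity 100.00% specificity -% accuracy -% DSC 1.00
conditional_probabilities(
  confusion_pixelwise(result$drusen_mask, bundle$drusen_mask, roi))
#> <conditional_probabilities> [pixel] sensitivity 98.99% specificity 99.94% accuracy 99.93% DSC 0.89
```

All 10 planted drusen are recovered (region sensitivity 100%); the pixel
Dice of 0.89 reflects the soft lesion boundaries, where the entropy cut
accepts slightly more of each druse's taper than the half-contrast truth
contour. On an image the detector reports the disc centroid, the ROI
circle, the three entropy component thresholds with their blend weights,
and the final mask.

A command-line front end is installed with the package
(`system.file("scripts", "druscan", package = "druscan")`) with
`segment`, `eval`, and `phantom` subcommands that read PNG/TIFF/BMP images
and write mask PNGs plus JSON sidecars.

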