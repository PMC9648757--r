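# dermseg

Automatic segmentation of pigmented skin lesions in dermoscopic images.

Dermoscopy images carry two systematic artifacts that derail naive
segmenters: near-black **corner borders** left by the round dermatoscope
lens, and dark **hair strokes** crossing the lesion. dermseg implements a
four-stage pipeline that deals with both before extracting the lesion:

1. **Corner-border removal** — the image is thresholded at gray level
   T = 4; the *extreme outer contour* is taken from dark components touching
   the image corners, and the *extreme inner contour* is found by walking
   each corner diagonal inward from the estimated border extent (20 px)
   until a pixel and its two diagonal predecessors are all below T. The
   ring between the contours is detached (cropped), and the crop offset is
   kept so the final mask returns in the original frame.
2. **Hair removal** — hair contours from the closing difference
   `T(I) = (I ● K) − I` with a 17×17 cross element K; a binary in-paint
   mask by gray-level slicing (values < 10 → 0, else 255); removal by
   fast-marching inpainting, filling masked pixels in order of arrival time
   from the mask boundary as normalized weighted sums of first-order
   extrapolations `I(q) + ∇I(q)·(p−q)`, with weights
   `w = dir·dst·lev` (directional, inverse-square distance, level-set
   proximity).
3. **Enhancement** — the HSV value channel is passed through a monotone
   log-exp transfer built from its (uniform-blended) histogram; hue and
   saturation are untouched. CLAHE and histogram equalization are available
   for ablation.
4. **GrabCut segmentation** — an automatic rectangle (start 5% in from the
   top-left, end 7% in from the bottom-right, truncated integers; for
   430×430 that is (21, 21)–(400, 400)) initializes a tri-map
   {background, unknown, foreground = ∅}; two 5-component Gaussian mixtures
   over RGB are refined by alternating component assignment, refit, and
   graph min-cut (data terms = negative mixture log-likelihoods; smoothness
   `γ·exp(−β‖z_p−z_q‖²)/d(p,q)` on 8-neighbors; compiled Dinic solver)
   until labels converge.

Predicted masks are scored against ground truth with the Jaccard index
`TP/(TP+FP+FN)` and Dice index `2TP/((FP+TP)+(TP+FN))`. A seeded synthetic
fixture generator (skin texture, irregular lesion, hairs, corner borders,
each with a paired truth mask) makes the whole pipeline testable with no
dataset download.

## Worked example

```r
library(dermseg)

fx  <- generateFixture(fixtureSpec(seed = 7, height = 320, width = 320,
                                   borders = TRUE, hairs = TRUE))
res <- runPipeline(fixtureImage(fx))
res
#> SegmentationResult
#>   stages: border_removal -> hair_removal -> enhancement -> segmentation
#>   borders present: TRUE | hairs present: TRUE
#>   mask: 320 x 320, 26860 lesion pixel(s)

cc <- confusionCounts(lesionMask(res), lesionTruth(fx))
cat(sprintf("jaccard %.3f  dice %.3f\n", jaccardIndex(cc), diceIndex(cc)))
#> jaccard 0.787  dice 0.881
```

The stage log shows both artifacts were detected and removed before
segmentation; the returned mask lives in the original 320×320 frame with
the detached border ring forced to background. The overlap scores compare
the mask against the generator's ground truth: a Jaccard of 0.787 means
that intersection over union with the true lesion is ~79% — on a small
frame whose soft lesion boundary is a sizable fraction of the lesion area.

Real images go through the same call: `runPipeline(readImageRGB("img.bmp"))`.
A thin command-line front end is installed at `inst/scripts/dermseg.R`
(subcommands `segment`, `batch`, `synth`, `eval`).

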