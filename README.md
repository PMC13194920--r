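# rodmorph

Single-cell size measurement for rod-shaped bacteria from instance
segmentation masks.

Fluorescent-membrane imaging makes individual bacterial cells — including
cells inside chains — segmentable, but turning a 2D label mask into biology
still requires three things this package provides:

1. **Morphometry.** Per-cell length, width profile, membrane surface area
   and volume from a label mask, under a spherocylinder model (a cylinder
   with hemispherical caps, imaged at the medial focal plane). The exact
   Euclidean distance transform gives the local radius along a thinned
   one-pixel centerline; the centerline is treated as a graph (edges between
   skeleton pixels closer than 1.5 px) so that branched skeletons are
   handled by taking the per-metric median across all endpoint-to-endpoint
   candidate paths. On a centerline with radii `r_c`, cap radii `r_s1, r_s2`
   and unit slab height `h`:

   ```
   L    = r_s1 + r_s2 + sum_i d(i, i+1)
   wbar = (2/n) sum_i r_c,i
   S    = 2*pi * (r_s1^2 + r_s2^2 + h * sum_i r_c,i)
   V    = pi * ((2/3) r_s1^3 + (2/3) r_s2^3 + h * sum_i r_c,i^2)
   ```

   Cross-sectional area, convex-hull area, eccentricity and solidity come
   directly from the mask region.

2. **Measurement-bias correction.** Automatic segmenters produce masks that
   are systematically (and linearly) too large or too small. rodmorph fits
   `truth ~ Normal(m * auto + n, sigma)` by MCMC with priors
   `m, n ~ Normal(0, 20)` and Half-Cauchy `sigma` (4 chains x 3000 draws =
   12000 posterior samples), then transforms each measurement with 250
   jointly drawn `(m, n)` posterior pairs, so corrected sizes carry the
   transformation's uncertainty. Histogram KL divergence and a
   Levene-gated ANOVA/Kruskal–Wallis flow quantify distribution agreement.

3. **Benchmarking and simulation.** F1 against IoU curves over the standard
   eleven thresholds (0.5 to 1.0 in 0.05 steps) with optimal one-to-one IoU
   matching, and a synthetic fluorescent-membrane simulator (spherocylinders
   rendered at 15 nm/px, membrane emitters on 90% of contour points,
   Gaussian-PSF blur, rescale to 65 nm/px) that provides exact ground truth
   for validating the whole pipeline without any external data.

## Worked example

Simulate a small scene, measure it, and correct a biased width
distribution:

```r
library(rodmorph)

spec  <- scene_spec(n_cells = 3, width_um = c(0.7, 1.0), length_um = 4, seed = 11)
scene <- generate_scene(spec)           # exact labels at 15 nm/px
out   <- rescale_scene(scene)           # rescaled to 65 nm/px
tab   <- measure_mask(out$mask, image_id = "demo")
tab[, c("cell_label", "length_um", "mean_width_um", "surface_um2", "volume_um3")]
#>   cell_label length_um mean_width_um surface_um2 volume_um3
#> 1          1     3.917        0.7971       9.808      1.822
#> 2          2     4.011        0.7092       8.907      1.489
#> 3          3     3.967        0.9819      12.220      2.752
scene$cells[, c("cell_label", "width_um", "length_um")]   # ground truth
#>   cell_label width_um length_um
#> 1          1   0.7832         4
#> 2          2   0.7194         4
#> 3          3   0.9722         4
```

Lengths are recovered within ~0.08 µm (just over one 65 nm pixel) and
widths within ~0.015 µm of the generating parameters. Correcting a
synthetic linear width bias:

```r
set.seed(1)
truth <- rnorm(400, 0.90, 0.07)                  # true widths, um
auto  <- (truth - 0.20) / 0.88 + rnorm(400, 0, 0.01)   # biased segmenter
fit   <- fit_correction_model(auto, truth, metric = "width", seed = 1)
fit
#> correction_model [width]: 12000 draws (4 chains x 3000)
#>   m = 0.8598, n = 0.2168, sigma = 0.0094 (posterior means)
corrected <- apply_correction(fit, auto, K = 250, seed = 1)
kl_divergence(auto, truth)              #> 3.029
kl_divergence(corrected$summary, truth) #> 0.019
```

The fitted slope/intercept recover the generating bias (0.88, 0.20), and
the corrected distribution is two orders of magnitude closer to the truth
in KL divergence. Benchmarking a segmentation against ground truth:

```r
curve <- f1_curve(list(gt_mask), list(pred_mask))
curve$mean_f1        # one F1 value per IoU threshold, 0.5 ... 1.0
```

A thin command-line front end (`inst/cli/rodmorph`) exposes `measure`,
`simulate`, `benchmark`, `correct-fit` and `correct-apply` over file globs
and CSVs.

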