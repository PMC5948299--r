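# femload

Micro-finite-element based inverse remodelling: predicting hip joint
load vectors from trabecular bone architecture.

Bone adapts to its mechanical environment, so an observed architecture
carries information about the loads that shaped it. `femload`
implements the inverse-remodelling estimator of those loads for the
proximal femur, for researchers in computational biomechanics and
skeletal functional morphology: from a voxel image it segments bone,
builds an implant-style anatomical frame (femoral head sphere fit,
shaft axis, neck axis), applies a set of unit contact loads over
sphere–cone patches, solves linear elastic voxel finite-element models
for per-element strain energy density (SED), and finds the load scaling
that brings the tissue stimulus closest to remodelling equilibrium.

The core estimator: with unit-load SED fields $U_i(\mathbf{x})$ and an
equilibrium stimulus $\tilde U$ (0.02 MPa),

$$\min_{s \ge 0} \sum_{\mathbf{x}\in\mathcal{X}}
 \Bigl[\tilde U - \sum_{i=1}^{n} s_i\,U_i(\mathbf{x})\Bigr]^2,
 \qquad \alpha_i = \sqrt{n\,s_i},$$

solved by non-negative least squares; $\alpha_i \mathbf{F}_i$ are the
predicted joint load vectors (1000 N unit resultants at −20°, 20°, 60°,
100° frontal-plane inclination by default), and the coefficient of
variation of the combined stimulus before/after optimization measures
tissue-loading homogeneity.

The package also ships:

* a **synthetic specimen generator** — forward-remodelling–adapted
  "mini joint" structures with a known load history, CT-like grayscale
  rendering, and instrumented-prosthesis-style load traces — so the
  whole pipeline runs at desk scale with no external data;
* a packaged table of published per-specimen scaling factors and CoV
  values (`table2_fixture()`);
* a one-at-a-time **parameter sensitivity harness** (nine parameters,
  two variations each, with SED-field caching);
* **plausibility utilities**: peak extraction and inclination ranges
  from load traces, group summaries, Wilcoxon signed-rank test.

## Worked example

Generate a structure adapted to a single 20° load at its calibrated
physiologic magnitude, then recover the load from the image alone:

```r
library(femload)

M <- calibrate_load_magnitude(c(36, 36, 36), voxel_size = 0.5, angle = 20)
round(M, 1)
#> [1] 82.6

mix <- data.frame(angle = c(-20, 20, 60, 100), magnitude = c(0, 82.6, 0, 0))
specimen <- generate_adapted_structure(c(36, 36, 36), mix,
                                       remodelling_params(seed = 1))
specimen
#> <synthetic_specimen> 36 x 36 x 36 voxels, 2118 foreground, 12 remodelling iterations

inv <- invert_specimen(specimen)
inv$prediction
#> <load_prediction> 4 load cases over 586 ROI elements
#>   alpha: 0.00 0.09 0.05 0.00
#>   peak: 94.6 N at +20.0 deg; mean: 34.2 N at +33.6 deg
#>   CoV 128.9% -> 72.8%
```

The inversion identifies the generating case (peak at +20°) and
recovers its magnitude (94.6 N vs the true 82.6 N); optimization
roughly halves the tissue-loading inhomogeneity (CoV 129% → 73%).

Published printed inputs can be analysed directly:

```r
tab <- table2_fixture()
alpha1 <- as.numeric(tab[1, paste0("alpha_", 1:4)])
va <- vectors_and_angles(alpha1, c(-20, 20, 60, 100), 1000)
c(peak_deg = va$peak_inclination, mean_deg = round(va$mean_inclination, 1))
#> peak_deg mean_deg
#>     20.0     27.6
```

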