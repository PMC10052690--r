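# beziershape

Compact parametric shape codes for single-object binary segmentation masks.

Pixel-wise segmentation of solid, smooth structures — skin lesions, tumours
on MRI, lesions in endoscopy images — produces label maps that can be
ragged, disconnected, expensive to transmit, and awkward for a clinician to
correct. `beziershape` represents such an object by a closed piecewise
Bézier contour instead: the boundary is split at its four extreme points
(top, leftmost, bottom, rightmost) and each arc is fit with a quintic
Bézier segment

$$B(t) = \sum_{i=0}^{5} \binom{5}{i} (1-t)^{5-i} t^i \, P_i , \qquad t \in [0,1],$$

whose endpoints are pinned to the extreme points. The whole shape becomes a
**40-value shape code** (4 extreme points + 16 interior control points),
which is connected and smooth by construction, carries sub-pixel accuracy,
rescales to any resolution exactly (Bézier curves are affine-equivariant),
and can be refined by dragging control points.

The package provides:

* exact Bernstein and De Casteljau curve evaluation, cross-checked to 1e-12;
* sub-pixel contour extraction (0.5 iso-level marching squares), extreme-point
  location with corner tie-breaking, and arc splitting;
* the constrained least-squares fit of interior control points via the
  Moore–Penrose pseudo-inverse (`fit_segment`, `encode_mask`);
* decoding and even-odd pixel-center rasterization (`decode_code`,
  `rasterize_contour`), with JSON/PNG/CSV I/O;
* segmentation metrics: IoU, symmetric Hausdorff distance, Matthews
  correlation coefficient, false-positive/negative rates;
* a differentiable shape decoder with a two-term smooth-L1 loss
  (coordinate regression + decoded point matching, both weights 1),
  analytic gradients validated against finite differences, and a
  gradient-descent demonstrator (`total_loss`, `optimize_code`);
* a Gaussian-noise sensitivity experiment comparing the Bézier code with an
  equal-complexity 20-vertex polygon (`perturb_and_score`,
  `sensitivity_experiment`);
* a synthetic mask generator (ellipses, superellipses, Fourier blobs,
  dumbbells, squares) covering region-of-interest areas from ~750 to
  ~29,000 pixels, so everything is testable without external data.

## Worked example

```r
library(beziershape)

# a synthetic lesion-like blob, ~14k px in a 256x256 frame
mask <- generate_mask(shape_spec("fourier_blob", area = 14000, seed = 3))
sum(mask)
#> [1] 13995

code <- encode_mask(mask)          # 40-value shape code
length(code$values)
#> [1] 40

contour <- decode_code(code)       # 4 x 71 boundary points
recon   <- rasterize_contour(contour, 256, 256)
mask_iou(recon, mask)              # round-trip fidelity
#> [1] 0.9976452
```

The IoU of 0.998 says the 40 numbers reproduce the 13,995-pixel mask almost
exactly. Noise robustness against the equal-complexity polygon:

```r
masks <- generate_battery(10, "medium", seed = 7, kinds = "fourier_blob")
sensitivity_experiment(masks, deltas = c(5, 10, 20), trials = 20, seed = 7)
#>   delta representation  mean_iou     sd_iou n_trials
#> 1     5         bezier 0.9280365 0.01710046      200
#> 2    10         bezier 0.8614549 0.03219086      200
#> 3    20         bezier 0.7428559 0.06265799      200
#> 4     5        polygon 0.9031450 0.01868458      200
#> 5    10        polygon 0.8156745 0.03779126      200
#> 6    20        polygon 0.6622042 0.06480473      200
```

At every noise level δ the Bézier code retains a higher mean IoU than the
20-gon: spreading a control-point perturbation through the Bernstein basis
moves the curve less than moving a vertex moves a polygon corner.

A thin command-line surface over the same functions lives at
`inst/cli/beziershape.R` (subcommands `generate`, `encode`, `decode`,
`metrics`, `sensitivity`, `demo-optimize`, `degree-sweep`).

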