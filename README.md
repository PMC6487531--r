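# plantalign

Automated registration of multimodal plant images from high-throughput
phenotyping platforms.

Fluorescence (FLU) images show a plant shoot as a bright silhouette on a dark
background and are nearly trivial to segment; visible-light (VIS) images carry
the phenotype but bury the plant among soil, carriers and shadows. Once the
FLU image is geometrically aligned to the VIS image, the FLU segmentation mask
transfers directly — `plantalign` estimates that alignment, evaluates it, and
fuses several registrations when individual leaves moved between exposures.

All engines estimate a **similarity transform** (rotation `α`, isotropic scale
`s`, translation `(tx, ty)`) mapping moving (FLU) into fixed (VIS) pixel
coordinates:

```
        [ s·cos α   −s·sin α   tx ]
  T  =  [ s·sin α    s·cos α   ty ]
        [ 0          0          1 ]
```

Three independent engines are provided:

| Engine | Idea | Quality score |
|---|---|---|
| `register_fp()`  | multi-detector feature points (Harris, min-eigenvalue, FAST, multi-scale, extremal regions, DoG/DoH blobs), patch descriptors, ratio-test + cross-check matching, 2-point RANSAC with closed-form least-squares refit | inlier count |
| `register_pc()`  | Fourier–Mellin phase correlation: log-polar correlation of magnitude spectra for rotation/scale, Cartesian phase correlation for translation, subpixel peak fits | peak height `H` (gated at `H > 0.03`) |
| `register_mi()`  | Mattes-style mutual information (Parzen joint histogram) maximized by a seeded (1+1) evolution strategy over a coarse-to-fine pyramid | MI (nats) |

Around them: a preprocessing chain (grayscale GS / color-edge CE
representations, FLU→VIS prescaling, anti-aliased downscaling, blue-mat
removal), admissibility gating (|T| < 300 px, |sin α| < 0.15,
s ∈ [0.75, 1.25]), evaluation (success rate `SR = n_s/n`, asymmetric overlap
ratio `OR = a_r/a` against ground-truth masks), a scale sweep over
methods × representations × 36 scales in [0.3, 1.0], and an **integrated
mask**: the union of the FLU mask warped by every admissible registration,
which piecewise-covers nonuniformly moving leaves that no single rigid
transform can align. A seeded phantom generator
(`generate_phantom_pair()`, `split_motion_phantom()`) produces multimodal
FLU/VIS pairs with exact masks and known ground truth, so the whole pipeline
is testable without any external data.

## Worked example

```r
library(plantalign)

# a synthetic FLU/VIS pair whose true alignment is s = 1.04, 3 deg, known shift
ph  <- generate_phantom_pair(phantom_spec(
         seed = 42, truth = c(s = 1.04, alpha = 3 * pi / 180, tx = 12, ty = -8)))

pre <- prescale_flu_to_vis(ph$flu, ph$vis)     # match camera resolutions
mov <- color_edge_magnitude(pre$image)         # CE representation, moving
fix <- color_edge_magnitude(ph$vis)            # CE representation, fixed

r <- register_pc(mov, fix)                     # Fourier–Mellin engine
r
#> registration_result [PC, scale 1.00]: success (quality = 0.1391)
#> similarity_transform: s = 1.04093, alpha = 2.973 deg, t = (15.23, -21.63) px

pm <- (prescale_flu_to_vis(ph$flu_mask, ph$vis)$image >= 0.5) * 1
overlap_ratio(pm, ph$vis_mask, r$transform)$OR
#> [1] 0.9920481
```

The recovered transform matches the injected truth (global-frame decomposition
`s = 1.04`, `α = 3.0°`, `t = (15.58, −21.53)`) to a tenth of a percent in
scale and a fraction of a pixel, and transfers the plant mask with 99.2%
overlap — the discretization ceiling at this canvas size. The report line
means: the registration passed every admissibility gate (`success`), and the
phase-correlation peak height 0.139 is far above the 0.03 reliability
threshold.

A command-line front end is installed with the package
(`system.file("cli", "plantalign", package = "plantalign")`) with subcommands
`register`, `sweep`, `evaluate`, `phantoms` and `dump-config`; exit codes are
0 (success), 2 (gate failure), 3 (engine failure), 64 (usage error).

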