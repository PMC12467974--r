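# savehsi

Spectral reconstruction and narrow-band imaging (NBI) emulation from
standard white-light RGB endoscopy images.

Wireless capsule endoscopes and many conventional endoscopes record only
broad RGB channels and lack the narrow-band illumination hardware that
highlights mucosal vasculature at the haemoglobin absorption peaks (415 and
540 nm). `savehsi` implements a software-only enhancement chain: a colour
calibration fitted on a 24-patch checker converts each RGB pixel into an
estimated reflectance spectrum (a hyperspectral cube), and narrow-band
images are rendered from the reconstructed spectra.

The fitted chain is

1. sRGB decode → CIE 1931 XYZ (IEC transfer function, sRGB/D65 primaries);
2. polynomial camera correction `XYZ_corr = C · V`, where
   `V = [1, X, Y, Z, X², …, XYZ]` is the 20-term third-order feature vector
   and `C = XYZ_ref · pinv(V)` is fitted on the checker by SVD least squares;
3. a six-component PCA basis over the checker reflectances and a second
   matrix `M = Score · pinv(V_colour)` mapping corrected-XYZ features to PC
   scores, so each pixel's spectrum is `mean + (M·V)ᵀ·loadings`;
4. Gaussian narrow bands (415/540 nm primary, 600/700/780 nm auxiliary)
   whose weights are tuned by fast simulated annealing with the
   Cauchy–Lorentz visiting distribution under a mean-CIEDE2000 objective,
   rendered to display channels (415 → G,B; longer bands → R).

Quality metrics (spectral RMSE, CIEDE2000, SSIM, PSNR, histogram entropy)
and a synthetic-camera fixture generator make every stage testable without
any external data. See `vignettes/save-pipeline.Rmd` for the full model
description and design rationale.

## Worked example

Calibrate on synthetic checker captures and inspect the round trip:

```r
library(savehsi)

cap   <- simulate_capture(colorchecker_reference(), synthetic_camera())
model <- save_calibrate(cap$srgb, colorchecker_reference())
model
#> <save_model>
#>   <correction_model> order 3 (20 terms); training RMSE 0.04499; mean dE00 4.808 -> 0.179
#>   <transformation_model> 6 PCs x 20 terms; score RMSE 0.01317
#>   <nbi_model> 5 bands (nb415=1.000, nb540=1.000, nb600=0.100, nb700=0.100, nb780=0.100); objective unfitted

rt <- checker_roundtrip()
sprintf("mean RMSE %.4f | max RMSE %.4f | black RMSE %.4f | mean dE00 %.3f",
        rt$mean_rmse, rt$max_rmse, rt$black_rmse, rt$mean_de2000)
#> "mean RMSE 0.0045 | max RMSE 0.0095 | black RMSE 0.0039 | mean dE00 0.284"
```

The correction report reads: before calibration the synthetic camera's patch
colours are off by 4.8 CIEDE2000 units on average (clearly visible); after
the third-order fit the residual is 0.18 units (well below a just-noticeable
difference). The full round trip — camera colour → corrected XYZ → PC scores
→ spectrum — reproduces the 24 reference reflectances with a mean per-patch
RMSE of 0.0045 reflectance units, and re-integrating the reconstructed
spectra to colours leaves a mean difference of 0.28 ΔE00.

Convert an image and render NBI:

```r
cube <- rgb_image_to_cube(read_image("scene.png"), model$correction,
                          model$transformation)
write_cube_envi(cube, "scene.bsq")
nbi  <- render_nbi_image(cube, model$nbi)
write_image(nbi, "scene_nbi.png")
```

A command-line wrapper with the same functionality is installed at
`system.file("cli", "save.R", package = "savehsi")` (subcommands
`fixtures make`, `calibrate`, `convert --mode hsi|nbi`, `evaluate`,
`manifest summarize`).

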