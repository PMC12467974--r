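# High-level pipeline: one-call calibration from checker measurements, and
# the checker round-trip harness used for self-evaluation.

#' Calibrate the full RGB-to-spectrum model from checker measurements
#'
#' Fits, in order: the polynomial camera correction (camera XYZ against
#' spectrometer-reference XYZ of the checker patches), the PCA spectral basis
#' over the reference reflectances, and the transformation matrix from
#' corrected-XYZ features to PC scores.
#'
#' @param camera_srgb 24 x 3 (or n x 3) matrix of measured patch colours,
#'   sRGB-encoded in `[0, 1]`.
#' @param reference_spectra Paired reference reflectance spectra (matrix with
#'   grid attribute, or list of [reflectance_spectrum()]).
#' @param n_pc Number of principal components (default 6).
#' @param order Polynomial expansion order (default 3).
#' @param illum,cmf Optional illuminant/observer; bundled D65 and CIE 1931 by
#'   default.
#' @param grid Optional grid when `reference_spectra` is a bare matrix.
#' @return An object of class `save_model`: `correction`, `transformation`,
#'   `nbi` (default [nbi_model()], uncalibrated) and `grid`.
#' @export
save_calibrate <- function(camera_srgb, reference_spectra, n_pc = 6,
                           order = 3, illum = NULL, cmf = NULL, grid = NULL) {
  sp <- .as_spectra_matrix(reference_spectra, grid)
  if (is.null(illum)) illum <- illuminant_d65(sp$grid)
  if (is.null(cmf)) cmf <- cmf_cie1931(sp$grid)
  cmf3 <- cbind(cmf$xbar, cmf$ybar, cmf$zbar)
  ref_xyz <- .spectra_to_xyz(sp$values, sp$grid, illum$power, cmf3)
  white <- drop(.spectra_to_xyz(matrix(1, 1, n_bands(sp$grid)), sp$grid,
                                illum$power, cmf3))
  cam <- .as_triplet_matrix(camera_srgb, "camera sRGB")
  cam_xyz <- linear_rgb_to_xyz(srgb_to_linear_rgb(cam))
  expansion <- feature_expansion(order)
  correction <- fit_correction_model(cam_xyz, ref_xyz, expansion,
                                     white = white)
  corrected <- apply_correction(correction, cam_xyz)
  basis <- fit_spectral_basis(sp$values, n_pc = n_pc, grid = sp$grid)
  transformation <- fit_transformation_matrix(basis, corrected, expansion)
  structure(list(correction = correction, transformation = transformation,
                 nbi = nbi_model(), grid = sp$grid),
            class = "save_model")
}

#' @export
print.save_model <- function(x, ...) {
  cat("<save_model>\n  ")
  print(x$correction)
  cat("  ")
  print(x$transformation)
  cat("  ")
  print(x$nbi)
  invisible(x)
}

#' Checker round-trip self-evaluation harness
#'
#' Captures the 24 bundled checker patches through a synthetic camera,
#' calibrates the full chain on them, reconstructs each patch spectrum from
#' its own camera colour, and scores the reconstruction. `measurement =
#' "direct"` uses noise-free continuous patch colours from
#' [simulate_capture()]; `measurement = "mosaic"` renders an 8-bit mosaic
#' with per-pixel noise and measures patch colours as ROI means, the standard
#' practice for noisy captures.
#'
#' Per-patch RMSE is computed over the grid's integration window (the range
#' the XYZ integrals see); CIEDE2000 compares the colours of reconstructed
#' and reference spectra under the same illuminant and observer.
#'
#' @param camera A [synthetic_camera()].
#' @param measurement `"direct"` or `"mosaic"`.
#' @param patch_px Mosaic patch size in pixels (mosaic measurement only).
#' @param n_pc,order Model sizes (defaults 6 PCs, order 3).
#' @param grid A [spectral_grid()].
#' @return List with `per_patch_rmse` (named), `mean_rmse`, `max_rmse`,
#'   `black_rmse`, `mean_de2000`, `pre_de2000`, `post_de2000` (correction-fit
#'   means), `model` (the fitted `save_model`) and `reconstructed` (24 x
#'   n_bands matrix).
#' @export
checker_roundtrip <- function(camera = synthetic_camera(),
                              measurement = c("direct", "mosaic"),
                              patch_px = 16, n_pc = 6, order = 3,
                              grid = spectral_grid()) {
  measurement <- match.arg(measurement)
  checker <- colorchecker_reference(grid)
  illum <- illuminant_d65(grid)
  cmf <- cmf_cie1931(grid)
  cmf3 <- cbind(cmf$xbar, cmf$ybar, cmf$zbar)
  ref_xyz <- .spectra_to_xyz(checker, grid, illum$power, cmf3)
  white <- drop(.spectra_to_xyz(matrix(1, 1, n_bands(grid)), grid,
                                illum$power, cmf3))
  cam_xyz <- if (measurement == "direct") {
    cap <- simulate_capture(checker, camera, illum, cmf)
    linear_rgb_to_xyz(srgb_to_linear_rgb(cap$srgb))
  } else {
    mos <- make_checker_mosaic(camera, patch_px = patch_px, grid = grid,
                               illum = illum, cmf = cmf)
    mosaic_patch_xyz(mos$image, mos$patch_ids)
  }
  expansion <- feature_expansion(order)
  correction <- fit_correction_model(cam_xyz, ref_xyz, expansion,
                                     white = white)
  corrected <- apply_correction(correction, cam_xyz)
  basis <- fit_spectral_basis(checker, n_pc = n_pc)
  transformation <- fit_transformation_matrix(basis, corrected, expansion)
  recon <- reconstruct_reflectance(transformation, corrected)
  rownames(recon) <- rownames(checker)
  idx <- window_index(grid)
  per <- sqrt(rowMeans((checker[, idx, drop = FALSE] -
                          recon[, idx, drop = FALSE])^2))
  names(per) <- rownames(checker)
  lab_ref <- xyz_to_lab(ref_xyz, white)
  lab_rec <- xyz_to_lab(.spectra_to_xyz(recon, grid, illum$power, cmf3),
                        white)
  model <- structure(list(correction = correction,
                          transformation = transformation,
                          nbi = nbi_model(), grid = grid),
                     class = "save_model")
  list(per_patch_rmse = per,
       mean_rmse = mean(per),
       max_rmse = max(per),
       black_rmse = unname(per["black"]),
       mean_de2000 = mean(ciede2000(lab_rec, lab_ref)),
       pre_de2000 = mean(correction$fit_report$de2000_pre),
       post_de2000 = mean(correction$fit_report$de2000_post),
       model = model,
       reconstructed = recon)
}
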