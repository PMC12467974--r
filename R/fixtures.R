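# Synthetic fixtures: bundled 24-patch checker reflectances, a parametric
# synthetic camera, planted calibration distortion, and checker mosaics with
# ground-truth cubes. Everything needed to exercise the pipeline offline.

#' Bundled 24-patch colour checker reflectances
#'
#' A synthetic analog of the classic 24-patch calibration chart (six neutral
#' greys from white to black plus 18 smooth chromatic patches), bundled as a
#' CSV table of parametric reflectance spectra and resampled onto the working
#' grid. The spectra share the smoothness class of real chart reflectances;
#' they are generated, not measured.
#'
#' @param grid A [spectral_grid()].
#' @param as `"matrix"` (default) for a 24 x n_bands matrix with patch row
#'   names and a `grid` attribute, or `"list"` for a named list of
#'   [reflectance_spectrum()] objects.
#' @return Spectra of the 24 patches.
#' @export
colorchecker_reference <- function(grid = spectral_grid(),
                                   as = c("matrix", "list")) {
  as <- match.arg(as)
  tab <- utils::read.csv(extdata_path("colorchecker_synthetic_24patch.csv"))
  nm <- setdiff(names(tab), "wavelength_nm")
  vals <- t(vapply(nm, function(p)
    resample_to_grid(tab$wavelength_nm, tab[[p]], grid),
    numeric(n_bands(grid))))
  rownames(vals) <- nm
  if (as == "list")
    return(stats::setNames(
      lapply(nm, function(p) reflectance_spectrum(vals[p, ], grid)), nm))
  attr(vals, "grid") <- grid
  vals
}

#' Parametric synthetic RGB camera
#'
#' Smooth Gaussian-shaped spectral sensitivities (deliberately distinct from
#' the CIE observer so the polynomial correction has real work to do), an
#' sRGB-style encoder, per-channel dark offset, additive Gaussian shot noise
#' on the linear response, and an optional planted polynomial colour
#' distortion.
#'
#' @param peaks R, G, B sensitivity peak wavelengths in nm.
#' @param fwhm Sensitivity FWHM in nm (shared).
#' @param dark_offset Per-channel constant in `[0, 0.05]` added to the linear
#'   response.
#' @param noise_sigma Gaussian noise standard deviation in linear units.
#' @param distortion `NULL`, the string `"planted"` (loads the bundled
#'   second-order fixture), or a 3 x 10 coefficient matrix over the terms
#'   `1, r, g, b, r^2, g^2, b^2, rg, rb, gb`.
#' @param seed Integer RNG seed; captures are reproducible given the seed.
#' @param sensitivities Optional explicit 3 x n_bands sensitivity matrix on
#'   the working grid, overriding the parametric Gaussian curves.
#' @return An object of class `synthetic_camera`.
#' @export
synthetic_camera <- function(peaks = c(610, 550, 460), fwhm = 70,
                             dark_offset = c(0, 0, 0), noise_sigma = 0,
                             distortion = NULL, seed = 1L,
                             sensitivities = NULL) {
  stopifnot(length(peaks) == 3, fwhm > 0, length(dark_offset) %in% c(1, 3),
            noise_sigma >= 0)
  dark_offset <- rep_len(dark_offset, 3)
  if (any(dark_offset < 0) || any(dark_offset > 0.05))
    stop("`dark_offset` must lie in [0, 0.05]")
  if (is.character(distortion) && identical(distortion, "planted"))
    distortion <- planted_distortion()
  if (!is.null(distortion) &&
      (!is.matrix(distortion) || !all(dim(distortion) == c(3, 10))))
    stop("`distortion` must be NULL, \"planted\", or a 3 x 10 matrix")
  if (!is.null(sensitivities) &&
      (!is.matrix(sensitivities) || nrow(sensitivities) != 3 ||
       any(sensitivities < 0)))
    stop("`sensitivities` must be a nonnegative 3 x n_bands matrix")
  structure(list(peaks = peaks, fwhm = fwhm, dark_offset = dark_offset,
                 noise_sigma = noise_sigma, distortion = distortion,
                 seed = as.integer(seed), sensitivities = sensitivities),
            class = "synthetic_camera")
}

#' @export
print.synthetic_camera <- function(x, ...) {
  cat(sprintf(
    "<synthetic_camera> peaks %s nm, FWHM %g nm; dark %s; noise sigma %g;%s seed %d\n",
    paste(x$peaks, collapse = "/"), x$fwhm,
    paste(format(x$dark_offset), collapse = "/"), x$noise_sigma,
    if (is.null(x$distortion)) " no distortion;" else " planted distortion;",
    x$seed))
  invisible(x)
}

#' Spectral sensitivities of a synthetic camera
#'
#' @param camera A [synthetic_camera()].
#' @param grid A [spectral_grid()].
#' @return 3 x n_bands matrix (rows R, G, B), nonnegative.
#' @export
camera_sensitivities <- function(camera, grid = spectral_grid()) {
  stopifnot(inherits(camera, "synthetic_camera"))
  if (!is.null(camera$sensitivities)) {
    if (ncol(camera$sensitivities) != n_bands(grid))
      stop("explicit sensitivities do not match the grid band count")
    out <- camera$sensitivities
    rownames(out) <- c("R", "G", "B")
    return(out)
  }
  s <- camera$fwhm / (2 * sqrt(2 * log(2)))
  out <- t(sapply(camera$peaks, function(p)
    exp(-((grid$wavelengths - p)^2) / (2 * s^2))))
  rownames(out) <- c("R", "G", "B")
  out
}

#' Bundled planted calibration distortion
#'
#' The fixed second-order polynomial colour distortion used by the
#' calibration-gain harness, stored as a CSV fixture (not tuned per run).
#' Coefficients act on linear RGB over the terms
#' `1, r, g, b, r^2, g^2, b^2, rg, rb, gb` and are strong enough that the
#' pre-correction mean CIEDE2000 on the bundled checker exceeds 10.
#'
#' @return 3 x 10 numeric matrix with channel row names.
#' @export
planted_distortion <- function() {
  tab <- utils::read.csv(extdata_path("planted_distortion_synthetic.csv"))
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$channel
  m
}

.apply_rgb_distortion <- function(rgb, coef) {
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  feats <- cbind(1, r, g, b, r^2, g^2, b^2, r * g, r * b, g * b)
  feats %*% t(coef)
}

# noiseless linear camera response (distortion and dark applied, no noise);
# each channel normalized by its response to a perfect reflector
.camera_linear <- function(values, grid, camera, illum) {
  sens <- camera_sensitivities(camera, grid)
  wl <- grid$wavelengths
  tw <- diff(wl)
  wts <- c(tw / 2, 0) + c(0, tw / 2)
  lin <- sapply(1:3, function(ch) {
    w <- illum$power * sens[ch, ] * wts
    as.vector(values %*% w) / sum(w)
  })
  lin <- matrix(lin, ncol = 3)
  if (!is.null(camera$distortion))
    lin <- .apply_rgb_distortion(lin, camera$distortion)
  sweep(lin, 2, camera$dark_offset, `+`)
}

#' Simulate paired camera and spectrometer measurements of a scene
#'
#' Computes the camera's linear response to each scene spectrum under the
#' illuminant (integral of illuminant x reflectance x sensitivity, normalized
#' per channel to the perfect reflector), applies the planted distortion and
#' dark offset, adds Gaussian noise drawn from the camera's seed, clips to
#' `[0, 1]` and sRGB-encodes. The paired noiseless spectrometer-side XYZ is
#' computed by trapezoid integration against the CIE observer.
#'
#' @param spectra Scene spectra (anything accepted by [spectrum_to_xyz()]).
#' @param camera A [synthetic_camera()].
#' @param illum An [illuminant()]; bundled D65 by default.
#' @param cmf A [cmf_cie1931()]; bundled observer by default.
#' @param grid Optional grid when `spectra` is a bare matrix.
#' @return List with `srgb` (n x 3 in `[0, 1]`), `xyz_reference` (n x 3,
#'   noiseless spectrometer side) and `linear` (n x 3 noisy linear response).
#' @export
simulate_capture <- function(spectra, camera, illum = NULL, cmf = NULL,
                             grid = NULL) {
  stopifnot(inherits(camera, "synthetic_camera"))
  sp <- .as_spectra_matrix(spectra, grid)
  if (is.null(illum)) illum <- illuminant_d65(sp$grid)
  if (is.null(cmf)) cmf <- cmf_cie1931(sp$grid)
  stop_if_grid_mismatch(sp$grid, illum$grid)
  stop_if_grid_mismatch(sp$grid, cmf$grid)
  lin <- .camera_linear(sp$values, sp$grid, camera, illum)
  if (camera$noise_sigma > 0)
    lin <- lin + .with_seed(camera$seed,
      matrix(stats::rnorm(length(lin), 0, camera$noise_sigma),
             nrow = nrow(lin)))
  lin_cl <- pmin(pmax(lin, 0), 1)
  xyz_ref <- .spectra_to_xyz(sp$values, sp$grid, illum$power,
                             cbind(cmf$xbar, cmf$ybar, cmf$zbar))
  rownames(xyz_ref) <- rownames(sp$values)
  list(srgb = linear_rgb_to_srgb(lin_cl), xyz_reference = xyz_ref,
       linear = lin)
}

#' Render a synthetic checker mosaic with its ground-truth cube
#'
#' Lays the 24 bundled checker patches out as a 4 x 6 mosaic, renders it
#' through the synthetic camera with per-pixel noise, optionally quantizes to
#' 8-bit levels, and returns the true per-pixel reflectance cube alongside.
#'
#' @param camera A [synthetic_camera()].
#' @param patch_px Patch side length in pixels (>= 1).
#' @param grid A [spectral_grid()].
#' @param illum,cmf Optional illuminant/observer; bundled D65 and CIE 1931 by
#'   default.
#' @param quantize Quantize the sRGB image to 8-bit levels (default TRUE).
#' @return List with `image` (4p x 6p x 3 sRGB array), `cube`
#'   ([hyperspectral_cube()] of true reflectances), `patch_ids` (4p x 6p
#'   integer matrix of patch indices) and `xyz_reference` (24 x 3).
#' @export
make_checker_mosaic <- function(camera = synthetic_camera(), patch_px = 16,
                                grid = spectral_grid(), illum = NULL,
                                cmf = NULL, quantize = TRUE) {
  stopifnot(patch_px >= 1)
  checker <- colorchecker_reference(grid)
  if (is.null(illum)) illum <- illuminant_d65(grid)
  if (is.null(cmf)) cmf <- cmf_cie1931(grid)
  h <- 4L * patch_px; w <- 6L * patch_px
  patch_of <- function(row, col) (row - 1L) * 6L + col
  patch_ids <- outer(seq_len(h), seq_len(w), function(i, j)
    patch_of(ceiling(i / patch_px), ceiling(j / patch_px)))
  lin0 <- .camera_linear(checker, grid, camera, illum)
  ids <- as.vector(patch_ids)
  lin_px <- lin0[ids, , drop = FALSE]
  if (camera$noise_sigma > 0)
    lin_px <- lin_px + .with_seed(camera$seed,
      matrix(stats::rnorm(length(lin_px), 0, camera$noise_sigma),
             nrow = nrow(lin_px)))
  srgb <- linear_rgb_to_srgb(pmin(pmax(lin_px, 0), 1))
  if (quantize) srgb <- round(srgb * 255) / 255
  image <- array(srgb, dim = c(h, w, 3))
  cube <- hyperspectral_cube(
    array(checker[ids, , drop = FALSE], dim = c(h, w, n_bands(grid))), grid)
  xyz_ref <- .spectra_to_xyz(checker, grid, illum$power,
                             cbind(cmf$xbar, cmf$ybar, cmf$zbar))
  rownames(xyz_ref) <- rownames(checker)
  list(image = image, cube = cube, patch_ids = patch_ids,
       xyz_reference = xyz_ref)
}

#' Mean camera XYZ per mosaic patch
#'
#' Decodes the mosaic to linear RGB, averages pixels within each patch (the
#' standard ROI-mean colour measurement), and converts to XYZ.
#'
#' @param image Mosaic sRGB array.
#' @param patch_ids Integer matrix of patch indices, as returned by
#'   [make_checker_mosaic()].
#' @return n_patches x 3 matrix of camera XYZ.
#' @export
mosaic_patch_xyz <- function(image, patch_ids) {
  lin <- matrix(srgb_to_linear_rgb(.as_rgb_image(image)), ncol = 3)
  ids <- as.vector(patch_ids)
  means <- sapply(1:3, function(ch)
    tapply(lin[, ch], ids, mean))
  linear_rgb_to_xyz(matrix(means, ncol = 3))
}
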