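# Core colour science: sRGB transfer functions, the sRGB/D65 primary matrix,
# spectral integration to XYZ, CIE Lab, and CIEDE2000.

# IEC 61966-2-1 sRGB -> XYZ primary matrix (D65), Y of white = 1
.srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.check_unit_range <- function(x, what) {
  if (any(!is.finite(x)) || any(x < -1e-9) || any(x > 1 + 1e-9))
    stop(sprintf("%s components must lie in [0, 1]", what), call. = FALSE)
}

#' sRGB transfer functions
#'
#' `srgb_to_linear_rgb()` decodes sRGB-encoded values (8-bit inputs divided by
#' 255 first) to linear light using the IEC 61966-2-1 piecewise function
#' (linear segment below 0.04045, exponent 2.4 above);
#' `linear_rgb_to_srgb()` is the exact inverse.
#'
#' @param x Numeric vector, matrix or array with components in `[0, 1]`.
#' @return An object of the same shape as `x`.
#' @examples
#' srgb_to_linear_rgb(0.5)
#' linear_rgb_to_srgb(srgb_to_linear_rgb(0.73))
#' @export
srgb_to_linear_rgb <- function(x) {
  .check_unit_range(x, "sRGB")
  out <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  attributes(out) <- attributes(x)
  out
}

#' @rdname srgb_to_linear_rgb
#' @export
linear_rgb_to_srgb <- function(x) {
  .check_unit_range(x, "linear RGB")
  out <- ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  attributes(out) <- attributes(x)
  out
}

.as_triplet_matrix <- function(x, what = "colour") {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop(sprintf("%s matrix must have 3 columns", what))
    x
  } else if (is.numeric(x) && length(x) == 3) {
    matrix(x, nrow = 1)
  } else {
    stop(sprintf("%s must be a length-3 vector or an n x 3 matrix", what))
  }
}

.restore_shape <- function(out, x, names3) {
  colnames(out) <- names3
  if (!is.matrix(x)) out <- drop(out)
  out
}

#' Linear RGB to CIE 1931 XYZ and back
#'
#' Applies the standard sRGB/D65 3x3 primary matrix, scaled so linear
#' `(1, 1, 1)` maps to the D65 white point on the 0--100 scale. Negative
#' tristimulus values from out-of-gamut input are carried through unclipped.
#'
#' @param rgb,xyz Length-3 vector or n x 3 matrix.
#' @return Matching shape; XYZ on the 0--100 scale.
#' @export
linear_rgb_to_xyz <- function(rgb) {
  m <- .as_triplet_matrix(rgb, "linear RGB")
  if (any(!is.finite(m))) stop("linear RGB must be finite")
  .restore_shape(100 * m %*% t(.srgb_to_xyz_matrix), rgb, c("X", "Y", "Z"))
}

#' @rdname linear_rgb_to_xyz
#' @export
xyz_to_linear_rgb <- function(xyz) {
  m <- .as_triplet_matrix(xyz, "XYZ")
  if (any(!is.finite(m))) stop("XYZ must be finite")
  .restore_shape(m %*% t(solve(.srgb_to_xyz_matrix)) / 100, xyz,
                 c("R", "G", "B"))
}

#' Integrate reflectance spectra to XYZ tristimulus values
#'
#' Discrete trapezoid quadrature of `k * integral(S R cmf dlambda)` over the
#' grid's integration window, with `k = 100 / integral(S ybar dlambda)` so a
#' perfect reflector always has Y = 100.
#'
#' @param spectra A [reflectance_spectrum()], a list of them, or an
#'   n x n_bands matrix (pass `grid` via attribute or use spectra objects).
#' @param illum An [illuminant()] on the same grid.
#' @param cmf A [cmf_cie1931()] on the same grid.
#' @return Named XYZ vector for a single spectrum, otherwise an n x 3 matrix.
#' @examples
#' g <- spectral_grid()
#' white <- reflectance_spectrum(rep(1, n_bands(g)), g)
#' spectrum_to_xyz(white, illuminant_d65(g), cmf_cie1931(g))
#' @export
spectrum_to_xyz <- function(spectra, illum, cmf) {
  sp <- .as_spectra_matrix(spectra)
  stop_if_grid_mismatch(sp$grid, illum$grid)
  stop_if_grid_mismatch(sp$grid, cmf$grid)
  out <- .spectra_to_xyz(sp$values, sp$grid, illum$power,
                         cbind(cmf$xbar, cmf$ybar, cmf$zbar))
  rownames(out) <- rownames(sp$values)
  if (inherits(spectra, "reflectance_spectrum")) drop(out) else out
}

.spectra_to_xyz <- function(values, grid, power, cmf3) {
  idx <- window_index(grid)
  wl <- grid$wavelengths[idx]
  sy <- power[idx] * cmf3[idx, 2]
  denom <- trapz(wl, sy)
  if (abs(denom) < 1e-12)
    stop("normalization error: illuminant x ybar integrates to zero over the window")
  k <- 100 / denom
  out <- sapply(1:3, function(ch) {
    w <- power[idx] * cmf3[idx, ch]
    # trapezoid weights folded into a dot product for all spectra at once
    tw <- diff(wl)
    wts <- c(tw / 2, 0) + c(0, tw / 2)
    k * as.vector(values[, idx, drop = FALSE] %*% (w * wts))
  })
  out <- matrix(out, ncol = 3, dimnames = list(NULL, c("X", "Y", "Z")))
  out
}

#' Normalization scalar of an illuminant
#'
#' `k = 100 / integral(S ybar dlambda)` over the integration window, for a
#' given observer; recomputed from the current power and CMFs on every call.
#'
#' @param illum An [illuminant()].
#' @param cmf A [cmf_cie1931()] on the same grid.
#' @return Positive scalar.
#' @export
illuminant_k <- function(illum, cmf) {
  stop_if_grid_mismatch(illum$grid, cmf$grid)
  idx <- window_index(illum$grid)
  wl <- illum$grid$wavelengths[idx]
  denom <- trapz(wl, illum$power[idx] * cmf$ybar[idx])
  if (abs(denom) < 1e-12)
    stop("normalization error: illuminant x ybar integrates to zero over the window")
  100 / denom
}

#' Package default white point
#'
#' XYZ of the perfect reflector under D65 using the bundled tables on the
#' given grid. All Lab conversions in the calibration chain default to this
#' white so the spectral and camera routes stay self-consistent.
#'
#' @param grid A [spectral_grid()].
#' @return Named XYZ vector with Y = 100.
#' @export
d65_white_xyz <- function(grid = spectral_grid()) {
  spectrum_to_xyz(reflectance_spectrum(rep(1, n_bands(grid)), grid),
                  illuminant_d65(grid), cmf_cie1931(grid))
}

#' XYZ to CIE 1976 L*a*b*
#'
#' Standard cube-root / linear-segment conversion relative to a white point
#' with Y = 100.
#'
#' @param xyz Length-3 vector or n x 3 matrix on the 0--100 scale.
#' @param white White point XYZ (positive components, Y = 100). Defaults to
#'   [d65_white_xyz()] on the default grid.
#' @return Lab triplet(s), same shape convention as `xyz`.
#' @export
xyz_to_lab <- function(xyz, white = d65_white_xyz()) {
  m <- .as_triplet_matrix(xyz, "XYZ")
  white <- as.numeric(white)
  if (length(white) != 3 || any(!is.finite(white)) || any(white <= 0))
    stop("`white` must have three positive components")
  if (abs(white[2] - 100) > 1e-2)
    stop("`white` must be normalized to Y = 100")
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(m[, 1] / white[1])
  fy <- f(m[, 2] / white[2])
  fz <- f(m[, 3] / white[3])
  .restore_shape(cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz)),
                 xyz, c("L", "a", "b"))
}

#' CIEDE2000 colour difference
#'
#' Full CIEDE2000 formula with parametric factors kL = kC = kH = 1,
#' vectorized over rows. Symmetric in its two arguments.
#'
#' @param lab1,lab2 Lab triplets (length-3 vectors or n x 3 matrices).
#' @return Nonnegative colour difference(s).
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))
#' @export
ciede2000 <- function(lab1, lab2) {
  m1 <- .as_triplet_matrix(lab1, "Lab")
  m2 <- .as_triplet_matrix(lab2, "Lab")
  if (nrow(m1) != nrow(m2)) {
    if (nrow(m1) == 1) m1 <- m1[rep(1, nrow(m2)), , drop = FALSE]
    else if (nrow(m2) == 1) m2 <- m2[rep(1, nrow(m1)), , drop = FALSE]
    else stop("lab1 and lab2 must have the same number of rows")
  }
  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]
  deg <- pi / 180
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) / deg) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) / deg) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
                ifelse(abs(dh) <= 180, dh, dh - sign(dh) * 360))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * deg / 2)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
                ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                       ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))
  T_ <- 1 - 0.17 * cos((hbp - 30) * deg) + 0.24 * cos(2 * hbp * deg) +
    0.32 * cos((3 * hbp + 6) * deg) - 0.20 * cos((4 * hbp - 63) * deg)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * dtheta * deg) * RC
  dE <- sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
               RT * (dCp / SC) * (dHp / SH))
  unname(dE)
}
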