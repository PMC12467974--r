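# Spectrum- and image-fidelity metrics: spectral RMSE, SSIM, PSNR, histogram
# entropy, and a combined quality report.

#' Root-mean-square difference between two reflectance spectra
#'
#' @param a,b [reflectance_spectrum()] objects on one grid, or plain numeric
#'   vectors of equal length.
#' @return Nonnegative scalar.
#' @export
spectral_rmse <- function(a, b) {
  if (inherits(a, "reflectance_spectrum") &&
      inherits(b, "reflectance_spectrum")) {
    stop_if_grid_mismatch(a$grid, b$grid)
    a <- a$values; b <- b$values
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("spectra must share one grid")
  sqrt(mean((a - b)^2))
}

.as_gray_stack <- function(x, what = "image") {
  if (is.matrix(x)) return(list(x))
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[3]), function(ch) x[, , ch]))
  stop(sprintf("%s must be a matrix or an H x W x C array", what))
}

# valid-region separable Gaussian filter; K is the (n - 2r) x n banded
# convolution operator for one axis
.gauss_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- n - 2L * r
  if (m < 1) stop("image too small for the filter window")
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + 2L * r)] <- kernel
  K
}

#' Structural similarity index
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma = 1.5), K1 = 0.01,
#' K2 = 0.03, and population (uncentred-moment) statistics, averaged over the
#' valid filter region. Multi-channel images are averaged over per-channel
#' SSIM values.
#'
#' @param a,b Images of identical shape (matrix or H x W x C array) on the
#'   `[0, data_range]` scale, at least 11 x 11.
#' @param data_range Dynamic range of the data (255 for 8-bit).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = 255) {
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  ach <- .as_gray_stack(a); bch <- .as_gray_stack(b)
  r <- 5L
  x <- seq(-r, r)
  kern <- exp(-x^2 / (2 * 1.5^2)); kern <- kern / sum(kern)
  vals <- mapply(function(x1, x2) {
    if (any(dim(x1) < 2L * r + 1L)) stop("images must be at least 11 x 11")
    Kr <- .gauss_operator(nrow(x1), kern)
    Kc <- t(.gauss_operator(ncol(x1), kern))
    filt <- function(z) Kr %*% z %*% Kc
    ux <- filt(x1); uy <- filt(x2)
    vx <- filt(x1 * x1) - ux^2
    vy <- filt(x2 * x2) - uy^2
    vxy <- filt(x1 * x2) - ux * uy
    C1 <- (0.01 * data_range)^2
    C2 <- (0.03 * data_range)^2
    mean(((2 * ux * uy + C1) * (2 * vxy + C2)) /
           ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
  }, ach, bch)
  mean(vals)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(data_range^2 / MSE)` in dB; identical images return the
#' documented cap (100 dB by convention) rather than infinity.
#'
#' @param a,b Images of identical shape on the `[0, data_range]` scale.
#' @param data_range Dynamic range (255 for 8-bit).
#' @param cap Value returned for identical images.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, data_range = 255, cap = 100) {
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(cap)
  min(10 * log10(data_range^2 / mse), cap)
}

.to_luma <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    # ITU-R BT.601 luma for colour input
    0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  } else if (is.matrix(x) || is.numeric(x)) {
    x
  } else stop("image must be numeric")
}

#' Shannon entropy of an 8-bit image histogram
#'
#' Entropy in bits of the 256-bin normalized histogram; colour images are
#' converted to BT.601 luma first.
#'
#' @param x Image on the 0--255 scale (matrix or H x W x 3 array).
#' @return Entropy in bits (0 to 8).
#' @export
shannon_entropy <- function(x) {
  if (length(x) == 0) stop("empty image")
  g <- round(pmin(pmax(.to_luma(x), 0), 255))
  p <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy difference between two images
#'
#' Absolute difference of histogram entropies, also expressed as a percent of
#' the 8-bit maximum. The percent form mirrors how entropy agreement is often
#' quoted for enhanced-image comparisons; it is an experimental convention.
#'
#' @param a,b Images on the 0--255 scale.
#' @return List with `bits` and `percent`.
#' @export
entropy_difference <- function(a, b) {
  d <- abs(shannon_entropy(a) - shannon_entropy(b))
  list(bits = d, percent = d / 8 * 100)
}

#' Combined quality report
#'
#' Image metrics (SSIM, PSNR, entropy) between a reference and a test image,
#' optionally with per-patch spectral RMSE and mean CIEDE2000 when paired
#' spectra are supplied.
#'
#' @param reference,test Images of identical shape on the `[0, 1]` or 0--255
#'   scale (scaled to 0--255 internally when the maximum is <= 1).
#' @param spectra_reference,spectra_test Optional paired spectra (matrix with
#'   grid attribute or lists of [reflectance_spectrum()]).
#' @param illum,cmf Optional illuminant/observer for the CIEDE2000 summary;
#'   bundled D65 and CIE 1931 by default.
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(reference, test,
                           spectra_reference = NULL, spectra_test = NULL,
                           illum = NULL, cmf = NULL) {
  scale255 <- function(x) if (max(x) <= 1 + 1e-9) x * 255 else x
  reference <- scale255(reference); test <- scale255(test)
  rep_ <- list(ssim = ssim(reference, test),
               psnr = psnr(reference, test),
               entropy_reference = shannon_entropy(reference),
               entropy_test = shannon_entropy(test),
               entropy_difference = entropy_difference(reference, test))
  if (!is.null(spectra_reference) && !is.null(spectra_test)) {
    sr <- .as_spectra_matrix(spectra_reference)
    st <- .as_spectra_matrix(spectra_test)
    stop_if_grid_mismatch(sr$grid, st$grid)
    if (nrow(sr$values) != nrow(st$values))
      stop("spectra sets must pair 1:1")
    per <- sqrt(rowMeans((sr$values - st$values)^2))
    if (is.null(illum)) illum <- illuminant_d65(sr$grid)
    if (is.null(cmf)) cmf <- cmf_cie1931(sr$grid)
    cmf3 <- cbind(cmf$xbar, cmf$ybar, cmf$zbar)
    white <- drop(.spectra_to_xyz(matrix(1, 1, n_bands(sr$grid)), sr$grid,
                                  illum$power, cmf3))
    lab_r <- xyz_to_lab(.spectra_to_xyz(sr$values, sr$grid, illum$power, cmf3),
                        white)
    lab_t <- xyz_to_lab(.spectra_to_xyz(st$values, sr$grid, illum$power, cmf3),
                        white)
    rep_$per_patch_rmse <- per
    rep_$mean_rmse <- mean(per)
    rep_$max_rmse <- max(per)
    rep_$mean_de2000 <- mean(ciede2000(lab_r, lab_t))
  }
  structure(rep_, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> SSIM %.4f | PSNR %.2f dB | entropy %.3f vs %.3f bits\n",
              x$ssim, x$psnr, x$entropy_reference, x$entropy_test))
  if (!is.null(x$mean_rmse))
    cat(sprintf("  spectral RMSE mean %.4f max %.4f | mean dE00 %.3f\n",
                x$mean_rmse, x$max_rmse, x$mean_de2000))
  invisible(x)
}
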