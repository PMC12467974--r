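# PCA spectral basis over the checker reflectances, the transformation matrix
# mapping corrected-XYZ features to PC scores, and per-pixel reconstruction.

#' Fit a PCA spectral basis
#'
#' Mean-centred PCA by SVD over a set of reflectance spectra. Deterministic up
#' to sign; signs are fixed so each loading's largest-magnitude entry is
#' positive. The training scores are retained so a transformation matrix can
#' be fitted against paired camera colours.
#'
#' @param spectra A list of [reflectance_spectrum()] objects or an
#'   n x n_bands matrix with a `grid` attribute.
#' @param n_pc Number of principal components to keep (default 6).
#' @param grid Optional [spectral_grid()] when `spectra` is a bare matrix.
#' @return An object of class `spectral_basis`: `grid`, `mean_spectrum`,
#'   `loadings` (n_pc x n_bands, orthonormal rows), `explained_variance_ratio`
#'   (per kept PC, nonincreasing), `scores` (training, n x n_pc) and
#'   `patch_names`.
#' @export
fit_spectral_basis <- function(spectra, n_pc = 6, grid = NULL) {
  sp <- .as_spectra_matrix(spectra, grid)
  X <- sp$values
  n <- nrow(X)
  if (n < n_pc + 1)
    stop("need at least n_pc + 1 spectra to fit the basis")
  if (n_pc > min(n - 1, ncol(X)))
    stop("n_pc exceeds min(n_samples - 1, n_bands)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  evr_all <- sv$d^2 / sum(sv$d^2)
  V <- sv$v[, seq_len(n_pc), drop = FALSE]          # bands x n_pc
  flip <- vapply(seq_len(n_pc), function(j) {
    col <- V[, j]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  V <- sweep(V, 2, flip, `*`)
  scores <- Xc %*% V                                 # n x n_pc
  structure(list(grid = sp$grid,
                 mean_spectrum = mu,
                 loadings = t(V),
                 explained_variance_ratio = evr_all[seq_len(n_pc)],
                 scores = scores,
                 patch_names = rownames(X)),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> %d PCs x %d bands; cumulative variance %.4f%%\n",
              nrow(x$loadings), ncol(x$loadings),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Fit the XYZ-feature-to-score transformation matrix
#'
#' Least-squares fit of the matrix `M` mapping polynomial features of
#' corrected camera XYZ to the basis's training PC scores:
#' `M = t(Score) %*% pinv(t(features))`, pseudoinverse by SVD. The paired
#' `corrected_xyz` rows must correspond 1:1 to the spectra the basis was
#' fitted on.
#'
#' @param basis A [fit_spectral_basis()] result.
#' @param corrected_xyz n x 3 matrix of corrected camera XYZ, paired with the
#'   basis training spectra.
#' @param expansion A [feature_expansion()] (order 3 by default, mirroring the
#'   camera correction).
#' @return An object of class `transformation_model`: `basis`, `expansion`,
#'   `M` (n_pc x n_terms), `score` (training scores) and `fit_rmse` (score
#'   residual RMSE).
#' @export
fit_transformation_matrix <- function(basis, corrected_xyz,
                                      expansion = feature_expansion(3)) {
  stopifnot(inherits(basis, "spectral_basis"))
  xyz <- .as_triplet_matrix(corrected_xyz, "corrected XYZ")
  if (nrow(xyz) != nrow(basis$scores))
    stop("corrected_xyz must pair 1:1 with the basis training spectra")
  feats <- expand_features(xyz, expansion)
  Mt <- .pinv(feats) %*% basis$scores               # n_terms x n_pc
  fitted <- feats %*% Mt
  structure(list(basis = basis, expansion = expansion, M = t(Mt),
                 score = basis$scores,
                 fit_rmse = sqrt(mean((fitted - basis$scores)^2))),
            class = "transformation_model")
}

#' @export
print.transformation_model <- function(x, ...) {
  cat(sprintf("<transformation_model> %d PCs x %d terms; score RMSE %.4g\n",
              nrow(x$M), ncol(x$M), x$fit_rmse))
  invisible(x)
}

# scores -> spectra matrix (rows), mean added back
.scores_to_spectra <- function(model, scores, clip = TRUE) {
  out <- sweep(scores %*% model$basis$loadings, 2, -model$basis$mean_spectrum)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Reconstruct a reflectance spectrum from a corrected colour
#'
#' Computes PC scores as `M x features(xyz)` and the spectrum as
#' `mean + scores' x loadings`, clipped to `[0, 1]`.
#'
#' @param model A [fit_transformation_matrix()] result.
#' @param xyz Length-3 vector or n x 3 matrix of corrected XYZ.
#' @param clip Clip the reconstruction to `[0, 1]` (default TRUE).
#' @return A [reflectance_spectrum()] for a single colour, otherwise an
#'   n x n_bands matrix.
#' @export
reconstruct_reflectance <- function(model, xyz, clip = TRUE) {
  stopifnot(inherits(model, "transformation_model"))
  m <- .as_triplet_matrix(xyz, "XYZ")
  if (any(!is.finite(m))) stop("XYZ must be finite")
  scores <- expand_features(m, model$expansion) %*% t(model$M)
  out <- .scores_to_spectra(model, scores, clip = clip)
  if (!is.matrix(xyz)) {
    if (clip) reflectance_spectrum(out[1, ], model$basis$grid)
    else structure(list(values = out[1, ], grid = model$basis$grid),
                   class = "reflectance_spectrum")
  } else out
}

#' Hyperspectral reflectance cube
#'
#' @param values H x W x B numeric array of reflectances; clipped to `[0, 1]`.
#' @param grid A [spectral_grid()] with B bands.
#' @return An object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(values, grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be an H x W x B array")
  if (dim(values)[3] != n_bands(grid))
    stop("band count must equal the grid length")
  if (any(!is.finite(values))) stop("cube values must be finite")
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, grid = grid), class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyperspectral_cube> %d x %d pixels x %d bands\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# coerce an image argument to an H x W x 3 array in [0, 1]
.as_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("`image` must be an H x W x 3 array")
  if (any(dim(image)[1:2] == 0)) stop("zero-size image")
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) > 1 + 1e-9) image <- image / 255   # 8-bit integer input
  .check_unit_range(image, "image")
  image
}

#' Convert an sRGB image to a hyperspectral reflectance cube
#'
#' Per-pixel chain: sRGB decode, primary matrix to XYZ, polynomial camera
#' correction, transformation matrix to PC scores, spectral reconstruction.
#' Fully vectorized; identical to the per-pixel loop to numerical precision.
#'
#' @param image H x W x 3 sRGB array in `[0, 1]` (or 8-bit integers 0--255).
#' @param correction A [fit_correction_model()] result.
#' @param model A [fit_transformation_matrix()] result.
#' @return A [hyperspectral_cube()] on the model's grid.
#' @export
rgb_image_to_cube <- function(image, correction, model) {
  stopifnot(inherits(correction, "correction_model"),
            inherits(model, "transformation_model"))
  image <- .as_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- matrix(image, ncol = 3)                     # column-major pixel list
  xyz <- linear_rgb_to_xyz(srgb_to_linear_rgb(px))
  xyz_c <- apply_correction(correction, xyz)
  spectra <- reconstruct_reflectance(model, xyz_c)
  hyperspectral_cube(array(spectra, dim = c(h, w, ncol(spectra))),
                     model$basis$grid)
}
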