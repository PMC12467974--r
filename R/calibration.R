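# Variable-matrix camera correction: polynomial feature expansion of camera
# XYZ and a pseudoinverse least-squares fit to spectrometer-reference XYZ.

# exponent triples (X, Y, Z) in the fixed canonical ordering; order 3 gives
# the full 20-term set, lower orders are prefixes
.expansion_exponents <- function(order) {
  e <- rbind(
    c(0, 0, 0),
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
    c(3, 0, 0), c(0, 3, 0), c(0, 0, 3),
    c(2, 1, 0), c(2, 0, 1), c(1, 2, 0), c(0, 2, 1),
    c(1, 0, 2), c(0, 1, 2), c(1, 1, 1))
  n <- c(`1` = 4, `2` = 10, `3` = 20)[[as.character(order)]]
  e[seq_len(n), , drop = FALSE]
}

.term_label <- function(ex) {
  if (all(ex == 0)) return("1")
  parts <- mapply(function(v, p) {
    if (p == 0) "" else if (p == 1) v else paste0(v, "^", p)
  }, c("X", "Y", "Z"), ex)
  paste(parts[nzchar(parts)], collapse = "*")
}

#' Polynomial feature expansion of tristimulus values
#'
#' Defines the fixed, ordered monomial set used by both the camera correction
#' and the spectral transformation matrix. For `order = 3` the 20 terms are
#' `1, X, Y, Z, X^2, Y^2, Z^2, XY, XZ, YZ, X^3, Y^3, Z^3, X^2Y, X^2Z, XY^2,`
#' `Y^2Z, XZ^2, YZ^2, XYZ`; orders 1 and 2 are the leading 4 and 10 terms.
#' The constant term doubles as the dark-current offset whose coefficient is
#' learned during fitting.
#'
#' @param order Integer 1, 2 or 3.
#' @return An object of class `feature_expansion` with fields `order`,
#'   `exponents` (n_terms x 3) and `terms` (labels).
#' @export
feature_expansion <- function(order = 3) {
  if (!length(order) == 1 || !order %in% 1:3)
    stop("`order` must be 1, 2 or 3")
  ex <- .expansion_exponents(order)
  structure(list(order = as.integer(order), exponents = ex,
                 terms = apply(ex, 1, .term_label)),
            class = "feature_expansion")
}

#' @export
print.feature_expansion <- function(x, ...) {
  cat(sprintf("<feature_expansion> order %d, %d terms: %s\n", x$order,
              length(x$terms), paste(x$terms, collapse = ", ")))
  invisible(x)
}

#' Evaluate polynomial features of XYZ colours
#'
#' @param xyz Length-3 vector or n x 3 matrix of tristimulus values.
#' @param expansion A [feature_expansion()].
#' @return n x n_terms feature matrix (a vector input gives a 1-row matrix).
#' @examples
#' expand_features(c(2, 0, 0), feature_expansion(3))
#' @export
expand_features <- function(xyz, expansion = feature_expansion(3)) {
  stopifnot(inherits(expansion, "feature_expansion"))
  m <- .as_triplet_matrix(xyz, "XYZ")
  if (any(!is.finite(m))) stop("XYZ must be finite")
  ex <- expansion$exponents
  out <- sapply(seq_len(nrow(ex)), function(j)
    m[, 1]^ex[j, 1] * m[, 2]^ex[j, 2] * m[, 3]^ex[j, 3])
  out <- matrix(out, nrow = nrow(m), dimnames = list(NULL, expansion$terms))
  out
}

# Moore-Penrose pseudoinverse via SVD, relative singular-value cutoff
.pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit the variable-matrix camera correction
#'
#' Least-squares fit of a 3 x n_terms matrix `C` mapping polynomial features
#' of camera XYZ to spectrometer-reference XYZ:
#' `C = t(reference) %*% pinv(t(features))`, with the pseudoinverse computed
#' by SVD at a relative cutoff of 1e-10. The canonical input is the 24-patch
#' colour checker.
#'
#' @param camera_xyz n x 3 matrix of camera-side tristimulus values.
#' @param reference_xyz n x 3 matrix of reference tristimulus values, paired
#'   row-wise with `camera_xyz`.
#' @param expansion A [feature_expansion()]; order 3 (20 terms) by default.
#' @param white White point used for the CIEDE2000 fit report.
#' @return An object of class `correction_model` with fields `expansion`, `C`
#'   (3 x n_terms) and `fit_report` (per-sample CIEDE2000 before/after, XYZ
#'   residual RMSE, notes).
#' @export
fit_correction_model <- function(camera_xyz, reference_xyz,
                                 expansion = feature_expansion(3),
                                 white = d65_white_xyz()) {
  cam <- .as_triplet_matrix(camera_xyz, "camera XYZ")
  ref <- .as_triplet_matrix(reference_xyz, "reference XYZ")
  if (nrow(cam) != nrow(ref))
    stop("camera and reference lists must have equal length")
  if (nrow(cam) < 4)
    stop("under-determined: at least 4 paired samples are required")
  if (any(!is.finite(cam)) || any(!is.finite(ref)))
    stop("tristimulus inputs must be finite")
  feats <- expand_features(cam, expansion)
  notes <- character(0)
  if (qr(feats)$rank < min(dim(feats)))
    notes <- c(notes, sprintf("rank-deficient feature matrix (rank %d of %d)",
                              qr(feats)$rank, min(dim(feats))))
  Ct <- .pinv(feats) %*% ref                       # n_terms x 3
  C <- t(Ct)
  dimnames(C) <- list(c("X", "Y", "Z"), expansion$terms)
  fitted <- feats %*% Ct
  lab_ref <- xyz_to_lab(ref, white)
  report <- list(
    de2000_pre = ciede2000(xyz_to_lab(cam, white), lab_ref),
    de2000_post = ciede2000(xyz_to_lab(fitted, white), lab_ref),
    rmse = sqrt(mean((fitted - ref)^2)),
    notes = notes)
  structure(list(expansion = expansion, C = C, fit_report = report),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> order %d (%d terms); training RMSE %.4g; mean dE00 %.3f -> %.3f\n",
    x$expansion$order, ncol(x$C), x$fit_report$rmse,
    mean(x$fit_report$de2000_pre), mean(x$fit_report$de2000_post)))
  invisible(x)
}

#' Apply a fitted camera correction
#'
#' Deterministic matrix-vector product of the learned matrix `C` with the
#' expanded features of the input colours.
#'
#' @param model A [fit_correction_model()] result.
#' @param xyz Length-3 vector or n x 3 matrix.
#' @return Corrected XYZ, same shape convention as the input.
#' @export
apply_correction <- function(model, xyz) {
  stopifnot(inherits(model, "correction_model"))
  m <- .as_triplet_matrix(xyz, "XYZ")
  if (any(!is.finite(m))) stop("XYZ must be finite")
  .restore_shape(expand_features(m, model$expansion) %*% t(model$C), xyz,
                 c("X", "Y", "Z"))
}
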