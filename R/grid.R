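#' Wavelength grid for spectral data
#'
#' A uniformly spaced, strictly increasing wavelength axis shared by all
#' spectral objects in the package. Storage runs over the full grid (default
#' 400--780 nm in 10 nm steps, 39 bands, so that the 600/700/780 nm auxiliary
#' narrow bands are representable), while tristimulus integration is
#' restricted to `integration_window` (default 400--700 nm).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing
#'   with a uniform step.
#' @param integration_window Length-2 numeric vector; both endpoints must lie
#'   on the grid. XYZ integrals run over this window only.
#' @return An object of class `spectral_grid`.
#' @examples
#' g <- spectral_grid()
#' n_bands(g)
#' @export
spectral_grid <- function(wavelengths = seq(400, 780, by = 10),
                          integration_window = c(400, 700)) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2 || anyNA(wavelengths))
    stop("`wavelengths` must be a numeric vector of length >= 2 with no NA")
  d <- diff(wavelengths)
  if (any(d <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (diff(range(d)) > 1e-9 * mean(d))
    stop("`wavelengths` must be uniformly spaced")
  integration_window <- as.numeric(integration_window)
  if (length(integration_window) != 2 ||
      integration_window[1] >= integration_window[2])
    stop("`integration_window` must be an increasing pair of wavelengths")
  on_grid <- vapply(integration_window,
                    function(w) any(abs(wavelengths - w) < 1e-9), logical(1))
  if (!all(on_grid))
    stop("`integration_window` endpoints must lie on the grid")
  structure(list(wavelengths = wavelengths,
                 integration_window = integration_window),
            class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g nm, step %g nm (%d bands); XYZ window %g-%g nm\n",
              min(x$wavelengths), max(x$wavelengths), diff(x$wavelengths[1:2]),
              length(x$wavelengths),
              x$integration_window[1], x$integration_window[2]))
  invisible(x)
}

#' Number of bands of a spectral grid
#' @param grid A `spectral_grid`.
#' @return Integer number of wavelengths.
#' @export
n_bands <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  length(grid$wavelengths)
}

# TRUE when two grids share wavelengths (window may differ for illuminants
# reused across renderers; wavelengths are what integration aligns on)
grids_match <- function(a, b) {
  inherits(a, "spectral_grid") && inherits(b, "spectral_grid") &&
    length(a$wavelengths) == length(b$wavelengths) &&
    all(abs(a$wavelengths - b$wavelengths) < 1e-9)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_match(a, b))
    stop("spectral grids do not match", call. = FALSE)
  invisible(TRUE)
}

window_index <- function(grid) {
  which(grid$wavelengths >= grid$integration_window[1] - 1e-9 &
          grid$wavelengths <= grid$integration_window[2] + 1e-9)
}

#' Single reflectance spectrum
#'
#' Per-wavelength reflectance in `[0, 1]` on a shared grid. Values outside the
#' unit interval are clipped; the number of clipped entries is stored in the
#' `"n_clipped"` attribute.
#'
#' @param values Numeric vector, one reflectance per grid wavelength.
#' @param grid A [spectral_grid()].
#' @return An object of class `reflectance_spectrum` with fields `values` and
#'   `grid`.
#' @export
reflectance_spectrum <- function(values, grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  values <- as.numeric(values)
  if (length(values) != n_bands(grid))
    stop("`values` length must equal the number of grid bands")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  n_clipped <- sum(values < 0 | values > 1)
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, grid = grid),
            n_clipped = n_clipped, class = "reflectance_spectrum")
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d bands, range [%.4f, %.4f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Spectral power distribution of an illuminant
#'
#' @param power Nonnegative relative spectral power per grid wavelength.
#' @param grid A [spectral_grid()].
#' @param name Optional label.
#' @return An object of class `illuminant`.
#' @export
illuminant <- function(power, grid, name = "custom") {
  stopifnot(inherits(grid, "spectral_grid"))
  power <- as.numeric(power)
  if (length(power) != n_bands(grid))
    stop("`power` length must equal the number of grid bands")
  if (any(!is.finite(power)) || any(power < 0))
    stop("`power` must be finite and nonnegative")
  structure(list(power = power, grid = grid, name = name),
            class = "illuminant")
}

#' @export
print.illuminant <- function(x, ...) {
  cat(sprintf("<illuminant> %s, %d bands\n", x$name, length(x$power)))
  invisible(x)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "savehsi")
  if (!nzchar(p)) stop("bundled table not found: ", file)
  p
}

# linear interpolation of a bundled table column onto a working grid
resample_to_grid <- function(wl_table, values, grid) {
  wl <- grid$wavelengths
  if (min(wl) < min(wl_table) - 1e-9 || max(wl) > max(wl_table) + 1e-9)
    stop("grid extends beyond the bundled table's wavelength range")
  stats::approx(wl_table, values, xout = wl, rule = 1)$y
}

#' CIE 1931 2-degree colour matching functions
#'
#' Bundled 10 nm tabulation of the standard observer, resampled onto the
#' working grid by linear interpolation.
#'
#' @param grid A [spectral_grid()].
#' @return An object of class `save_cmf` with fields `grid`, `xbar`, `ybar`,
#'   `zbar`.
#' @export
cmf_cie1931 <- function(grid = spectral_grid()) {
  tab <- utils::read.csv(extdata_path("cie1931_2deg_10nm.csv"))
  structure(list(grid = grid,
                 xbar = resample_to_grid(tab$wavelength_nm, tab$xbar, grid),
                 ybar = resample_to_grid(tab$wavelength_nm, tab$ybar, grid),
                 zbar = resample_to_grid(tab$wavelength_nm, tab$zbar, grid)),
            class = "save_cmf")
}

#' Standard illuminants on a working grid
#'
#' `illuminant_d65()` resamples the bundled CIE D65 relative spectral power
#' table; `illuminant_equal_energy()` is the flat (E) illuminant.
#'
#' @param grid A [spectral_grid()].
#' @return An [illuminant()].
#' @export
illuminant_d65 <- function(grid = spectral_grid()) {
  tab <- utils::read.csv(extdata_path("illuminant_d65_10nm.csv"))
  illuminant(resample_to_grid(tab$wavelength_nm, tab$power, grid), grid,
             name = "D65")
}

#' @rdname illuminant_d65
#' @export
illuminant_equal_energy <- function(grid = spectral_grid()) {
  illuminant(rep(1, n_bands(grid)), grid, name = "E")
}

# --- internal spectra-matrix helpers -------------------------------------
# Collections of spectra travel as an n x n_bands matrix with rownames;
# .as_spectra_matrix() accepts a matrix, a reflectance_spectrum, or a list of
# reflectance_spectrum objects and returns list(values, grid).
.as_spectra_matrix <- function(spectra, grid = NULL) {
  if (inherits(spectra, "reflectance_spectrum")) {
    return(list(values = matrix(spectra$values, nrow = 1),
                grid = spectra$grid))
  }
  if (is.list(spectra) && length(spectra) &&
      all(vapply(spectra, inherits, logical(1), "reflectance_spectrum"))) {
    g <- spectra[[1]]$grid
    for (s in spectra) stop_if_grid_mismatch(s$grid, g)
    v <- do.call(rbind, lapply(spectra, `[[`, "values"))
    rownames(v) <- names(spectra)
    return(list(values = v, grid = g))
  }
  if (is.matrix(spectra)) {
    g <- if (!is.null(grid)) grid else attr(spectra, "grid")
    if (is.null(g))
      stop("a spectra matrix needs a `grid` (argument or attribute)")
    if (ncol(spectra) != n_bands(g))
      stop("spectra matrix must have one column per grid band")
    return(list(values = spectra, grid = g))
  }
  if (is.numeric(spectra) && !is.null(grid)) {
    return(list(values = matrix(spectra, nrow = 1), grid = grid))
  }
  stop("cannot interpret `spectra` as reflectance spectra")
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
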