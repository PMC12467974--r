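# File I/O: images, ENVI/TIFF hyperspectral cubes, model JSON serialization,
# spectra CSV, dataset manifests, quality-report output.

#' Read an sRGB image
#'
#' PNG and TIFF are read natively; JPEG is read through EBImage when that
#' package is installed. Images are returned as H x W x 3 arrays in `[0, 1]`
#' (alpha dropped, grayscale replicated).
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package; convert to PNG/TIFF")
      aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
    },
    stop("unsupported image format: ", ext))
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write an sRGB image
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output path; format chosen by extension (png or tif/tiff).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8),
    stop("unsupported output image format: ", ext))
  invisible(path)
}

# --- ENVI BSQ cubes -------------------------------------------------------

#' Write a hyperspectral cube as ENVI BSQ
#'
#' 32-bit little-endian floats, band-sequential, with the wavelength list in
#' the text header. Writes `<path>` (data) and `<path>.hdr`.
#'
#' @param cube A [hyperspectral_cube()].
#' @param path Data file path (conventionally `.bsq` or `.dat`).
#' @return The path, invisibly.
#' @export
write_cube_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {reflectance cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$grid$wavelengths, trim = TRUE),
                  collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$values[, , b])), con, size = 4,
             endian = "little")
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*([0-9]+)"), txt))[[1]]
    if (length(m) < 2) stop("malformed ENVI header: missing ", key)
    as.integer(m[2])
  }
  m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(m) < 2) stop("malformed ENVI header: missing wavelength list")
  wl <- as.numeric(trimws(strsplit(m[2], ",")[[1]]))
  interleave <- regmatches(txt,
    regexec("interleave\\s*=\\s*(\\w+)", txt))[[1]][2]
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       interleave = tolower(interleave), wavelengths = wl)
}

#' Read an ENVI BSQ hyperspectral cube
#'
#' @param path Data file path; the header is expected at `<path>.hdr`.
#' @param integration_window Optional window passed to the reconstructed
#'   grid; defaults to the stored wavelength range clipped to 400--700 nm
#'   when representable.
#' @return A [hyperspectral_cube()].
#' @export
read_cube_envi <- function(path, integration_window = NULL) {
  h <- .parse_envi_header(paste0(path, ".hdr"))
  if (h$data_type != 4) stop("format error: only data type 4 (float32) is supported")
  if (h$interleave != "bsq") stop("format error: only BSQ interleave is supported")
  if (length(h$wavelengths) != h$bands)
    stop("format error: header wavelength list length differs from band count")
  if (is.null(integration_window)) {
    wl <- h$wavelengths
    lo <- wl[wl >= 400][1]
    hi <- rev(wl[wl <= 700])[1]
    integration_window <- if (!is.na(lo) && !is.na(hi) && lo < hi)
      c(lo, hi) else range(wl)
  }
  grid <- spectral_grid(h$wavelengths, integration_window)
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(raw_vals) != n) stop("format error: truncated ENVI data file")
  vals <- array(NA_real_, dim = c(h$lines, h$samples, h$bands))
  per_band <- h$samples * h$lines
  for (b in seq_len(h$bands)) {
    block <- raw_vals[((b - 1) * per_band + 1):(b * per_band)]
    vals[, , b] <- t(matrix(block, nrow = h$samples))
  }
  hyperspectral_cube(vals, grid)
}

#' Write / read a hyperspectral cube as multi-band float TIFF
#'
#' One 32-bit float directory per band. TIFF stores no wavelength metadata,
#' so reading requires the grid.
#'
#' @param cube A [hyperspectral_cube()].
#' @param path TIFF file path.
#' @param grid The cube's [spectral_grid()] (read side).
#' @return The path (write) or a [hyperspectral_cube()] (read).
#' @export
write_cube_tiff <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  d <- dim(cube$values)
  pages <- lapply(seq_len(d[3]), function(b) cube$values[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_cube_tiff
#' @export
read_cube_tiff <- function(path, grid) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_bands(grid))
    stop("format error: band count differs from grid length")
  vals <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  hyperspectral_cube(vals, grid)
}

# --- model JSON -----------------------------------------------------------

#' Serialize a fitted SAVE model to JSON
#'
#' One file holds the correction matrix, the spectral basis and
#' transformation matrix, and the NBI band model. Numeric values are written
#' at full precision so the round trip is exact.
#'
#' @param model A `save_model` (see [save_calibrate()]).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_save_model <- function(model, path) {
  stopifnot(inherits(model, "save_model"))
  tr <- model$transformation
  obj <- list(
    format = "savehsi-model",
    version = 1L,
    grid = list(wavelengths = model$grid$wavelengths,
                integration_window = model$grid$integration_window),
    correction = list(
      order = model$correction$expansion$order,
      terms = model$correction$expansion$terms,
      C = as.vector(t(model$correction$C)),   # row-major
      fit_report = model$correction$fit_report),
    transformation = list(
      order = tr$expansion$order,
      mean_spectrum = tr$basis$mean_spectrum,
      loadings = as.vector(t(tr$basis$loadings)),
      n_pc = nrow(tr$basis$loadings),
      explained_variance_ratio = tr$basis$explained_variance_ratio,
      patch_names = tr$basis$patch_names,
      M = as.vector(t(tr$M)),
      score = as.vector(t(tr$score)),
      fit_rmse = tr$fit_rmse),
    nbi = list(
      bands = lapply(model$nbi$bands, function(b)
        list(center = b$center, fwhm = b$fwhm, weight = b$weight)),
      display_map = model$nbi$display_map,
      objective_value = model$nbi$objective_value))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a SAVE model from JSON
#'
#' @param path JSON path written by [write_save_model()].
#' @return A `save_model`.
#' @export
read_save_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "savehsi-model"))
    stop("not a savehsi model file")
  grid <- spectral_grid(obj$grid$wavelengths, obj$grid$integration_window)
  expansion <- feature_expansion(obj$correction$order)
  n_terms <- length(expansion$terms)
  C <- matrix(obj$correction$C, nrow = 3, byrow = TRUE,
              dimnames = list(c("X", "Y", "Z"), expansion$terms))
  fr <- obj$correction$fit_report
  fr$notes <- as.character(fr$notes)
  correction <- structure(list(expansion = expansion, C = C,
                               fit_report = fr),
                          class = "correction_model")
  tr <- obj$transformation
  n_pc <- tr$n_pc
  loadings <- matrix(tr$loadings, nrow = n_pc, byrow = TRUE)
  score <- matrix(tr$score, ncol = n_pc, byrow = TRUE)
  basis <- structure(list(grid = grid, mean_spectrum = tr$mean_spectrum,
                          loadings = loadings,
                          explained_variance_ratio =
                            tr$explained_variance_ratio,
                          scores = score,
                          patch_names = tr$patch_names),
                     class = "spectral_basis")
  texp <- feature_expansion(tr$order)
  transformation <- structure(
    list(basis = basis, expansion = texp,
         M = matrix(tr$M, nrow = n_pc, byrow = TRUE),
         score = score, fit_rmse = tr$fit_rmse),
    class = "transformation_model")
  bands <- lapply(obj$nbi$bands, function(b)
    nbi_band(b$center, b$fwhm, b$weight))
  display_map <- lapply(obj$nbi$display_map, function(ch) as.character(ch))
  nbi <- nbi_model(bands, display_map)
  nbi$objective_value <- if (is.null(obj$nbi$objective_value)) NA_real_
    else obj$nbi$objective_value
  structure(list(correction = correction, transformation = transformation,
                 nbi = nbi, grid = grid),
            class = "save_model")
}

# --- spectra CSV ----------------------------------------------------------

#' Read reflectance spectra from CSV
#'
#' Expects a `wavelength_nm` column plus one column per spectrum, values in
#' `[0, 1]`.
#'
#' @param path CSV path.
#' @param integration_window Window for the grid; clamped to the table's
#'   wavelength range and snapped to grid points.
#' @return n x n_bands matrix with a `grid` attribute and spectrum row names.
#' @export
read_spectra_csv <- function(path, integration_window = c(400, 700)) {
  tab <- utils::read.csv(path)
  if (!"wavelength_nm" %in% names(tab))
    stop("spectra CSV needs a wavelength_nm column")
  wl <- tab$wavelength_nm
  snap <- function(w) wl[which.min(abs(wl - w))]
  win <- c(snap(max(min(wl), integration_window[1])),
           snap(min(max(wl), integration_window[2])))
  if (win[1] >= win[2]) win <- range(wl)
  grid <- spectral_grid(wl, win)
  nm <- setdiff(names(tab), "wavelength_nm")
  vals <- t(as.matrix(tab[, nm, drop = FALSE]))
  rownames(vals) <- nm
  attr(vals, "grid") <- grid
  vals
}

#' Write reflectance spectra to CSV
#'
#' @param spectra Spectra matrix (with grid attribute) or list of
#'   [reflectance_spectrum()].
#' @param path Output CSV path.
#' @param grid Optional grid for bare matrices.
#' @return The path, invisibly.
#' @export
write_spectra_csv <- function(spectra, path, grid = NULL) {
  sp <- .as_spectra_matrix(spectra, grid)
  nm <- rownames(sp$values)
  if (is.null(nm)) nm <- paste0("spectrum_", seq_len(nrow(sp$values)))
  out <- data.frame(wavelength_nm = sp$grid$wavelengths, t(sp$values))
  names(out) <- c("wavelength_nm", nm)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# --- dataset manifest -----------------------------------------------------

#' Read a dataset manifest
#'
#' CSV with columns `class_name`, `split` (train/validation/test) and
#' `count`.
#'
#' @param path CSV path.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(man)
}

#' Validate a dataset manifest
#'
#' @param manifest Data frame with `class_name`, `split`, `count`.
#' @return The manifest, invisibly checked.
#' @export
validate_manifest <- function(manifest) {
  need <- c("class_name", "split", "count")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (!all(manifest$split %in% c("train", "validation", "test")))
    stop("split must be one of train, validation, test")
  if (any(!is.finite(manifest$count)) || any(manifest$count < 0))
    stop("counts must be nonnegative")
  dup <- duplicated(manifest[, c("class_name", "split")])
  if (any(dup)) stop("class names must be unique within each split")
  manifest
}

#' Summarize a dataset manifest
#'
#' Exact integer totals per split, per class, and overall.
#'
#' @param manifest A manifest data frame (see [read_manifest()]).
#' @return List with `split_totals`, `class_totals`, `grand_total` and a
#'   `table` (classes x splits with margins).
#' @export
summarize_manifest <- function(manifest) {
  validate_manifest(manifest)
  splits <- c("train", "validation", "test")
  if (nrow(manifest) == 0) {
    return(list(split_totals = stats::setNames(rep(0L, 3), splits),
                class_totals = integer(0), grand_total = 0L,
                table = NULL))
  }
  split_totals <- vapply(splits, function(s)
    sum(manifest$count[manifest$split == s]), numeric(1))
  class_totals <- tapply(manifest$count, manifest$class_name, sum)
  tab <- stats::xtabs(count ~ class_name + split, data = manifest)
  # per-class margins must equal the sum of their splits by construction;
  # recompute both ways as a consistency check
  stopifnot(all(abs(rowSums(tab)[names(class_totals)] - class_totals) < 1e-9))
  list(split_totals = split_totals,
       class_totals = class_totals[unique(manifest$class_name)],
       grand_total = sum(manifest$count),
       table = stats::addmargins(tab))
}

#' Bundled dataset manifest of the published 6490-image benchmark
#'
#' The printed class-by-split counts of the eight-category endoscopy
#' benchmark, shipped as a CSV fixture.
#'
#' @return Manifest data frame.
#' @export
kvasir_manifest <- function() {
  read_manifest(extdata_path("kvasir_v2_manifest.csv"))
}

#' Write a quality report as JSON (and optionally CSV)
#'
#' @param report A [quality_report()].
#' @param json_path Output JSON path.
#' @param csv_path Optional CSV path for the scalar metrics.
#' @return `json_path`, invisibly.
#' @export
write_quality_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "quality_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  if (!is.null(csv_path)) {
    scalars <- Filter(function(v) is.numeric(v) && length(v) == 1,
                      unclass(report))
    utils::write.csv(data.frame(metric = names(scalars),
                                value = unlist(scalars)),
                     csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
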