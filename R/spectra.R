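# Chromophore extinction spectra, Beer's-law synthesis and unmixing.

#' Construct a chromophore extinction spectrum
#'
#' A spectrum holds the absorption coefficient (mm^-1) of a chromophore at
#' unit concentration on a strictly ascending wavelength grid. For water and
#' lipid, unit concentration is volume fraction 1.0 and reported
#' concentrations are in percent; for the hemoglobins the unit is micromolar.
#'
#' @param name chromophore label, one of `"water"`, `"lipid"`,
#'   `"oxyhemoglobin"`, `"deoxyhemoglobin"`.
#' @param wavelengths wavelength grid in nm, strictly ascending, no
#'   duplicates.
#' @param unit_absorption absorption coefficient mm^-1 at unit concentration,
#'   non-negative, same length as `wavelengths`.
#' @param conc_unit unit in which concentrations of this chromophore are
#'   reported: `"percent"` (volume-fraction percent, water/lipid) or `"uM"`
#'   (hemoglobins).
#' @param source free-text provenance recorded with the spectrum.
#' @return An object of class `chromophore_spectrum`.
#' @export
chromophore_spectrum <- function(name, wavelengths, unit_absorption,
                                 conc_unit = c("percent", "uM"),
                                 source = "unspecified") {
  conc_unit <- match.arg(conc_unit)
  wavelengths <- as.numeric(wavelengths)
  unit_absorption <- as.numeric(unit_absorption)
  if (length(wavelengths) != length(unit_absorption))
    stop("wavelengths and unit_absorption must have equal length")
  if (anyDuplicated(wavelengths) || is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly ascending with no duplicates")
  if (any(!is.finite(unit_absorption)) || any(unit_absorption < 0))
    stop("unit_absorption must be finite and >= 0 everywhere")
  structure(
    list(name = name, wavelengths = wavelengths,
         unit_absorption = unit_absorption, conc_unit = conc_unit,
         source = source),
    class = "chromophore_spectrum")
}

#' @export
print.chromophore_spectrum <- function(x, ...) {
  cat(sprintf("<chromophore_spectrum> %s: %d points, %.0f-%.0f nm, unit %s\n",
              x$name, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), x$conc_unit))
  invisible(x)
}

#' Load a packaged chromophore extinction spectrum
#'
#' Reads one of the extinction-spectrum fixtures shipped with the package
#' (650-1000 nm at 1-nm spacing). The packaged spectra are smooth synthetic
#' approximations anchored at standard literature magnitudes; see the CSV
#' headers for details.
#'
#' @param name `"water"`, `"lipid"`, `"oxyhemoglobin"` or
#'   `"deoxyhemoglobin"`.
#' @param path optional path to a CSV with columns `wavelength_nm`, `value`
#'   (comment lines starting with `#` allowed) to load instead of the
#'   packaged fixture.
#' @return A [chromophore_spectrum()].
#' @export
load_chromophore <- function(name = c("water", "lipid", "oxyhemoglobin",
                                      "deoxyhemoglobin"),
                             path = NULL) {
  name <- match.arg(name)
  if (is.null(path)) {
    file <- paste0(name, "_synthetic.csv")
    path <- system.file("extdata", file, package = "sfdimap")
    if (!nzchar(path)) stop("packaged spectrum not found: ", file)
  }
  hdr <- readLines(path, n = 20L)
  src <- paste(sub("^#\\s*", "", grep("^#", hdr, value = TRUE)),
               collapse = " ")
  d <- utils::read.csv(path, comment.char = "#")
  unit <- if (name %in% c("water", "lipid")) "percent" else "uM"
  chromophore_spectrum(name, d$wavelength_nm, d$value, conc_unit = unit,
                       source = src)
}

#' Resample a chromophore spectrum onto a new wavelength grid
#'
#' Linear interpolation; values at wavelengths already present in the native
#' grid are unchanged. Extrapolation is refused.
#'
#' @param spectrum a [chromophore_spectrum()].
#' @param target_grid wavelengths (nm) within the support of `spectrum`.
#' @return A [chromophore_spectrum()] on `target_grid`.
#' @export
resample_spectrum <- function(spectrum, target_grid) {
  stopifnot(inherits(spectrum, "chromophore_spectrum"))
  target_grid <- as.numeric(target_grid)
  lo <- min(spectrum$wavelengths); hi <- max(spectrum$wavelengths)
  bad <- target_grid < lo | target_grid > hi
  if (any(bad))
    stop(sprintf("target wavelength %g nm outside spectrum support [%g, %g]",
                 target_grid[which(bad)[1]], lo, hi))
  v <- stats::approx(spectrum$wavelengths, spectrum$unit_absorption,
                     xout = target_grid, method = "linear")$y
  chromophore_spectrum(spectrum$name, target_grid, v,
                       conc_unit = spectrum$conc_unit,
                       source = spectrum$source)
}

#' Assemble a chromophore basis on a common wavelength grid
#'
#' Resamples the given spectra onto one grid and forms the Beer's-law design
#' matrix (wavelengths x chromophores) whose column `i` is the absorption
#' per reported concentration unit of chromophore `i` (per percent for
#' water/lipid, per uM for hemoglobins), so that
#' `mu_a = basis_matrix %*% concentrations`.
#'
#' @param spectra list of [chromophore_spectrum()] objects (distinct names).
#' @param grid common wavelength grid, nm.
#' @return An object of class `chromophore_basis` with elements `grid`,
#'   `names`, `conc_units`, `matrix`.
#' @export
chromophore_basis <- function(spectra, grid) {
  if (inherits(spectra, "chromophore_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "chromophore_spectrum")))
  nms <- vapply(spectra, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate chromophore names in basis")
  res <- lapply(spectra, resample_spectrum, target_grid = grid)
  scale <- ifelse(vapply(res, `[[`, "", "conc_unit") == "percent", 0.01, 1)
  B <- vapply(seq_along(res),
              function(i) res[[i]]$unit_absorption * scale[i],
              numeric(length(grid)))
  B <- matrix(B, nrow = length(grid), dimnames = list(NULL, nms))
  if (qr(B)$rank < ncol(B))
    stop("basis matrix is rank-deficient on the requested grid")
  structure(list(grid = as.numeric(grid), names = nms,
                 conc_units = vapply(res, `[[`, "", "conc_unit"),
                 matrix = B, spectra = res),
            class = "chromophore_basis")
}

#' @export
print.chromophore_basis <- function(x, ...) {
  cat(sprintf("<chromophore_basis> %s on %d wavelengths (%.0f-%.0f nm)\n",
              paste(x$names, collapse = ", "), length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Default water/lipid basis on a 900-1000 nm grid
#'
#' @param grid wavelength grid, nm (default 900-1000 at 1 nm).
#' @param chromophores chromophore names to include.
#' @return A [chromophore_basis()].
#' @export
default_basis <- function(grid = seq(900, 1000, by = 1),
                          chromophores = c("water", "lipid")) {
  chromophore_basis(lapply(chromophores, load_chromophore), grid)
}

#' Synthesize an absorption spectrum from concentrations (Beer's law)
#'
#' `mu_a(lambda) = sum_i c_i * eps_i(lambda)`, with `c_i` in each
#' chromophore's reported unit (percent for water/lipid, uM for
#' hemoglobins).
#'
#' @param basis a [chromophore_basis()].
#' @param conc numeric vector of concentrations, one per basis chromophore
#'   (optionally named).
#' @return Absorption spectrum, mm^-1, on `basis$grid`.
#' @export
synthesize_absorption <- function(basis, conc) {
  stopifnot(inherits(basis, "chromophore_basis"))
  if (length(conc) != ncol(basis$matrix))
    stop(sprintf("conc has length %d but basis has %d chromophores",
                 length(conc), ncol(basis$matrix)))
  if (any(!is.finite(conc))) stop("conc must be finite")
  if (!is.null(names(conc))) conc <- conc[basis$names]
  drop(basis$matrix %*% as.numeric(conc))
}

#' Fit chromophore concentrations to a measured absorption spectrum
#'
#' Least-squares Beer's-law unmixing of an absorption spectrum on the basis
#' grid. With `nonneg = TRUE` (default) the fit is non-negative least
#' squares; the unconstrained solution is available for diagnostics.
#' Non-finite absorption values are masked out provided at least as many
#' wavelengths as chromophores remain.
#'
#' @param mu_a_spectrum absorption, mm^-1, on `basis$grid`.
#' @param basis a [chromophore_basis()].
#' @param nonneg constrain concentrations to be >= 0 (default TRUE).
#' @return list with `concentrations` (named, in reported units),
#'   `residual_norm` (root-mean-square misfit, mm^-1) and `n_used`
#'   (wavelengths entering the fit).
#' @export
fit_concentrations <- function(mu_a_spectrum, basis, nonneg = TRUE) {
  stopifnot(inherits(basis, "chromophore_basis"))
  y <- as.numeric(mu_a_spectrum)
  if (length(y) != length(basis$grid))
    stop("mu_a_spectrum length does not match basis grid")
  ok <- is.finite(y)
  p <- ncol(basis$matrix)
  if (sum(ok) < p)
    stop(sprintf("only %d finite wavelengths but %d chromophores",
                 sum(ok), p))
  A <- basis$matrix[ok, , drop = FALSE]
  yy <- y[ok]
  if (qr(A)$rank < p) stop("basis matrix is rank-deficient after masking")
  if (nonneg) {
    fit <- pracma::lsqnonneg(A, yy)
    cf <- fit$x
  } else {
    cf <- qr.coef(qr(A), yy)
  }
  names(cf) <- basis$names
  resid <- yy - drop(A %*% cf)
  list(concentrations = cf,
       residual_norm = sqrt(mean(resid^2)),
       n_used = sum(ok))
}

#' Unmix a per-pixel absorption cube into chromophore concentration maps
#'
#' Vectorized Beer's-law fit across pixels: the unconstrained normal-equation
#' solution is computed for all pixels at once and pixels with any negative
#' coefficient are re-solved by non-negative least squares when
#' `nonneg = TRUE`.
#'
#' @param mu_a_cube array `[H, W, n_wavelengths]` of absorption (mm^-1),
#'   third dimension matching `basis$grid`.
#' @param basis a [chromophore_basis()].
#' @param nonneg constrain concentrations to be >= 0 (default TRUE).
#' @return list with `concentrations` (array `[H, W, n_chromophores]`,
#'   dimnames on the third axis), `residual_norm` (matrix `[H, W]`) and
#'   `n_clipped` (pixels that required the constrained solver).
#' @export
unmix_map <- function(mu_a_cube, basis, nonneg = TRUE) {
  stopifnot(inherits(basis, "chromophore_basis"))
  d <- dim(mu_a_cube)
  if (length(d) != 3 || d[3] != length(basis$grid))
    stop("mu_a_cube must be [H, W, n_wavelengths] matching the basis grid")
  A <- basis$matrix
  p <- ncol(A)
  Y <- matrix(mu_a_cube, nrow = d[1] * d[2])      # pixels x wavelengths
  P <- solve(crossprod(A), t(A))                  # p x wavelengths
  C <- Y %*% t(P)                                 # pixels x p
  n_clipped <- 0L
  if (nonneg) {
    bad <- which(rowSums(C < 0) > 0)
    n_clipped <- length(bad)
    for (i in bad) C[i, ] <- pracma::lsqnonneg(A, Y[i, ])$x
  }
  R <- Y - C %*% t(A)
  conc <- array(C, dim = c(d[1], d[2], p),
                dimnames = list(NULL, NULL, basis$names))
  list(concentrations = conc,
       residual_norm = matrix(sqrt(rowMeans(R^2)), d[1], d[2]),
       n_clipped = n_clipped)
}

#' Circular region-of-interest statistics on a concentration map
#'
#' Averages over all pixels whose centers lie within a circle of the given
#' physical diameter. If the circle is smaller than one pixel pitch the
#' single pixel nearest the center is used. NaN pixels are excluded and
#' counted.
#'
#' @param map matrix (one chromophore) or array `[H, W, n_chromophores]`
#'   with dimnames on the third axis.
#' @param center circle center, `c(row, col)` in pixel coordinates.
#' @param diameter circle diameter, mm.
#' @param pixel_pitch pixel pitch, mm/pixel, > 0.
#' @return data.frame with one row per chromophore: `chromophore`, `mean`,
#'   `sd`, `n_pixels`, `n_nan`.
#' @export
roi_average <- function(map, center, diameter, pixel_pitch) {
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (diameter <= 0) stop("diameter must be > 0")
  if (is.matrix(map)) {
    map <- array(map, dim = c(dim(map), 1L),
                 dimnames = list(NULL, NULL, "value"))
  }
  d <- dim(map)
  r_px <- (diameter / 2) / pixel_pitch
  if (center[1] - r_px < 0.5 || center[1] + r_px > d[1] + 0.5 ||
      center[2] - r_px < 0.5 || center[2] + r_px > d[2] + 0.5)
    stop("ROI circle extends outside the image")
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  inside <- (rows - center[1])^2 + (cols - center[2])^2 <= r_px^2
  if (!any(inside)) {
    # degenerate ROI: nearest single pixel
    i <- pmin(pmax(round(center[1]), 1), d[1])
    j <- pmin(pmax(round(center[2]), 1), d[2])
    inside[i, j] <- TRUE
  }
  nms <- dimnames(map)[[3]]
  if (is.null(nms)) nms <- paste0("ch", seq_len(d[3]))
  out <- lapply(seq_len(d[3]), function(k) {
    v <- map[, , k][inside]
    nan <- !is.finite(v)
    v <- v[!nan]
    data.frame(chromophore = nms[k], mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_pixels = length(v), n_nan = sum(nan))
  })
  do.call(rbind, out)
}
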