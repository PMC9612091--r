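# Diffusion-approximation forward model of spatially modulated diffuse
# reflectance, lookup-table construction and per-pixel inversion.

#' Scalar attenuation coefficient of spatially modulated light
#'
#' `mu_eff'(fx) = sqrt(mu_eff^2 + (2 pi fx)^2)` with
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`. At `fx = 0` this reduces to
#' `mu_eff`.
#'
#' @param mu_a absorption coefficient, mm^-1 (> 0); vectorized.
#' @param mu_s_prime reduced scattering coefficient, mm^-1 (> 0).
#' @param fx spatial frequency, mm^-1 (>= 0).
#' @return mu_eff'(fx), mm^-1.
#' @export
mu_eff_prime <- function(mu_a, mu_s_prime, fx) {
  check_props(mu_a, mu_s_prime, fx)
  sqrt(3 * mu_a * (mu_a + mu_s_prime) + (2 * pi * fx)^2)
}

check_props <- function(mu_a, mu_s_prime, fx = 0) {
  if (any(!is.finite(mu_a)) || any(mu_a <= 0))
    stop("mu_a must be finite and > 0")
  if (any(!is.finite(mu_s_prime)) || any(mu_s_prime <= 0))
    stop("mu_s_prime must be finite and > 0")
  if (any(fx < 0)) stop("fx must be >= 0")
  invisible(TRUE)
}

#' Diffuse reflectance of a semi-infinite homogeneous medium under
#' spatially modulated illumination
#'
#' Closed-form diffusion-approximation forward model. With
#' `mu_tr = mu_a + mu_s'`, `a' = mu_s'/mu_tr`, and
#' `mu_eff'(fx)` from [mu_eff_prime()], the internal-reflection parameter is
#' `R_eff = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2`,
#' `A = (1 - R_eff) / (2 (1 + R_eff))`, and
#' `Rd = 3 A a' / ((mu_eff'/mu_tr + 1)(mu_eff'/mu_tr + 3A))`.
#'
#' All arguments are vectorized and recycle.
#'
#' @inheritParams mu_eff_prime
#' @param n_rel relative refractive index of the medium (default 1.4).
#' @return Diffuse reflectance in (0, 1), dimensionless.
#' @export
rd_forward <- function(mu_a, mu_s_prime, fx, n_rel = 1.4) {
  check_props(mu_a, mu_s_prime, fx)
  mu_tr <- mu_a + mu_s_prime
  a_prime <- mu_s_prime / mu_tr
  mep <- sqrt(3 * mu_a * mu_tr + (2 * pi * fx)^2) / mu_tr
  r_eff <- 0.0636 * n_rel + 0.668 + 0.710 / n_rel - 1.440 / n_rel^2
  A <- (1 - r_eff) / (2 * (1 + r_eff))
  3 * A * a_prime / ((mep + 1) * (mep + 3 * A))
}

#' Effective penetration depth of spatially modulated light
#'
#' `delta_eff'(fx) = 1 / mu_eff'(fx)`: the characteristic decay depth of the
#' modulated fluence. Strictly decreasing in `fx`, `mu_a` and `mu_s_prime`.
#'
#' @inheritParams mu_eff_prime
#' @return Depth, mm.
#' @export
effective_penetration_depth <- function(mu_a, mu_s_prime, fx) {
  1 / mu_eff_prime(mu_a, mu_s_prime, fx)
}

#' Build a reflectance lookup table over (mu_a, mu_s') for a frequency pair
#'
#' Populates Rd tables at the two spatial frequencies on a grid that is
#' logarithmically spaced in `mu_a` and linear in `mu_s'`, using
#' [rd_forward()]. An externally computed table with the same schema (e.g. a
#' photon-transport Monte Carlo table) can be swapped in via [read_lut()].
#'
#' @param mu_a_range range of mu_a, mm^-1 (default `c(0.001, 0.2)`).
#' @param mu_s_range range of mu_s', mm^-1 (default `c(0.3, 6)`).
#' @param grid_sizes grid dimensions `c(n_mu_a, n_mu_s)` (default 128, 128).
#' @param fx_pair the two spatial frequencies `c(f1, f2)`, mm^-1, distinct.
#' @param n_rel relative refractive index (default 1.4).
#' @return An object of class `reflectance_lut` with elements `mu_a_grid`,
#'   `mu_s_grid`, `fx_pair`, `rd1`, `rd2` (matrices `n_mu_a x n_mu_s`),
#'   `n_rel`, `model`.
#' @export
build_lut <- function(mu_a_range = c(0.001, 0.2), mu_s_range = c(0.3, 6),
                      grid_sizes = c(128, 128), fx_pair = c(0, 0.2),
                      n_rel = 1.4) {
  stopifnot(length(fx_pair) == 2, length(grid_sizes) == 2)
  if (any(mu_a_range <= 0) || any(mu_s_range <= 0))
    stop("mu_a_range and mu_s_range must be positive")
  if (fx_pair[1] == fx_pair[2])
    stop("degenerate frequency pair: f1 == f2 cannot be inverted")
  mu_a_grid <- exp(seq(log(mu_a_range[1]), log(mu_a_range[2]),
                       length.out = grid_sizes[1]))
  mu_s_grid <- seq(mu_s_range[1], mu_s_range[2], length.out = grid_sizes[2])
  MA <- matrix(mu_a_grid, grid_sizes[1], grid_sizes[2])
  MS <- matrix(mu_s_grid, grid_sizes[1], grid_sizes[2], byrow = TRUE)
  structure(
    list(mu_a_grid = mu_a_grid, mu_s_grid = mu_s_grid, fx_pair = fx_pair,
         rd1 = rd_forward(MA, MS, fx_pair[1], n_rel),
         rd2 = rd_forward(MA, MS, fx_pair[2], n_rel),
         n_rel = n_rel, model = "diffusion"),
    class = "reflectance_lut")
}

#' @export
print.reflectance_lut <- function(x, ...) {
  cat(sprintf(paste0("<reflectance_lut> %dx%d nodes, mu_a [%.4g, %.4g],",
                     " mu_s' [%.3g, %.3g] mm^-1, fx [%g, %g] mm^-1 (%s)\n"),
              length(x$mu_a_grid), length(x$mu_s_grid),
              min(x$mu_a_grid), max(x$mu_a_grid),
              min(x$mu_s_grid), max(x$mu_s_grid),
              x$fx_pair[1], x$fx_pair[2], x$model))
  invisible(x)
}

#' Write a reflectance LUT to disk
#'
#' Long-format CSV with columns `mu_a, mu_s_prime, f1, f2, Rd1, Rd2` plus a
#' JSON header carrying the grid specification and model provenance.
#'
#' @param lut a [build_lut()] result.
#' @param path directory to write `lut.csv` and `lut.json` into (created if
#'   needed).
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "reflectance_lut"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- expand.grid(mu_a = lut$mu_a_grid, mu_s_prime = lut$mu_s_grid)
  d <- data.frame(mu_a = g$mu_a, mu_s_prime = g$mu_s_prime,
                  f1 = lut$fx_pair[1], f2 = lut$fx_pair[2],
                  Rd1 = as.vector(lut$rd1), Rd2 = as.vector(lut$rd2))
  utils::write.csv(d, file.path(path, "lut.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_mu_a = length(lut$mu_a_grid), n_mu_s = length(lut$mu_s_grid),
         mu_a_range = range(lut$mu_a_grid), mu_s_range = range(lut$mu_s_grid),
         fx_pair = lut$fx_pair, n_rel = lut$n_rel, model = lut$model),
    file.path(path, "lut.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reflectance LUT from disk
#'
#' Accepts the schema written by [write_lut()]; an externally generated
#' table (e.g. Monte Carlo) with the same schema is usable interchangeably.
#' Imported tables are inverted through bilinear interpolation of the table
#' itself rather than the closed-form model.
#'
#' @param path directory containing `lut.csv` and `lut.json`.
#' @param model override the model tag (`"imported"` marks the table as
#'   external so inversion interpolates the table).
#' @return A `reflectance_lut`.
#' @export
read_lut <- function(path, model = NULL) {
  meta <- jsonlite::read_json(file.path(path, "lut.json"),
                              simplifyVector = TRUE)
  d <- utils::read.csv(file.path(path, "lut.csv"))
  mu_a_grid <- sort(unique(d$mu_a))
  mu_s_grid <- sort(unique(d$mu_s_prime))
  if (length(mu_a_grid) * length(mu_s_grid) != nrow(d))
    stop("lut.csv is not a complete rectangular grid")
  o <- order(d$mu_s_prime, d$mu_a)
  structure(
    list(mu_a_grid = mu_a_grid, mu_s_grid = mu_s_grid,
         fx_pair = c(d$f1[1], d$f2[1]),
         rd1 = matrix(d$Rd1[o], length(mu_a_grid), length(mu_s_grid)),
         rd2 = matrix(d$Rd2[o], length(mu_a_grid), length(mu_s_grid)),
         n_rel = meta$n_rel,
         model = if (is.null(model)) meta$model else model),
    class = "reflectance_lut")
}

# Rd evaluator at the LUT's frequency pair: closed form for diffusion-model
# tables, bilinear interpolation in (log mu_a, mu_s') for imported tables.
lut_evaluator <- function(lut) {
  if (identical(lut$model, "diffusion")) {
    function(mu_a, mu_s, which) {
      rd_forward(mu_a, mu_s, lut$fx_pair[which], lut$n_rel)
    }
  } else {
    la <- log(lut$mu_a_grid)
    ms <- lut$mu_s_grid
    function(mu_a, mu_s, which) {
      Tm <- if (which == 1L) lut$rd1 else lut$rd2
      x <- pmin(pmax(log(mu_a), la[1]), la[length(la)])
      y <- pmin(pmax(mu_s, ms[1]), ms[length(ms)])
      i <- pmin(pmax(findInterval(x, la), 1L), length(la) - 1L)
      j <- pmin(pmax(findInterval(y, ms), 1L), length(ms) - 1L)
      tx <- (x - la[i]) / (la[i + 1L] - la[i])
      ty <- (y - ms[j]) / (ms[j + 1L] - ms[j])
      n <- length(la)
      v00 <- Tm[cbind(i, j)];       v10 <- Tm[cbind(i + 1L, j)]
      v01 <- Tm[cbind(i, j + 1L)];  v11 <- Tm[cbind(i + 1L, j + 1L)]
      (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
        (1 - tx) * ty * v01 + tx * ty * v11
    }
  }
}

# Vectorized two-frequency inversion: LUT nearest-node seed followed by
# damped Gauss-Newton root polishing in (log mu_a, log mu_s') on the
# continuous surface. Returns clamped values plus an out_of_range flag; no
# NaNs are emitted.
invert_rd <- function(rd1, rd2, lut, tol = 1e-10, max_iter = 40L,
                      clamp_input = FALSE) {
  stopifnot(inherits(lut, "reflectance_lut"))
  rd1 <- as.numeric(rd1); rd2 <- as.numeric(rd2)
  if (length(rd1) != length(rd2)) stop("rd1 and rd2 must have equal length")
  bad_in <- !is.finite(rd1) | !is.finite(rd2) |
    rd1 <= 0 | rd1 >= 1 | rd2 <= 0 | rd2 >= 1
  if (any(bad_in)) {
    if (!clamp_input)
      stop("reflectance values must lie strictly in (0, 1)")
    eps <- 1e-6
    rd1[!is.finite(rd1)] <- 1 - eps
    rd2[!is.finite(rd2)] <- 1 - eps
    rd1 <- pmin(pmax(rd1, eps), 1 - eps)
    rd2 <- pmin(pmax(rd2, eps), 1 - eps)
  }
  ev <- lut_evaluator(lut)
  n <- length(rd1)

  # seed from a coarse subsample of the LUT nodes
  ia <- unique(round(seq(1, length(lut$mu_a_grid), length.out = 32)))
  is_ <- unique(round(seq(1, length(lut$mu_s_grid), length.out = 32)))
  sa <- lut$mu_a_grid[ia]; ss <- lut$mu_s_grid[is_]
  R1 <- as.vector(lut$rd1[ia, is_]); R2 <- as.vector(lut$rd2[ia, is_])
  G <- expand.grid(a = sa, s = ss)
  u <- v <- numeric(n)
  chunk <- 4096L
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    D <- outer(rd1[st:en], R1, `-`)^2 + outer(rd2[st:en], R2, `-`)^2
    best <- max.col(-D, ties.method = "first")
    u[st:en] <- log(G$a[best]); v[st:en] <- log(G$s[best])
  }

  ulim <- log(range(lut$mu_a_grid)); vlim <- log(range(lut$mu_s_grid))
  h <- 1e-5
  for (iter in seq_len(max_iter)) {
    mu_a <- exp(u); mu_s <- exp(v)
    r1 <- ev(mu_a, mu_s, 1L) - rd1
    r2 <- ev(mu_a, mu_s, 2L) - rd2
    if (max(abs(r1), abs(r2)) < tol) break
    j11 <- (ev(mu_a * exp(h), mu_s, 1L) - ev(mu_a * exp(-h), mu_s, 1L)) / (2 * h)
    j12 <- (ev(mu_a, mu_s * exp(h), 1L) - ev(mu_a, mu_s * exp(-h), 1L)) / (2 * h)
    j21 <- (ev(mu_a * exp(h), mu_s, 2L) - ev(mu_a * exp(-h), mu_s, 2L)) / (2 * h)
    j22 <- (ev(mu_a, mu_s * exp(h), 2L) - ev(mu_a, mu_s * exp(-h), 2L)) / (2 * h)
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- 1e-300
    du <- (j22 * r1 - j12 * r2) / det
    dv <- (j11 * r2 - j21 * r1) / det
    du <- pmin(pmax(du, -0.5), 0.5)
    dv <- pmin(pmax(dv, -0.5), 0.5)
    u <- pmin(pmax(u - du, ulim[1]), ulim[2])
    v <- pmin(pmax(v - dv, vlim[1]), vlim[2])
  }
  mu_a <- exp(u); mu_s <- exp(v)
  r1 <- ev(mu_a, mu_s, 1L) - rd1
  r2 <- ev(mu_a, mu_s, 2L) - rd2
  misfit <- sqrt(r1^2 + r2^2)
  # unattainable pairs: solution pinned at the boundary or residual mismatch
  at_edge <- (u <= ulim[1] + 1e-12) | (u >= ulim[2] - 1e-12) |
             (v <= vlim[1] + 1e-12) | (v >= vlim[2] - 1e-12)
  flag <- at_edge | misfit > 1e-6 | bad_in
  list(mu_a = mu_a, mu_s_prime = mu_s, out_of_range = flag, misfit = misfit)
}

#' Invert a pair of diffuse reflectance values to optical properties
#'
#' Finds the `(mu_a, mu_s')` whose forward reflectance at the LUT's two
#' spatial frequencies matches `rd_pair`: a nearest-node LUT search seeds a
#' damped Gauss-Newton refinement on the continuous reflectance surface.
#' Reflectance pairs outside the attainable set are clamped to the nearest
#' attainable point and flagged rather than returned as NaN.
#'
#' @param rd_pair reflectance at the two frequencies, `c(Rd(f1), Rd(f2))`,
#'   both strictly in (0, 1).
#' @param lut a [build_lut()] or [read_lut()] result.
#' @return list with `mu_a`, `mu_s_prime` (mm^-1) and `out_of_range`
#'   (logical).
#' @export
invert_pixel <- function(rd_pair, lut) {
  stopifnot(length(rd_pair) == 2)
  r <- invert_rd(rd_pair[1], rd_pair[2], lut)
  list(mu_a = r$mu_a, mu_s_prime = r$mu_s_prime,
       out_of_range = r$out_of_range)
}

#' Invert reflectance maps to optical-property maps
#'
#' Applies the two-frequency inversion pixel-by-pixel for each wavelength.
#' Input maps at the two frequencies must share shape. Out-of-range pixels
#' are clamped and flagged; the per-wavelength flagged-pixel count is
#' reported once per call.
#'
#' @param rd_f1,rd_f2 matrices `[H, W]` or arrays `[H, W, n_wavelengths]` of
#'   diffuse reflectance at the LUT's first and second spatial frequency.
#' @param lut a [build_lut()] or [read_lut()] result.
#' @param wavelengths optional wavelength labels for the third dimension.
#' @param quiet suppress the flagged-pixel summary message.
#' @return An object of class `optical_property_map`: list with `mu_a`,
#'   `mu_s_prime`, `out_of_range` (same shape as the inputs),
#'   `flagged_per_wavelength`, `wavelengths`.
#' @export
invert_map <- function(rd_f1, rd_f2, lut, wavelengths = NULL, quiet = FALSE) {
  if (!identical(dim(rd_f1), dim(rd_f2)))
    stop("rd_f1 and rd_f2 must share shape")
  was_matrix <- is.matrix(rd_f1)
  d <- dim(rd_f1)
  if (was_matrix) d <- c(d, 1L)
  r <- invert_rd(rd_f1, rd_f2, lut, clamp_input = TRUE)
  mu_a <- array(r$mu_a, d); mu_s <- array(r$mu_s_prime, d)
  flag <- array(r$out_of_range, d)
  flagged <- apply(flag, 3, sum)
  if (was_matrix) {
    mu_a <- mu_a[, , 1]; mu_s <- mu_s[, , 1]; flag <- flag[, , 1]
  }
  wl <- if (is.null(wavelengths)) seq_len(d[3]) else wavelengths
  if (!quiet && sum(flagged) > 0)
    message(sprintf("invert_map: %d out-of-range pixels clamped (%s)",
                    sum(flagged),
                    paste(sprintf("%s: %d", wl[flagged > 0],
                                  flagged[flagged > 0]), collapse = ", ")))
  structure(list(mu_a = mu_a, mu_s_prime = mu_s, out_of_range = flag,
                 flagged_per_wavelength = stats::setNames(flagged, wl),
                 wavelengths = wl),
            class = "optical_property_map")
}
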