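# Cramer-Rao-bound uncertainty analysis for spatial-frequency selection.

#' Reflectance-equivalent measurement noise model
#'
#' Two-parameter noise model for calibrated diffuse reflectance:
#' `sd(fx) = sigma0 + sigma1 * Rd(fx)` (additive plus multiplicative
#' components). Instrument-specific noise must be characterized per system;
#' the defaults are a documented stand-in of plausible magnitude, so
#' downstream analyses should rely on orderings and scalings rather than
#' absolute values.
#'
#' @param sigma0 additive reflectance noise sd, dimensionless (>= 0).
#' @param sigma1 multiplicative coefficient, sd as a fraction of Rd (>= 0).
#' @param per_frequency optional data.frame with columns `fx`, `sigma0`,
#'   `sigma1` overriding the global parameters at listed frequencies.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma0 = 0.002, sigma1 = 0.01, per_frequency = NULL) {
  if (sigma0 < 0 || sigma1 < 0) stop("noise parameters must be >= 0")
  if (sigma0 == 0 && sigma1 == 0 && is.null(per_frequency))
    stop("noise model cannot be identically zero")
  if (!is.null(per_frequency))
    stopifnot(all(c("fx", "sigma0", "sigma1") %in% names(per_frequency)))
  structure(list(sigma0 = sigma0, sigma1 = sigma1,
                 per_frequency = per_frequency),
            class = "noise_model")
}

# sd of the reflectance measurement at frequency fx given predicted Rd
noise_sd <- function(noise, fx, rd) {
  s0 <- noise$sigma0; s1 <- noise$sigma1
  pf <- noise$per_frequency
  if (!is.null(pf)) {
    i <- match(fx, pf$fx)
    if (!is.na(i)) { s0 <- pf$sigma0[i]; s1 <- pf$sigma1[i] }
  }
  s0 + s1 * rd
}

# Vectorized CRB sigmas over mu_a / mu_s vectors at one frequency pair.
# Central finite differences on rd_forward; 2x2 Fisher information inverted
# in closed form.
crb_sigma_vec <- function(mu_a, mu_s, fx_pair, noise, n_rel = 1.4,
                          rel_step = 1e-4) {
  f1 <- fx_pair[1]; f2 <- fx_pair[2]
  if (f1 == f2)
    stop(sprintf("singular design: frequency pair [%g, %g] is degenerate",
                 f1, f2))
  da <- mu_a * rel_step; ds <- mu_s * rel_step
  j1a <- (rd_forward(mu_a + da, mu_s, f1, n_rel) -
          rd_forward(mu_a - da, mu_s, f1, n_rel)) / (2 * da)
  j1s <- (rd_forward(mu_a, mu_s + ds, f1, n_rel) -
          rd_forward(mu_a, mu_s - ds, f1, n_rel)) / (2 * ds)
  j2a <- (rd_forward(mu_a + da, mu_s, f2, n_rel) -
          rd_forward(mu_a - da, mu_s, f2, n_rel)) / (2 * da)
  j2s <- (rd_forward(mu_a, mu_s + ds, f2, n_rel) -
          rd_forward(mu_a, mu_s - ds, f2, n_rel)) / (2 * ds)
  s1 <- noise_sd(noise, f1, rd_forward(mu_a, mu_s, f1, n_rel))
  s2 <- noise_sd(noise, f2, rd_forward(mu_a, mu_s, f2, n_rel))
  w1 <- 1 / s1^2; w2 <- 1 / s2^2
  faa <- j1a^2 * w1 + j2a^2 * w2
  fas <- j1a * j1s * w1 + j2a * j2s * w2
  fss <- j1s^2 * w1 + j2s^2 * w2
  det <- faa * fss - fas^2
  if (any(det <= 0) || any(!is.finite(det)))
    stop(sprintf("singular Fisher information for pair [%g, %g]", f1, f2))
  list(sigma_mu_a = sqrt(fss / det), sigma_mu_s = sqrt(faa / det))
}

#' Cramer-Rao lower bound on optical-property uncertainty
#'
#' For a two-frequency SFDI measurement with reflectance noise
#' `sd(f) = sigma0 + sigma1 * Rd(f)`, builds the 2x2 Jacobian of
#' `(Rd(f1), Rd(f2))` with respect to `(mu_a, mu_s')` by central finite
#' differences on [rd_forward()], forms the Fisher information
#' `F = J' Sigma^-1 J`, and returns the square roots of the diagonal of
#' `F^-1`: the minimum achievable estimator standard deviations.
#'
#' @param mu_a,mu_s_prime optical properties, mm^-1 (vectorized).
#' @param fx_pair the two spatial frequencies `c(f1, f2)`, mm^-1, distinct.
#' @param noise a [noise_model()].
#' @param n_rel relative refractive index (default 1.4).
#' @param rel_step relative central-difference step (default 1e-4).
#' @return list with `sigma_mu_a` and `sigma_mu_s` (mm^-1).
#' @export
crb_uncertainty <- function(mu_a, mu_s_prime, fx_pair, noise = noise_model(),
                            n_rel = 1.4, rel_step = 1e-4) {
  check_props(mu_a, mu_s_prime, fx_pair)
  stopifnot(inherits(noise, "noise_model"), length(fx_pair) == 2)
  crb_sigma_vec(mu_a, mu_s_prime, fx_pair, noise, n_rel, rel_step)
}

#' Scan candidate spatial-frequency pairs across wavelengths
#'
#' Evaluates [crb_uncertainty()] for each pair at each wavelength's optical
#' properties and ranks the pairs by mean uncertainty over the wavelength
#' range.
#'
#' @param pairs list of frequency pairs, each `c(f1, f2)` mm^-1.
#' @param wavelengths wavelengths, nm.
#' @param mu_a,mu_s_prime optical-property spectra (mm^-1), one value per
#'   wavelength.
#' @param noise a [noise_model()].
#' @param n_rel relative refractive index (default 1.4).
#' @return data.frame with columns `wavelength`, `f1`, `f2`, `sigma_mu_a`,
#'   `sigma_mu_s`; attribute `summary` is a per-pair data.frame of mean
#'   sigmas sorted best-first (plot-ready, write with [utils::write.csv()]).
#' @export
scan_frequency_pairs <- function(pairs, wavelengths, mu_a, mu_s_prime,
                                 noise = noise_model(), n_rel = 1.4) {
  if (length(pairs) == 0) stop("pairs must be non-empty")
  stopifnot(length(wavelengths) == length(mu_a),
            length(wavelengths) == length(mu_s_prime))
  rows <- lapply(pairs, function(p) {
    s <- crb_uncertainty(mu_a, mu_s_prime, p, noise, n_rel)
    data.frame(wavelength = wavelengths, f1 = p[1], f2 = p[2],
               sigma_mu_a = s$sigma_mu_a, sigma_mu_s = s$sigma_mu_s)
  })
  tab <- do.call(rbind, rows)
  key <- paste0("[", tab$f1, ",", tab$f2, "]")
  agg <- stats::aggregate(cbind(sigma_mu_a, sigma_mu_s) ~ f1 + f2,
                          data = tab, FUN = mean)
  names(agg)[3:4] <- c("mean_sigma_mu_a", "mean_sigma_mu_s")
  agg <- agg[order(agg$mean_sigma_mu_a), ]
  tab$pair <- key
  attr(tab, "summary") <- agg
  tab
}
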