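# Chromophore spectra, Beer's-law synthesis and least-squares unmixing.

test_that("resampling is the identity on the native grid and linear between
           points", {
  sp <- toy_spectrum("water", c(900, 910, 920), c(0.02, 0.04, 0.03))
  same <- resample_spectrum(sp, c(900, 910, 920))
  expect_identical(same$unit_absorption, sp$unit_absorption)

  mid <- resample_spectrum(sp, 905)
  expect_equal(mid$unit_absorption, 0.03)

  expect_error(resample_spectrum(sp, 930), "outside")
})

test_that("coarse resample then re-resample agrees with direct interpolation",
          {
  water <- load_chromophore("water")
  coarse <- resample_spectrum(water, seq(900, 1000, by = 5))
  fine_grid <- seq(900, 1000, by = 1)
  twice <- resample_spectrum(coarse, fine_grid)
  # oracle: direct piecewise-linear interpolation of the coarse nodes
  direct <- approx(coarse$wavelengths, coarse$unit_absorption,
                   xout = fine_grid)$y
  expect_lt(max(abs(twice$unit_absorption - direct)), 1e-12)
})

test_that("absorption synthesis is Beer's law in reported units", {
  basis <- test_basis()
  expect_equal(synthesize_absorption(basis, c(0, 0)),
               rep(0, length(basis$grid)))

  # 100% water reproduces the unit spectrum exactly
  water <- resample_spectrum(load_chromophore("water"), basis$grid)
  expect_equal(synthesize_absorption(basis, c(water = 100, lipid = 0)),
               water$unit_absorption)

  # hand arithmetic at a single wavelength
  wl <- which(basis$grid == 930)
  a_w <- water$unit_absorption[wl]
  a_l <- resample_spectrum(load_chromophore("lipid"),
                           basis$grid)$unit_absorption[wl]
  mu <- synthesize_absorption(basis, c(water = 80, lipid = 10))
  expect_equal(mu[wl], 0.8 * a_w + 0.1 * a_l)

  expect_error(synthesize_absorption(basis, c(1, 2, 3)), "length")
})

test_that("noiseless unmixing recovers concentrations to machine precision",
          {
  basis <- test_basis()
  for (truth in list(c(water = 85, lipid = 15), c(water = 20, lipid = 75),
                     c(water = 60, lipid = 40))) {
    mu <- synthesize_absorption(basis, truth)
    for (nn in c(TRUE, FALSE)) {
      fit <- fit_concentrations(mu, basis, nonneg = nn)
      expect_equal(fit$concentrations, truth, tolerance = 1e-10)
      expect_lt(fit$residual_norm, 1e-12)
    }
  }
})

test_that("two-wavelength fit matches the closed-form 2x2 solve", {
  # frozen from an independent linear-algebra evaluation of the same
  # 2x2 system built on the packaged fixtures at 930 and 970 nm with a
  # perturbed right-hand side
  basis <- test_basis(c(930, 970))
  y <- drop(basis$matrix %*% c(70, 25)) + c(0.001, -0.0005)
  fit <- fit_concentrations(y, basis, nonneg = FALSE)
  expect_equal(unname(fit$concentrations),
               c(68.07300540593936, 37.461430196972366), tolerance = 1e-9)
})

test_that("unmixing is unbiased under zero-mean noise", {
  basis <- test_basis()
  truth <- c(water = 70, lipid = 30)
  mu <- synthesize_absorption(basis, truth)
  n_rep <- 10000
  set.seed(42)
  sd_mu <- 0.001
  cube <- array(rep(mu, each = n_rep) +
                  rnorm(n_rep * length(mu), sd = sd_mu),
                dim = c(n_rep, 1, length(mu)))
  um <- unmix_map(cube, basis, nonneg = FALSE)
  est <- matrix(um$concentrations, n_rep, 2)
  se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_lt(abs(mean(est[, 1]) - 70), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - 30), 3 * se[2])
})

test_that("fit is scale-equivariant and flags out-of-span components", {
  basis <- test_basis()
  mu <- synthesize_absorption(basis, c(water = 55, lipid = 35))
  f1 <- fit_concentrations(mu, basis, nonneg = FALSE)
  f3 <- fit_concentrations(3 * mu, basis, nonneg = FALSE)
  expect_equal(f3$concentrations, 3 * f1$concentrations)
  expect_lt(f1$residual_norm, 1e-12)

  # perturb orthogonally to the basis span
  A <- basis$matrix
  set.seed(1)
  z <- rnorm(nrow(A))
  z_perp <- z - A %*% solve(crossprod(A), crossprod(A, z))
  f_perp <- fit_concentrations(mu + z_perp * 1e-3, basis, nonneg = FALSE)
  expect_gt(f_perp$residual_norm, 1e-6)
  expect_equal(f_perp$concentrations, f1$concentrations, tolerance = 1e-6)
})

test_that("NaN wavelengths are masked out, too few remaining is an error", {
  basis <- test_basis()
  mu <- synthesize_absorption(basis, c(water = 85, lipid = 15))
  mu_nan <- mu
  mu_nan[c(3, 7)] <- NaN
  fit <- fit_concentrations(mu_nan, basis)
  expect_equal(unname(fit$concentrations), c(85, 15), tolerance = 1e-8)
  expect_equal(fit$n_used, length(mu) - 2)

  mu_gone <- mu
  mu_gone[-1] <- NaN
  expect_error(fit_concentrations(mu_gone, basis), "finite wavelengths")
})

test_that("rank-deficient bases are rejected", {
  sp <- toy_spectrum("water", c(900, 950, 1000), c(0.01, 0.02, 0.03))
  sp2 <- toy_spectrum("lipid", c(900, 950, 1000), c(0.02, 0.04, 0.06))
  expect_error(chromophore_basis(list(sp, sp2), c(900, 950, 1000)),
               "rank")
})

test_that("ROI averaging honours the circle geometry", {
  m <- matrix(70, 40, 40)
  r <- roi_average(m, center = c(20, 20), diameter = 2, pixel_pitch = 0.1)
  expect_equal(r$mean, 70)
  expect_equal(r$sd, 0)

  # half-plane 60/80 with center on the boundary: brute-force enumeration
  hp <- matrix(60, 40, 40)
  hp[, 21:40] <- 80
  center <- c(20, 20.5)
  r_px <- (2 / 2) / 0.1
  rows <- matrix(1:40, 40, 40); cols <- matrix(1:40, 40, 40, byrow = TRUE)
  inside <- (rows - center[1])^2 + (cols - center[2])^2 <= r_px^2
  oracle <- mean(hp[inside])
  r2 <- roi_average(hp, center, diameter = 2, pixel_pitch = 0.1)
  expect_equal(r2$mean, oracle)
  expect_lt(abs(r2$mean - 70), 80 / sum(inside))  # pixel quantization

  # degenerate ROI: smaller than one pixel pitch
  r3 <- roi_average(m, center = c(10.2, 10.3), diameter = 0.05,
                    pixel_pitch = 0.1)
  expect_equal(r3$n_pixels, 1)
  expect_equal(r3$sd, 0)

  expect_error(roi_average(m, center = c(2, 2), diameter = 2,
                           pixel_pitch = 0.1), "outside")
})

test_that("ROI statistics exclude and count NaN pixels", {
  m <- matrix(50, 20, 20)
  m[10, 10] <- NaN
  r <- roi_average(m, c(10, 10), diameter = 0.6, pixel_pitch = 0.1)
  expect_equal(r$n_nan, 1)
  expect_equal(r$mean, 50)
})
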