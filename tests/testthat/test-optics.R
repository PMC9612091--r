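# Diffusion forward model, LUT construction and inversion.

test_that("forward reflectance matches the frozen closed-form value", {
  # frozen from an independent scripted evaluation of the closed form
  expect_equal(rd_forward(0.02, 1.0, 0), 0.5171879674542004,
               tolerance = 1e-12)
  expect_equal(rd_forward(0.02, 1.0, 0.2), 0.11680268645418103,
               tolerance = 1e-12)
})

test_that("modulated attenuation reduces to mu_eff at zero frequency", {
  mu_a <- c(0.01, 0.03, 0.08); mu_s <- c(0.8, 1.5, 4)
  expect_equal(mu_eff_prime(mu_a, mu_s, 0),
               sqrt(3 * mu_a * (mu_a + mu_s)))
})

test_that("reflectance is bounded and monotone in its arguments", {
  set.seed(11)
  mu_a <- exp(runif(200, log(0.0067), log(0.082)))
  mu_s <- runif(200, 0.67, 4.2)
  rd0 <- rd_forward(mu_a, mu_s, 0)
  rd2 <- rd_forward(mu_a, mu_s, 0.2)
  expect_true(all(rd0 > 0 & rd0 < 1))
  expect_true(all(rd2 < rd0))                          # decreasing in fx
  expect_true(all(rd_forward(mu_a * 1.05, mu_s, 0.2) < rd2))  # in mu_a
  expect_true(all(rd_forward(mu_a, mu_s * 1.05, 0.2) > rd2))  # in mu_s'
  expect_error(rd_forward(-0.01, 1, 0), "mu_a")
  expect_error(rd_forward(0.01, 0, 0), "mu_s_prime")
})

test_that("LUT nodes equal pointwise forward evaluations and are monotone", {
  small <- build_lut(grid_sizes = c(2, 2), fx_pair = c(0, 0.2))
  for (i in 1:2) for (j in 1:2) {
    expect_equal(small$rd1[i, j],
                 rd_forward(small$mu_a_grid[i], small$mu_s_grid[j], 0))
    expect_equal(small$rd2[i, j],
                 rd_forward(small$mu_a_grid[i], small$mu_s_grid[j], 0.2))
  }
  # node-wise monotonicity over the validated property ranges
  lut <- build_lut(mu_a_range = c(0.0067, 0.082),
                   mu_s_range = c(0.67, 4.2), grid_sizes = c(50, 50))
  expect_true(all(diff(lut$rd1) < 0))   # decreasing along mu_a
  expect_true(all(diff(lut$rd2) < 0))
  expect_true(all(lut$rd2 < lut$rd1))   # higher frequency darker node-wise
  expect_error(build_lut(fx_pair = c(0.2, 0.2)), "degenerate")
})

test_that("round trip through the inversion recovers properties within
           0.5% relative", {
  lut <- test_lut()
  set.seed(21)
  n <- 1000
  mu_a <- exp(runif(n, log(0.0067), log(0.082)))
  mu_s <- runif(n, 0.67, 4.2)
  inv <- invert_map(rd_forward(mu_a, mu_s, 0) |> matrix(n, 1),
                    rd_forward(mu_a, mu_s, 0.2) |> matrix(n, 1), lut)
  expect_lt(max(abs(as.vector(inv$mu_a) - mu_a) / mu_a), 0.005)
  expect_lt(max(abs(as.vector(inv$mu_s_prime) - mu_s) / mu_s), 0.005)
  expect_false(any(inv$out_of_range))
})

test_that("a LUT node reflectance pair is recovered exactly", {
  lut <- test_lut()
  i <- 40L; j <- 70L
  p <- invert_pixel(c(lut$rd1[i, j], lut$rd2[i, j]), lut)
  expect_equal(p$mu_a, lut$mu_a_grid[i], tolerance = 1e-9)
  expect_equal(p$mu_s_prime, lut$mu_s_grid[j], tolerance = 1e-9)
  expect_false(p$out_of_range)
})

test_that("unattainable reflectance pairs are clamped and flagged", {
  lut <- test_lut()
  p <- invert_pixel(c(0.99, 0.98), lut)
  expect_true(p$out_of_range)
  expect_true(p$mu_a >= min(lut$mu_a_grid) - 1e-12 &&
                p$mu_a <= max(lut$mu_a_grid) + 1e-12)
  expect_true(p$mu_s_prime >= min(lut$mu_s_grid) - 1e-12 &&
                p$mu_s_prime <= max(lut$mu_s_grid) + 1e-12)
})

test_that("map inversion broadcasts the single-pixel result and isolates
           corrupted pixels", {
  lut <- test_lut()
  r1 <- rd_forward(0.03, 1.8, 0); r2 <- rd_forward(0.03, 1.8, 0.2)
  m1 <- matrix(r1, 8, 8); m2 <- matrix(r2, 8, 8)
  inv <- invert_map(m1, m2, lut)
  expect_equal(as.vector(inv$mu_a), rep(0.03, 64), tolerance = 1e-8)
  expect_equal(as.vector(inv$mu_s_prime), rep(1.8, 64), tolerance = 1e-8)

  m1c <- m1; m1c[3, 5] <- 1.2          # corrupted pixel, Rd > 1
  invc <- suppressMessages(invert_map(m1c, m2, lut))
  expect_true(invc$out_of_range[3, 5])
  expect_equal(sum(invc$out_of_range), 1)
  keep <- !invc$out_of_range
  expect_equal(invc$mu_a[keep], inv$mu_a[keep], tolerance = 1e-10)

  expect_error(invert_map(m1, matrix(r2, 4, 4), lut), "shape")
})

test_that("inversion is insensitive to LUT grid density once converged", {
  lut1 <- test_lut()
  lut2 <- build_lut(grid_sizes = c(256, 256))
  set.seed(5)
  mu_a <- exp(runif(50, log(0.0067), log(0.082)))
  mu_s <- runif(50, 0.67, 4.2)
  r1 <- rd_forward(mu_a, mu_s, 0); r2 <- rd_forward(mu_a, mu_s, 0.2)
  a <- sfdimap:::invert_rd(r1, r2, lut1)
  b <- sfdimap:::invert_rd(r1, r2, lut2)
  expect_lt(max(abs(a$mu_a - b$mu_a) / b$mu_a), 0.001)
  expect_lt(max(abs(a$mu_s_prime - b$mu_s_prime) / b$mu_s_prime), 0.001)
})

test_that("LUT files round trip and imported tables invert consistently", {
  lut <- build_lut(grid_sizes = c(64, 64))
  dir <- withr::local_tempdir()
  write_lut(lut, dir)
  back <- read_lut(dir)
  expect_equal(back$mu_a_grid, lut$mu_a_grid)
  expect_equal(back$rd1, lut$rd1, ignore_attr = TRUE)
  expect_equal(back$fx_pair, lut$fx_pair)

  set.seed(8)
  mu_a <- exp(runif(100, log(0.01), log(0.06)))
  mu_s <- runif(100, 0.9, 3.5)
  r1 <- rd_forward(mu_a, mu_s, 0); r2 <- rd_forward(mu_a, mu_s, 0.2)
  # a re-read table of the same provenance inverts identically (up to the
  # text round trip of the grid nodes)
  a <- sfdimap:::invert_rd(r1, r2, lut)
  b <- sfdimap:::invert_rd(r1, r2, back)
  expect_equal(a$mu_a, b$mu_a, tolerance = 1e-12)
  # the same numbers tagged as an external table go through bilinear
  # interpolation of the stored surface instead of the closed form
  imp <- read_lut(dir, model = "imported")
  cc <- sfdimap:::invert_rd(r1, r2, imp)
  expect_lt(max(abs(cc$mu_a - mu_a) / mu_a), 0.02)
  expect_lt(max(abs(cc$mu_s_prime - mu_s) / mu_s), 0.02)
})

test_that("effective penetration depth follows 1/mu_eff'", {
  # frozen from independent evaluation of 1/sqrt(3 mu_a mu_tr + (2 pi fx)^2)
  expect_equal(effective_penetration_depth(0.02, 1.0, 0.2),
               0.7807886627022385, tolerance = 1e-12)
  expect_equal(effective_penetration_depth(0.02, 1.0, 0),
               4.0422604172722165, tolerance = 1e-12)
  expect_lt(effective_penetration_depth(0.02, 1.0, 0.4),
            effective_penetration_depth(0.02, 1.0, 0.2))
  expect_lt(effective_penetration_depth(0.04, 1.0, 0.2),
            effective_penetration_depth(0.02, 1.0, 0.2))
  expect_lt(effective_penetration_depth(0.02, 2.0, 0.2),
            effective_penetration_depth(0.02, 1.0, 0.2))
})
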