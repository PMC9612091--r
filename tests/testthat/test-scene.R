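# Synthetic scenes, the acquisition renderer and stack serialization.

test_that("scene templates produce their stated ground truth", {
  sc <- make_scene("homogeneous", list(water = 90, lipid = 10),
                   shape = c(10, 12))
  expect_true(all(sc$water == 90) && all(sc$lipid == 10))

  two <- make_scene("two_region", list(water1 = 90, lipid1 = 10,
                                       water2 = 70, lipid2 = 30),
                    shape = c(10, 12))
  pairs <- unique(paste(two$water, two$lipid))
  expect_length(pairs, 2)

  inj <- make_scene("injection", list(water = 60, amplitude = 15,
                                      sigma_mm = 0.5, n_times = 3),
                    shape = c(20, 20), pixel_pitch = 0.1)
  ctr <- inj$truth$center
  expect_equal(inj$water_t[[1]][ctr[1], ctr[2]], 60)
  expect_equal(inj$water_t[[2]][ctr[1], ctr[2]], 75)
  # blob ROI mean increases by less than the center amplitude
  r1 <- roi_average(inj$water_t[[1]], ctr, 1, 0.1)
  r2 <- roi_average(inj$water_t[[2]], ctr, 1, 0.1)
  expect_equal(r1$mean, 60)
  expect_gt(r2$mean, 60)
  expect_lt(r2$mean, 75)

  expect_error(make_scene("volcano"), "homogeneous, two_region, injection")
})

test_that("rendered stacks satisfy the acquisition-layout invariants", {
  acq <- quiet_acq(wavelengths = c(930, 970))
  st <- render_stack(make_scene("homogeneous"), acq)
  expect_s3_class(st, "raw_frame_stack")
  expect_equal(nrow(st$index), 2 * 5)      # 5 patterns per wavelength
  expect_true(all(st$frames >= 0))
  for (wl in c(930, 970)) {
    sub <- st$index[st$index$wavelength == wl, ]
    expect_setequal(sub$pattern[sub$fx == 0], c("white", "black"))
    expect_setequal(sub$pattern[sub$fx == 0.2],
                    c("phase0", "phase120", "phase240"))
  }
})

test_that("zero modulation renders a zero demodulated amplitude", {
  acq <- quiet_acq(wavelengths = 950, ac_level = 0)
  st <- render_stack(make_scene("homogeneous"), acq)
  dm <- demodulate_stack(st)
  expect_equal(max(abs(dm$ac)), 0)
  expect_gt(min(dm$dc), 0)
})

test_that("processing a noiseless rendering reproduces the scene exactly", {
  acq <- quiet_acq(wavelengths = seq(900, 1000, by = 25))
  sc <- make_scene("homogeneous", list(water = 85, lipid = 15),
                   shape = c(12, 12))
  rd <- calibrate_stack(
    demodulate_stack(render_stack(sc, acq)),
    demodulate_stack(render_reference_stack(acq, shape = c(12, 12))))
  basis <- default_basis(acq$wavelengths)
  mu <- synthesize_absorption(basis, c(water = 85, lipid = 15))
  mu_s <- 2.0 * (acq$wavelengths / 1000)^-1.3
  rd_true <- rd_forward(mu, mu_s, 0.2)
  for (k in seq_along(acq$wavelengths))
    expect_lt(max(abs(rd$rd_f2[, , k] / rd_true[k] - 1)), 1e-10)
})

test_that("renderer drift plus tile correction closes in time", {
  drift_fun <- function(t) c(1, 1.08, 0.93)[t]
  acq <- quiet_acq(wavelengths = c(930, 970), drift = drift_fun)
  sc <- make_scene("homogeneous", list(water = 80, lipid = 20),
                   shape = c(16, 16), tile = c(1, 4, 1, 4))
  ref <- render_reference_stack(acq, shape = c(16, 16), time_index = 1)
  ref_dm <- demodulate_stack(ref)
  rd_t <- lapply(1:3, function(t)
    calibrate_stack(demodulate_stack(render_stack(sc, acq, time_index = t)),
                    ref_dm))
  # uncorrected series drifts...
  expect_gt(abs(rd_t[[2]]$rd_f1[8, 8, 1] / rd_t[[1]]$rd_f1[8, 8, 1] - 1),
            0.05)
  # ...and the tile correction removes it exactly
  for (k in 1:2) {
    ser <- array(unlist(lapply(rd_t, function(r) r$rd_f1[, , k])),
                 c(16, 16, 3))
    cor <- drift_correct(ser, c(1, 4, 1, 4))
    expect_equal(cor[, , 2], cor[, , 1], tolerance = 1e-12)
    expect_equal(cor[, , 3], cor[, , 1], tolerance = 1e-12)
  }
})

test_that("rendering is deterministic under seed with independent noise", {
  acq <- acquisition_spec(wavelengths = 950, noise_sd = 0.01)
  sc <- make_scene("homogeneous")
  a <- render_stack(sc, acq, seed = 42)
  b <- render_stack(sc, acq, seed = 42)
  expect_identical(a$frames, b$frames)
  c_ <- render_stack(sc, acq, seed = 43)
  expect_false(identical(a$frames, c_$frames))
  # noise in different frames is uncorrelated: subtract the noiseless render
  clean <- render_stack(sc, acquisition_spec(wavelengths = 950,
                                             noise_sd = 0))
  n1 <- a$frames[, , 3] - clean$frames[, , 3]
  n2 <- a$frames[, , 4] - clean$frames[, , 4]
  expect_lt(abs(cor(as.vector(n1), as.vector(n2))), 0.1)
})

test_that("stacks round trip through disk at 32- and 16-bit", {
  acq <- acquisition_spec(wavelengths = c(930, 970), noise_sd = 0.001)
  st <- render_stack(make_scene("homogeneous"), acq, seed = 3)
  for (bits in c(32L, 16L)) {
    dir <- withr::local_tempdir()
    write_stack(st, dir, bits = bits)
    back <- read_stack(dir)
    tol <- if (bits == 32L) 1e-6 else 1e-4
    expect_lt(max(abs(back$frames - st$frames)) / max(st$frames), tol)
    expect_equal(back$index$pattern, st$index$pattern)
    expect_equal(back$pixel_pitch, st$pixel_pitch)
  }
})

test_that("a manifest missing a phase frame is rejected by name", {
  acq <- quiet_acq(wavelengths = 950)
  st <- render_stack(make_scene("homogeneous"), acq)
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  keep <- meta$pages$pattern != "phase120"
  meta$pages <- meta$pages[keep, ]
  pages <- tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE)[keep]
  tiff::writeTIFF(pages, file.path(dir, "frames.tif"),
                  bits.per.sample = 32L)
  meta$pages$page <- seq_len(nrow(meta$pages))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  expect_error(read_stack(dir), "950.*fx=0.2|phase")
})
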