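# Synthetic acquisition: ground-truth scenes and a raw-frame renderer that
# inverts the processing chain, closing the loop for end-to-end tests.

#' Load the reference-phantom optical properties
#'
#' Packaged 10% intralipid calibration-phantom properties (650-1000 nm,
#' synthetic literature-style values; see the CSV header).
#'
#' @param path optional CSV with columns `wavelength_nm`, `mu_a`,
#'   `mu_s_prime` (comment lines with `#`).
#' @return data.frame with columns `wavelength_nm`, `mu_a`, `mu_s_prime`.
#' @export
reference_phantom <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "intralipid10_synthetic.csv",
                        package = "sfdimap")
  utils::read.csv(path, comment.char = "#")
}

# interpolate reference-phantom properties at given wavelengths
ref_props_at <- function(wavelengths, ref = reference_phantom()) {
  if (min(wavelengths) < min(ref$wavelength_nm) ||
      max(wavelengths) > max(ref$wavelength_nm))
    stop("requested wavelength outside the reference-phantom table")
  list(mu_a = stats::approx(ref$wavelength_nm, ref$mu_a, wavelengths)$y,
       mu_s_prime = stats::approx(ref$wavelength_nm, ref$mu_s_prime,
                                  wavelengths)$y)
}

#' Acquisition specification for the synthetic renderer
#'
#' @param wavelengths measurement wavelengths, nm (default 900-1000 at
#'   5-nm increments).
#' @param fx_pair the planar and modulated spatial frequencies
#'   `c(0, fx)`, mm^-1 (default `c(0, 0.2)`).
#' @param dc_level,ac_level planar and modulation illumination levels
#'   (arbitrary camera units, > 0).
#' @param dark_level dark/ambient offset added to every frame.
#' @param gain global detector gain.
#' @param noise_sd Gaussian camera noise sd per frame, same units as the
#'   levels (default 0.002).
#' @param drift optional function `t -> factor` applied multiplicatively to
#'   the illumination at time point `t` (default none).
#' @param phases_deg the three pattern phases, degrees.
#' @param n_rel relative refractive index assumed for the media.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(wavelengths = seq(900, 1000, by = 5),
                             fx_pair = c(0, 0.2), dc_level = 0.6,
                             ac_level = 0.3, dark_level = 0.05, gain = 1,
                             noise_sd = 0.002, drift = NULL,
                             phases_deg = c(0, 120, 240), n_rel = 1.4) {
  if (fx_pair[1] == fx_pair[2]) stop("fx_pair must be distinct")
  if (dc_level <= 0 || ac_level < 0) stop("illumination levels must be positive")
  structure(list(wavelengths = wavelengths, fx_pair = fx_pair,
                 dc_level = dc_level, ac_level = ac_level,
                 dark_level = dark_level, gain = gain, noise_sd = noise_sd,
                 drift = drift, phases_deg = phases_deg, n_rel = n_rel),
            class = "acquisition_spec")
}

#' Construct a ground-truth chromophore scene
#'
#' Templates:
#' * `"homogeneous"`: uniform water/lipid concentrations
#'   (`water`, `lipid`, percent).
#' * `"two_region"`: left/right halves with two concentration pairs
#'   (`water1`, `lipid1`, `water2`, `lipid2`).
#' * `"injection"`: a homogeneous baseline plus a Gaussian water-content
#'   blob appearing from the second time point onward, emulating a
#'   subcutaneous bolus (`water`, `lipid`, `amplitude` percent,
#'   `sigma_mm`, `n_times`).
#'
#' A rectangular correction tile with the reference phantom's 90/10
#' water/lipid recipe can be embedded via `tile = c(row1, row2, col1,
#' col2)`.
#'
#' @param template template name.
#' @param params named list of template parameters (see above).
#' @param shape image shape `c(rows, cols)` (default 48 x 48).
#' @param pixel_pitch pixel pitch, mm/pixel (default 0.1).
#' @param scatter_a,scatter_b reduced-scattering power law
#'   `mu_s'(lambda) = a * (lambda/1000)^(-b)` (defaults 2.0 mm^-1, 1.3).
#' @param tile optional tile rectangle `c(row1, row2, col1, col2)`.
#' @param seed unused by the deterministic templates, accepted for
#'   interface uniformity.
#' @return An object of class `scene`: per-pixel `water` and `lipid` maps
#'   (percent; for `"injection"` a list of water maps per time point),
#'   scattering parameters, pixel pitch, tile region and the ground truth
#'   echoed in `truth`.
#' @export
make_scene <- function(template = c("homogeneous", "two_region",
                                    "injection"),
                       params = list(), shape = c(48, 48),
                       pixel_pitch = 0.1, scatter_a = 2.0, scatter_b = 1.3,
                       tile = NULL, seed = NULL) {
  if (is.character(template) &&
      !template[1] %in% c("homogeneous", "two_region", "injection"))
    stop("unknown template '", template[1],
         "'; available: homogeneous, two_region, injection")
  template <- match.arg(template)
  p <- function(name, default) if (!is.null(params[[name]]))
    params[[name]] else default
  H <- shape[1]; W <- shape[2]
  water_t <- NULL
  if (template == "homogeneous") {
    water <- matrix(p("water", 90), H, W)
    lipid <- matrix(p("lipid", 10), H, W)
    truth <- list(water = p("water", 90), lipid = p("lipid", 10))
  } else if (template == "two_region") {
    half <- floor(W / 2)
    water <- matrix(p("water2", 70), H, W)
    water[, seq_len(half)] <- p("water1", 90)
    lipid <- matrix(p("lipid2", 30), H, W)
    lipid[, seq_len(half)] <- p("lipid1", 10)
    truth <- list(region1 = c(water = p("water1", 90),
                              lipid = p("lipid1", 10)),
                  region2 = c(water = p("water2", 70),
                              lipid = p("lipid2", 30)),
                  split_col = half)
  } else {
    water <- matrix(p("water", 60), H, W)
    lipid <- matrix(p("lipid", 25), H, W)
    amp <- p("amplitude", 15); sig <- p("sigma_mm", 1.0)
    n_times <- p("n_times", 5L)
    ctr <- p("center", c(H / 2, W / 2))
    rows <- matrix(seq_len(H), H, W); cols <- matrix(seq_len(W), H, W,
                                                     byrow = TRUE)
    r2 <- ((rows - ctr[1])^2 + (cols - ctr[2])^2) * pixel_pitch^2
    blob <- exp(-r2 / (2 * sig^2))
    water_t <- lapply(seq_len(n_times), function(t)
      if (t == 1) water else water + amp * blob)
    truth <- list(water_baseline = p("water", 60), lipid = p("lipid", 25),
                  amplitude = amp, sigma_mm = sig, center = ctr,
                  n_times = n_times)
  }
  if (!is.null(tile)) {
    stopifnot(length(tile) == 4, tile[1] >= 1, tile[2] <= H,
              tile[3] >= 1, tile[4] <= W)
    set_tile <- function(m, v) { m[tile[1]:tile[2], tile[3]:tile[4]] <- v; m }
    water <- set_tile(water, 90); lipid <- set_tile(lipid, 10)
    if (!is.null(water_t)) water_t <- lapply(water_t, set_tile, v = 90)
  }
  structure(list(template = template, water = water, lipid = lipid,
                 water_t = water_t, scatter_a = scatter_a,
                 scatter_b = scatter_b, pixel_pitch = pixel_pitch,
                 shape = c(H, W), tile = tile, truth = truth),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> template '%s', %dx%d px @ %.3g mm/px\n",
              x$template, x$shape[1], x$shape[2], x$pixel_pitch))
  invisible(x)
}

# scene concentration maps at a time point
scene_maps <- function(scene, time_index = 1L) {
  water <- if (!is.null(scene$water_t)) {
    if (time_index < 1 || time_index > length(scene$water_t))
      stop("time_index outside the scene's time axis")
    scene$water_t[[time_index]]
  } else scene$water
  list(water = water, lipid = scene$lipid)
}

#' Construct a raw SFDI frame stack
#'
#' Container for camera frames indexed by (wavelength, spatial frequency,
#' pattern). For each wavelength the planar frequency carries `white` and
#' `black` patterns and the modulated frequency carries three sinusoidal
#' phases.
#'
#' @param frames array `[H, W, n_pages]`, pixel values >= 0.
#' @param index data.frame with one row per page: `wavelength`, `fx`,
#'   `pattern` (`"white"`, `"black"`, `"phase0"`, `"phase120"`,
#'   `"phase240"`).
#' @param pixel_pitch mm/pixel.
#' @param exposure_ms camera exposure, ms.
#' @return An object of class `raw_frame_stack`.
#' @export
raw_frame_stack <- function(frames, index, pixel_pitch, exposure_ms = 100) {
  stopifnot(length(dim(frames)) == 3, nrow(index) == dim(frames)[3])
  validate_stack_index(index)
  structure(list(frames = frames, index = index, pixel_pitch = pixel_pitch,
                 exposure_ms = exposure_ms,
                 shape = dim(frames)[1:2]),
            class = "raw_frame_stack")
}

validate_stack_index <- function(index) {
  stopifnot(all(c("wavelength", "fx", "pattern") %in% names(index)))
  for (wl in unique(index$wavelength)) {
    sub <- index[index$wavelength == wl, ]
    for (fx in unique(sub$fx)) {
      pat <- sub$pattern[sub$fx == fx]
      if (fx == 0) {
        if (!all(c("white", "black") %in% pat))
          stop(sprintf("missing white/black pattern at (%g nm, fx=0)", wl))
      } else if (!all(c("phase0", "phase120", "phase240") %in% pat)) {
        stop(sprintf("missing phase frame at (%g nm, fx=%g)", wl, fx))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.raw_frame_stack <- function(x, ...) {
  cat(sprintf(
    "<raw_frame_stack> %dx%d px, %d pages (%d wavelengths), %.3g mm/px\n",
    x$shape[1], x$shape[2], nrow(x$index),
    length(unique(x$index$wavelength)), x$pixel_pitch))
  invisible(x)
}

# render frames from per-wavelength optical-property maps
render_from_props <- function(mu_a_fun, mu_s_fun, shape, pixel_pitch, acq,
                              drift_factor = 1) {
  H <- shape[1]; W <- shape[2]
  x_mm <- matrix((seq_len(W) - 1) * pixel_pitch, H, W, byrow = TRUE)
  fx <- acq$fx_pair[2]
  pages <- list(); idx <- list()
  for (wl in acq$wavelengths) {
    mu_a <- mu_a_fun(wl); mu_s <- mu_s_fun(wl)
    rd0 <- rd_forward(mu_a, mu_s, acq$fx_pair[1], acq$n_rel)
    rdf <- rd_forward(mu_a, mu_s, fx, acq$n_rel)
    add <- function(img, pattern, f) {
      pages[[length(pages) + 1L]] <<- img +
        if (acq$noise_sd > 0)
          matrix(stats::rnorm(H * W, sd = acq$noise_sd), H, W) else 0
      idx[[length(idx) + 1L]] <<- data.frame(wavelength = wl, fx = f,
                                             pattern = pattern)
    }
    g <- acq$gain * drift_factor
    add(g * rd0 * (acq$dc_level + acq$ac_level) + acq$dark_level,
        "white", acq$fx_pair[1])
    add(matrix(acq$dark_level, H, W), "black", acq$fx_pair[1])
    for (k in seq_along(acq$phases_deg)) {
      ph <- acq$phases_deg[k] * pi / 180
      add(g * (rd0 * acq$dc_level +
                 rdf * acq$ac_level * cos(2 * pi * fx * x_mm + ph)),
          paste0("phase", acq$phases_deg[k]), fx)
    }
  }
  frames <- array(unlist(pages), dim = c(H, W, length(pages)))
  frames[frames < 0] <- 0
  raw_frame_stack(frames, do.call(rbind, idx), pixel_pitch)
}

#' Render a raw SFDI frame stack from a ground-truth scene
#'
#' Inverts the processing chain: per pixel and wavelength, absorption
#' follows Beer's law from the scene's water/lipid maps and scattering from
#' its power law; diffuse reflectance at each spatial frequency comes from
#' [rd_forward()]; frames are composed as
#' `I_k = gain * (Rd(0) dc + Rd(fx) ac cos(2 pi fx x + phi_k)) + dark`,
#' `white = gain * Rd(0) (dc + ac) + dark`, `black = dark`, each with
#' additive Gaussian camera noise. With zero noise the demodulation and
#' calibration chain recovers the scene's forward-model reflectance to
#' machine precision.
#'
#' @param scene a [make_scene()] result.
#' @param acq an [acquisition_spec()].
#' @param seed RNG seed for the camera noise.
#' @param time_index time point of a time-varying scene to render.
#' @param spectra named list of [chromophore_spectrum()] objects for
#'   `water` and `lipid` (default the packaged fixtures).
#' @return A [raw_frame_stack()].
#' @export
render_stack <- function(scene, acq = acquisition_spec(), seed = NULL,
                         time_index = 1L,
                         spectra = list(water = load_chromophore("water"),
                                        lipid = load_chromophore("lipid"))) {
  stopifnot(inherits(scene, "scene"), inherits(acq, "acquisition_spec"))
  if (!is.null(seed)) set.seed(seed)
  maps <- scene_maps(scene, time_index)
  drift <- if (is.null(acq$drift)) 1 else acq$drift(time_index)
  eps_w <- resample_spectrum(spectra$water,
                             acq$wavelengths)$unit_absorption * 0.01
  eps_l <- resample_spectrum(spectra$lipid,
                             acq$wavelengths)$unit_absorption * 0.01
  mu_a_fun <- function(wl) {
    i <- match(wl, acq$wavelengths)
    mu <- maps$water * eps_w[i] + maps$lipid * eps_l[i]
    if (any(mu <= 0)) stop("scene produces non-positive absorption at ",
                           wl, " nm")
    mu
  }
  mu_s_fun <- function(wl)
    matrix(scene$scatter_a * (wl / 1000)^(-scene$scatter_b),
           scene$shape[1], scene$shape[2])
  render_from_props(mu_a_fun, mu_s_fun, scene$shape, scene$pixel_pitch,
                    acq, drift)
}

#' Render the matching reference-phantom stack
#'
#' Renders a homogeneous stack from the reference phantom's (mu_a, mu_s')
#' table under the same acquisition, for use as the calibration reference.
#'
#' @param acq an [acquisition_spec()].
#' @param shape image shape (default 48 x 48).
#' @param pixel_pitch mm/pixel (default 0.1).
#' @param seed RNG seed for the camera noise.
#' @param ref reference-phantom property table (see [reference_phantom()]).
#' @param time_index time point (drift applies as for the sample).
#' @return A [raw_frame_stack()].
#' @export
render_reference_stack <- function(acq = acquisition_spec(),
                                   shape = c(48, 48), pixel_pitch = 0.1,
                                   seed = NULL, ref = reference_phantom(),
                                   time_index = 1L) {
  if (!is.null(seed)) set.seed(seed)
  pr <- ref_props_at(acq$wavelengths, ref)
  drift <- if (is.null(acq$drift)) 1 else acq$drift(time_index)
  mu_a_fun <- function(wl)
    matrix(pr$mu_a[match(wl, acq$wavelengths)], shape[1], shape[2])
  mu_s_fun <- function(wl)
    matrix(pr$mu_s_prime[match(wl, acq$wavelengths)], shape[1], shape[2])
  render_from_props(mu_a_fun, mu_s_fun, shape, pixel_pitch, acq, drift)
}

#' Write a raw frame stack to disk
#'
#' Multi-page float TIFF (`frames.tif`) plus a JSON manifest
#' (`manifest.json`) mapping each page to (wavelength, fx, pattern) and
#' recording pixel pitch, exposure and the intensity scale used to fit the
#' on-disk sample format.
#'
#' @param stack a [raw_frame_stack()].
#' @param path output directory (created if needed).
#' @param bits TIFF bits per sample: 32 (float, default) or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 32L) {
  stopifnot(inherits(stack, "raw_frame_stack"), bits %in% c(16L, 32L))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(i) stack$frames[, , i] / scale)
  tiff::writeTIFF(pages, file.path(path, "frames.tif"),
                  bits.per.sample = bits)
  jsonlite::write_json(
    list(pages = cbind(page = seq_len(nrow(stack$index)), stack$index),
         pixel_pitch = stack$pixel_pitch, exposure_ms = stack$exposure_ms,
         scale = scale, bits = bits),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}

#' Read a raw frame stack from disk
#'
#' Reads the layout written by [write_stack()] and validates the manifest
#' (every modulated (wavelength, fx) must carry three phases; every planar
#' one white and black).
#'
#' @param path directory containing `frames.tif` and `manifest.json`.
#' @return A [raw_frame_stack()].
#' @export
read_stack <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(path, "frames.tif"), all = TRUE)
  if (length(pages) != nrow(meta$pages))
    stop(sprintf("manifest lists %d pages but TIFF has %d",
                 nrow(meta$pages), length(pages)))
  frames <- array(unlist(pages),
                  dim = c(dim(pages[[1]]), length(pages))) * meta$scale
  idx <- meta$pages[order(meta$pages$page), c("wavelength", "fx", "pattern")]
  raw_frame_stack(frames, idx, meta$pixel_pitch, meta$exposure_ms)
}
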