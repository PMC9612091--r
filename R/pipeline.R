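# Orchestration: stack-level demodulation/calibration, the full processing
# chain, and the measurement-design studies.

#' Demodulate a raw frame stack
#'
#' Applies [demodulate_dc()] to the white/black pair at the planar
#' frequency and [demodulate_ac()] to the three phase frames at the
#' modulated frequency, per wavelength.
#'
#' @param stack a [raw_frame_stack()].
#' @return list with `wavelengths`, `fx_pair`, and arrays `dc` and `ac`
#'   `[H, W, n_wavelengths]`.
#' @export
demodulate_stack <- function(stack) {
  stopifnot(inherits(stack, "raw_frame_stack"))
  idx <- stack$index
  wls <- sort(unique(idx$wavelength))
  fxs <- sort(unique(idx$fx))
  if (length(fxs) != 2 || fxs[1] != 0)
    stop("stack must contain the planar frequency and one modulated one")
  page <- function(wl, fx, pattern) {
    i <- which(idx$wavelength == wl & idx$fx == fx & idx$pattern == pattern)
    stack$frames[, , i[1]]
  }
  H <- stack$shape[1]; W <- stack$shape[2]
  dc <- ac <- array(0, c(H, W, length(wls)))
  for (k in seq_along(wls)) {
    wl <- wls[k]
    dc[, , k] <- demodulate_dc(page(wl, 0, "white"), page(wl, 0, "black"))
    ac[, , k] <- demodulate_ac(page(wl, fxs[2], "phase0"),
                               page(wl, fxs[2], "phase120"),
                               page(wl, fxs[2], "phase240"))
  }
  list(wavelengths = wls, fx_pair = fxs, dc = dc, ac = ac)
}

#' Calibrate demodulated sample maps against a reference stack
#'
#' For each wavelength and spatial frequency, predicts the reference
#' phantom's diffuse reflectance from its known optical properties via
#' [rd_forward()] and applies [calibrate()].
#'
#' @param sample_demod,ref_demod results of [demodulate_stack()] on the
#'   sample and reference stacks (matching wavelengths and frequencies).
#' @param ref reference-phantom property table ([reference_phantom()]).
#' @param n_rel relative refractive index of the reference phantom.
#' @return list with `wavelengths`, `fx_pair`, and reflectance arrays
#'   `rd_f1`, `rd_f2` `[H, W, n_wavelengths]`.
#' @export
calibrate_stack <- function(sample_demod, ref_demod,
                            ref = reference_phantom(), n_rel = 1.4) {
  if (!isTRUE(all.equal(sample_demod$wavelengths, ref_demod$wavelengths)) ||
      !isTRUE(all.equal(sample_demod$fx_pair, ref_demod$fx_pair)))
    stop("sample and reference stacks must share wavelengths and frequencies")
  wls <- sample_demod$wavelengths
  pr <- ref_props_at(wls, ref)
  d <- dim(sample_demod$dc)
  rd1 <- rd2 <- array(0, d)
  for (k in seq_along(wls)) {
    p1 <- rd_forward(pr$mu_a[k], pr$mu_s_prime[k], sample_demod$fx_pair[1],
                     n_rel)
    p2 <- rd_forward(pr$mu_a[k], pr$mu_s_prime[k], sample_demod$fx_pair[2],
                     n_rel)
    rd1[, , k] <- calibrate(sample_demod$dc[, , k], ref_demod$dc[, , k], p1)
    rd2[, , k] <- calibrate(sample_demod$ac[, , k], ref_demod$ac[, , k], p2)
  }
  list(wavelengths = wls, fx_pair = sample_demod$fx_pair,
       rd_f1 = rd1, rd_f2 = rd2)
}

# write a float map array to a multi-page TIFF + JSON sidecar
write_map <- function(arr, dir, name, labels, units) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(arr)
  if (length(d) == 2) { arr <- array(arr, c(d, 1)); d <- dim(arr) }
  scale <- max(arr, 1e-12, na.rm = TRUE)
  pages <- lapply(seq_len(d[3]), function(i) {
    m <- arr[, , i] / scale
    m[!is.finite(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 32L)
  jsonlite::write_json(list(name = name, labels = labels, units = units,
                            scale = scale),
                       file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full SFDI processing chain
#'
#' Demodulates sample and reference stacks, calibrates to diffuse
#' reflectance, optionally drift-corrects a time series against an in-FOV
#' correction tile, inverts to optical-property maps through the lookup
#' table, unmixes chromophore concentrations, and reports circular-ROI
#' statistics.
#'
#' `config` is a named list (or path to a JSON file) with fields:
#' * `input`: a [raw_frame_stack()], a stack directory, or a list of either
#'   (time series);
#' * `reference`: the reference-phantom stack or directory;
#' * `chromophores`: character vector (default `c("water", "lipid")`;
#'   hemoglobins additionally require wavelengths below 900 nm);
#' * `lut`: a [build_lut()] result (default built for the stack's
#'   frequency pair);
#' * `tile_roi`: correction-tile rectangle `c(row1, row2, col1, col2)` for
#'   time series;
#' * `rois`: list of `list(center = c(row, col), diameter = mm)`;
#' * `nonneg`: non-negative unmixing (default TRUE);
#' * `out_dir`: optional output directory for map TIFFs and provenance.
#'
#' @param config named list or JSON path as above.
#' @return An artifact bundle: list with `rd` (calibrated reflectance per
#'   time point), `props` ([invert_map()] results), `concentrations`
#'   (unmixing results), `roi_report` (data.frame), `provenance`.
#' @export
run_process <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  get <- function(name, default) if (!is.null(config[[name]]))
    config[[name]] else default
  chrom <- get("chromophores", c("water", "lipid"))
  nonneg <- get("nonneg", TRUE)

  load_one <- function(x) if (inherits(x, "raw_frame_stack")) x else
    read_stack(x)
  input <- config$input
  series <- is.list(input) && !inherits(input, "raw_frame_stack")
  stacks <- if (series) lapply(input, load_one) else list(load_one(input))
  ref_stack <- load_one(config$reference)

  ref <- if (!is.null(config$reference_table))
    utils::read.csv(config$reference_table, comment.char = "#") else
      reference_phantom()
  ref_demod <- demodulate_stack(ref_stack)
  wls <- ref_demod$wavelengths
  if (any(chrom %in% c("oxyhemoglobin", "deoxyhemoglobin")) &&
      min(wls) >= 900)
    stop(paste("hemoglobin unmixing requires wavelength coverage below",
               "900 nm; measured span starts at", min(wls), "nm"))

  rd <- lapply(stacks, function(s)
    calibrate_stack(demodulate_stack(s), ref_demod, ref))
  if (!is.null(config$tile_roi) && length(rd) > 1) {
    tile <- config$tile_roi
    nT <- length(rd)
    for (k in seq_along(wls)) {
      for (f in c("rd_f1", "rd_f2")) {
        ser <- array(unlist(lapply(rd, function(r) r[[f]][, , k])),
                     c(dim(rd[[1]][[f]])[1:2], nT))
        cor <- drift_correct(ser, tile, get("baseline_index", 1L))
        for (t in seq_len(nT)) rd[[t]][[f]][, , k] <- cor[, , t]
      }
    }
  }

  lut <- get("lut", build_lut(fx_pair = rd[[1]]$fx_pair))
  basis <- chromophore_basis(lapply(chrom, load_chromophore), wls)
  props <- lapply(rd, function(r)
    invert_map(r$rd_f1, r$rd_f2, lut, wavelengths = wls, quiet = TRUE))
  conc <- lapply(props, function(p) unmix_map(p$mu_a, basis, nonneg))

  roi_report <- NULL
  rois <- get("rois", list())
  if (length(rois) > 0) {
    rows <- list()
    for (t in seq_along(conc)) {
      for (i in seq_along(rois)) {
        r <- roi_average(conc[[t]]$concentrations, rois[[i]]$center,
                         rois[[i]]$diameter, stacks[[t]]$pixel_pitch)
        r$roi <- i; r$time <- t
        rows[[length(rows) + 1L]] <- r
      }
    }
    roi_report <- do.call(rbind, rows)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("sfdimap")),
    chromophores = chrom, wavelengths = wls, fx_pair = rd[[1]]$fx_pair,
    nonneg = nonneg, n_time_points = length(rd),
    flagged_pixels = vapply(props, function(p)
      sum(p$flagged_per_wavelength), 0),
    mean_fit_residual = vapply(conc, function(cc)
      mean(cc$residual_norm), 0))

  out_dir <- get("out_dir", NULL)
  if (!is.null(out_dir)) {
    for (t in seq_along(rd)) {
      tag <- if (length(rd) > 1) sprintf("_t%02d", t) else ""
      write_map(rd[[t]]$rd_f1, out_dir, paste0("rd_f1", tag), wls, "Rd")
      write_map(rd[[t]]$rd_f2, out_dir, paste0("rd_f2", tag), wls, "Rd")
      write_map(props[[t]]$mu_a, out_dir, paste0("mu_a", tag), wls, "mm^-1")
      write_map(props[[t]]$mu_s_prime, out_dir, paste0("mu_s_prime", tag),
                wls, "mm^-1")
      write_map(conc[[t]]$concentrations, out_dir, paste0("conc", tag),
                basis$names, "percent or uM")
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(roi_report))
      utils::write.csv(roi_report, file.path(out_dir, "roi_report.csv"),
                       row.names = FALSE)
  }

  simplify <- function(x) if (length(x) == 1) x[[1]] else x
  list(rd = simplify(rd), props = simplify(props),
       concentrations = simplify(conc), roi_report = roi_report,
       provenance = provenance)
}

#' Run the measurement-design studies
#'
#' Executes the Cramer-Rao-bound frequency-pair scan and the
#' wavelength-increment study, then applies explicit selection rules:
#' * frequency pair: lowest mean CRB absorption uncertainty among pairs
#'   whose mean effective penetration depth (at the modulated frequency,
#'   over the wavelength range) is at least `depth_min`;
#' * wavelength increment: coarsest increment whose percent-error sd stays
#'   within `sd_factor` times the finest increment's sd for both
#'   chromophores.
#'
#' @param pairs candidate frequency pairs (default the four canonical
#'   `[0, 0.05]`, `[0, 0.1]`, `[0, 0.2]`, `[0, 0.4]` mm^-1).
#' @param wavelengths wavelengths for the CRB scan, nm.
#' @param noise a [noise_model()].
#' @param study a [study_config()] for the increment study.
#' @param depth_min minimum acceptable mean effective penetration depth,
#'   mm (default 0.5).
#' @param sd_factor tolerated sd inflation relative to the finest increment
#'   (default 2.5).
#' @param ref reference-phantom table providing the intralipid-like
#'   properties for the CRB scan and depth calculation.
#' @return list with `crb_table`, `depths`, `selected_pair`,
#'   `study_result`, `selected_increment`, `summary` (text).
#' @export
run_design_studies <- function(pairs = list(c(0, 0.05), c(0, 0.1),
                                            c(0, 0.2), c(0, 0.4)),
                               wavelengths = seq(900, 1000, by = 5),
                               noise = noise_model(),
                               study = study_config(noise = noise),
                               depth_min = 0.5, sd_factor = 2.5,
                               ref = reference_phantom()) {
  pr <- ref_props_at(wavelengths, ref)
  crb_table <- scan_frequency_pairs(pairs, wavelengths, pr$mu_a,
                                    pr$mu_s_prime, noise)
  agg <- attr(crb_table, "summary")
  depths <- vapply(pairs, function(p)
    mean(effective_penetration_depth(pr$mu_a, pr$mu_s_prime, p[2])), 0)
  names(depths) <- vapply(pairs, function(p)
    paste0("[", p[1], ",", p[2], "]"), "")
  agg$depth <- depths[paste0("[", agg$f1, ",", agg$f2, "]")]
  eligible <- agg[agg$depth >= depth_min, ]
  if (nrow(eligible) == 0)
    stop("no frequency pair satisfies the penetration-depth threshold")
  sel <- eligible[which.min(eligible$mean_sigma_mu_a), ]
  selected_pair <- c(sel$f1, sel$f2)

  study_result <- run_increment_study(study)
  finest <- min(study_result$increment)
  ref_sd <- study_result[study_result$increment == finest, ]
  ok_inc <- vapply(sort(unique(study_result$increment)), function(inc) {
    sub <- study_result[study_result$increment == inc, ]
    all(sub$sd_pct_error[match(ref_sd$chromophore, sub$chromophore)] <=
          sd_factor * ref_sd$sd_pct_error)
  }, TRUE)
  incs <- sort(unique(study_result$increment))
  selected_increment <- max(incs[ok_inc])

  summary_text <- sprintf(
    paste0("Selected spatial-frequency pair [%g, %g] mm^-1 (lowest mean ",
           "CRB sigma_mu_a among pairs with mean effective penetration ",
           "depth >= %.2g mm) and %g-nm wavelength increment (coarsest ",
           "with percent-error sd within %.2gx of the %g-nm sd)."),
    selected_pair[1], selected_pair[2], depth_min, selected_increment,
    sd_factor, finest)
  list(crb_table = crb_table, depths = depths,
       selected_pair = selected_pair, study_result = study_result,
       selected_increment = selected_increment, summary = summary_text)
}
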