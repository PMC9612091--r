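# Shared fixtures built in code. The default 128x128 LUT and the packaged
# water/lipid basis are cached per test run since several files need them.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

test_lut <- function() cached("lut", build_lut())

test_basis <- function(grid = seq(900, 1000, by = 5)) {
  cached(paste0("basis", paste(range(grid), collapse = "_"),
                length(grid)),
         default_basis(grid))
}

# tiny two-point spectrum for hand-arithmetic tests
toy_spectrum <- function(name, wl, vals, unit = "percent") {
  chromophore_spectrum(name, wl, vals, conc_unit = unit)
}

# a small noiseless acquisition for closure tests
quiet_acq <- function(...) acquisition_spec(noise_sd = 0, ...)
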