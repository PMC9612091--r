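# sfdimap

Quantitative mapping of tissue **water and lipid content** with spatial
frequency domain imaging (SFDI) in the 900–1000 nm wavelength region.

Water and lipid dynamics mark edema, inflammation, and metabolic disease,
but few label-free, non-contact optical methods can map them spatially.
Their absorption features at 970 nm (water) and 930 nm (lipid) sit inside
the sensitivity range of ordinary silicon cameras, so a hyperspectral SFDI
system confined to 900–1000 nm can quantify both chromophores without the
shortwave-infrared detectors that earlier structured-light approaches
required. `sfdimap` implements the complete processing chain of such a
system, plus the measurement-design analyses used to choose its spatial
frequencies and wavelength sampling, and a synthetic acquisition renderer
so that every stage can be validated end-to-end without hardware. It is
aimed at biomedical-optics researchers building or analyzing SFDI-class
instruments.

## Method

For each wavelength λ and spatial frequency f<sub>x</sub>, three sinusoidal
illumination patterns shifted 120° in phase are demodulated pixel-wise to
the AC amplitude

> I = (√2/3) · √[(I₁−I₂)² + (I₂−I₃)² + (I₃−I₁)²],

and planar (f<sub>x</sub> = 0) illumination uses a white/black pattern
pair. Demodulated images are calibrated to diffuse reflectance against a
reference phantom of known optical properties:

> R<sub>d</sub>(f<sub>x</sub>) = I(f<sub>x</sub>) / I<sub>ref</sub>(f<sub>x</sub>) · R<sub>d,ref</sub>(f<sub>x</sub>).

The reflectance pair at f<sub>x</sub> = [0, 0.2] mm⁻¹ is inverted per
pixel to absorption μ<sub>a</sub> and reduced scattering μ<sub>s</sub>′
through a lookup table built from the diffusion-approximation forward
model for a semi-infinite medium,

> R<sub>d</sub> = 3Aa′ / [(μ<sub>eff</sub>′/μ<sub>tr</sub> + 1)(μ<sub>eff</sub>′/μ<sub>tr</sub> + 3A)],  μ<sub>eff</sub>′ = √(μ<sub>eff</sub>² + (2πf<sub>x</sub>)²),

with nearest-node seeding and Gauss–Newton polishing (externally computed
Monte Carlo tables can be swapped in via `read_lut()`). Finally the
per-pixel absorption spectra are unmixed by Beer's law,
μ<sub>a</sub>(λ) = Σᵢ cᵢ εᵢ(λ), via non-negative least squares over
water, lipid, and optionally the hemoglobins (the latter require coverage
below 900 nm).

Two design studies reproduce the instrument's measurement choices: a
Cramér–Rao-bound scan ranking candidate frequency pairs ([0, 0.05],
[0, 0.1], [0, 0.2], [0, 0.4] mm⁻¹) by achievable optical-property
precision, and a wavelength-increment simulation (100,000 random
water/lipid combinations, CRB-scaled Gaussian absorption noise, refits at
1/2/5/10 nm increments) quantifying the accuracy–acquisition-time
tradeoff.

## Worked example

Render a homogeneous 90% water / 10% lipid phantom with default camera
noise, then run the full chain and report a 2-mm circular ROI:

```r
library(sfdimap)
acq   <- acquisition_spec()   # 900-1000 nm, 5-nm steps, fx = [0, 0.2] mm^-1
scene <- make_scene("homogeneous", list(water = 90, lipid = 10),
                    shape = c(32, 32))
cfg <- list(
  input     = render_stack(scene, acq, seed = 1),
  reference = render_reference_stack(acq, shape = c(32, 32), seed = 2),
  rois      = list(list(center = c(16, 16), diameter = 2))
)
out <- run_process(cfg)
out$roi_report
#>   chromophore      mean       sd n_pixels n_nan roi time
#> 1       water 90.166784 2.098505      317     0   1    1
#> 2       lipid  9.870435 5.969720      317     0   1    1
```

The ROI means recover the ground truth within 0.2 percentage points; the
per-pixel sd reflects the default camera noise propagated through
inversion and unmixing. The design studies run the selection logic
explicitly:

```r
res <- run_design_studies(study = study_config(n_samples = 20000, seed = 11))
cat(res$summary)
#> Selected spatial-frequency pair [0, 0.2] mm^-1 (lowest mean CRB sigma_mu_a
#> among pairs with mean effective penetration depth >= 0.5 mm) and 5-nm
#> wavelength increment (coarsest with percent-error sd within 2.5x of the
#> 1-nm sd).
```

A thin command-line driver with `simulate`, `process`, `crb-scan`, and
`wavelength-study` subcommands lives at `inst/cli/sfdimap.R`.

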