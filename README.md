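# ductflux

Quantification toolkit for microfluidic duct-on-chip imaging assays: a
perfused endothelial microvessel cultured near an epithelial duct in a
collagen hydrogel, read out by time-lapse and multichannel fluorescence
microscopy, antibody-array densitometry, and nanoindentation. `ductflux` is
for experimentalists and image analysts who run these platforms and want the
figure-level numbers — vessel permeability, polarity angles, Ki67 fractions,
junctional actin scores, cytokine fold changes, hydrogel moduli, gradient
formation times — produced by tested, scriptable code instead of ad hoc
macros.

## What it computes

**Diffusive permeability.** A vessel of diameter *d* perfused with
fluorescent 70 kDa dextran and imaged at the mid-vessel plane obeys the wall
flux law *J* = *P*<sub>D</sub>(*c*<sub>vessel</sub> − *c*<sub>ECM</sub>).
Mass conservation over a window enclosing the vessel and perivascular gel
gives the estimator

  *P*<sub>D</sub> = (1 / (*I*<sub>init</sub> − *I*<sub>bg</sub>)) · (d*I*/d*t*) · (*d*/4),

where *I* is the window-averaged intensity, *I*<sub>bg</sub> its value
before the tracer arrives, *I*<sub>init</sub> its value immediately after
the vessel fills, and d*I*/d*t* the regression slope afterwards. The *d*/4
is the volume-to-surface ratio of a cylinder: the filling step scales with
the lumen cross-section π*d*²/4 while the flux crosses the perimeter π*d*;
dividing slope by step leaves exactly *d*/4. The derivation holds when the
step and the slope are measured on the same window-mean intensity under
depth-integrated imaging, which is the package default.

**Morphometry.** Junctional (cortical) actin is scored from a short-axis
line profile as the edge-area fraction
(*A*<sub>0–10%</sub> + *A*<sub>90–100%</sub>)/*A*<sub>Total</sub>;
Golgi polarity is the angle between the nucleus→GM130 vector and the apical
axis (0° apical, 180° basal); Ki67 fractions, vessel diameters, VE-cadherin
integrated density and sprout counts follow the standard thresholding and
annotation workflows.

**Secretome.** Duplicate-spot cytokine membranes are quantified by disk
densitometry and normalized across membranes by
((*i*<sub>test</sub> − Bg<sub>test</sub>)/(*i*<sub>EV</sub> − Bg<sub>EV</sub>)) ×
(Ref<sub>EV</sub>/Ref<sub>test</sub>), cancelling exposure differences.

**Mechanics.** Spherical nanoindentation curves are fit to the Hertz model
*F* = (4/3)(*E*/(1 − ν²))√*R* δ<sup>3/2</sup> (ν = 0.5 for an
incompressible gel) to report Young's modulus.

**Transport.** A conservative finite-volume solver simulates radial dextran
efflux across a permeable (Robin) vessel wall, and an implicit
finite-difference solver simulates growth-factor gradient formation between
the two channels, including the time for any location to reach half its
steady concentration.

**Synthetic data.** Every input above can be generated with embedded ground
truth (`generate_vessel_timelapse`, `generate_morphology_image`,
`generate_cytokine_array`, `generate_indentation_curve`), which is how the
test suite closes the loop between construction and estimation.

## Worked example

```r
library(ductflux)

# a synthetic permeability assay with known truth: 160 um vessel,
# frames every 10 s for 5 min, true P_D = 1e-6 cm/s
g   <- generate_vessel_timelapse(synthetic_vessel_spec(true_PD = 1e-6, seed = 1))
fit <- estimate_permeability(g$stack)
fit
#> <permeability_fit> P_D = 9.632e-07 cm/s
#>   step at frame 3; I_bg = 10, I_init = 37.36, dI/dt = 0.006672 a.u./s
#>   frames 3-15, R^2 = 0.9999
```

The vessel fills at frame 3 (two background frames precede the tracer), the
window mean steps from 10 to 37.4 a.u., and the post-filling slope converts
through the *d*/4 factor to 9.6 × 10⁻⁷ cm/s — within 4% of the constructed
truth; tight-barrier microvessels sit around 10⁻⁷–10⁻⁶ cm/s, so this is the
physiologic regime.

```r
# hydrogel stiffness: six noisy synthetic indentation curves at 130 Pa
fits <- sapply(1:6, function(s)
  fit_hertz(generate_indentation_curve(130, noise_sd = 2.5e-9,
                                       seed = s)$curve)$E)
s <- summarize_stiffness(fits)
sprintf("E = %.1f +/- %.1f Pa (n = %d)", s$mean, s$sd, s$n)
#> "E = 129.9 +/- 0.9 Pa (n = 6)"

# group statistics as used in figure panels
compare_groups(list(EV     = c(1.1, 0.9, 1.0, 1.2, 0.8),
                    mutant = c(1.6, 1.8, 1.7, 1.5, 1.9)))
#> <group_comparison> measurement: two-tailed unpaired t test
#>   EV           n=5   1 +/- 0.07071 (s.e.m.)
#>   mutant       n=5   1.7 +/- 0.07071 (s.e.m.)
#>   statistic = -7, p = 0.0001126
```

A config-driven batch runner (`run_pipeline`) executes all modules over a
YAML description (see `inst/extdata/demo_config.yaml`) and writes tidy CSVs,
JSON summaries, QC plots and a log; a thin CLI wrapper lives at
`inst/scripts/ductflux.R`.

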