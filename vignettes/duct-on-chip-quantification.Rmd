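---
title: "Quantifying vessel barrier, morphometry and transport in a duct-on-chip platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vessel barrier, morphometry and transport in a duct-on-chip platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductflux)
```

## The measurement problem

Microfluidic organotypic models that pair a perfused endothelial microvessel
with an epithelial duct in a collagen hydrogel are read out almost entirely
through images: a dextran time-lapse reports vascular barrier function, fixed
multichannel snapshots report polarity, proliferation and junctional
organization, antibody membranes report the secretome, and nanoindentation
reports the gel mechanics the tissues grow in. `ductflux` implements each of
those quantifications as tested, scriptable functions, together with a
synthetic-data generator that embeds ground truth so every estimator can be
validated by construction.

## Diffusive permeability from a dextran time-lapse

A vessel of diameter $d$ is perfused with fluorescent 70 kDa dextran and
imaged at the mid-vessel plane every 10 s for 5 min. The wall flux obeys

$$J = P_D\,(c_{vessel} - c_{ECM}),$$

with $P_D$ the diffusive permeability (cm/s). Writing mass conservation for a
measurement window that encloses the vessel and its perivascular gel, with
window intensity proportional to tracer mass per unit vessel length, gives
the estimator

$$P_D = \frac{1}{I_{init} - I_{bg}}\,\frac{dI}{dt}\,\frac{d}{4},$$

where $I_{bg}$ is the window mean before the tracer arrives, $I_{init}$ the
window mean immediately after the vessel fills, and $dI/dt$ the regression
slope afterwards. The $d/4$ is the volume-to-surface ratio of a cylinder: the
filling step is proportional to the lumen cross-section $\pi d^2/4$ while the
flux enters through the perimeter $\pi d$. That derivation fixes a
convention: the step and the slope must be measured on the *same*
window-averaged intensity, under depth-integrated imaging; `estimate_permeability`
therefore defaults to the window mean (`config$initial = "window"`), with a
vessel-mask variant available for sensitivity checks.

Two practical choices matter and both are configurable:

* **Filling detection.** The filling step is the largest single-frame
  increase of the vessel-mask mean; a stack whose largest jump is not clearly
  above the frame-to-frame jitter fails with "no detectable filling step"
  rather than fitting noise.
* **Fit window.** $c_{ECM}$ at the wall rises during the movie, so the
  driving difference decays and a full-movie slope underestimates $P_D$ —
  for $P_D = 10^{-5}$ cm/s, wall tracer reaches roughly a quarter of the
  lumen concentration by 5 min. Chord-projected imaging gives no direct wall
  concentration to correct with, so the default regresses only frames within
  `fit_window_s = 120` s of filling, where the driving term is still near
  its initial value; `fit_window_s = Inf` restores the full-movie fit.

Negative slopes are reported with their sign (they diagnose bleaching or
drift), and fits with $R^2$ below `r2_floor = 0.8` carry a
`low_r_squared` flag.

```{r perm, eval = FALSE}
g <- generate_vessel_timelapse(synthetic_vessel_spec(true_PD = 1e-6))
fit <- estimate_permeability(g$stack)
fit$P_D    # ~9.6e-07 cm/s on the noiseless default render
```

## Transport physics

`simulate_radial_efflux` is a conservative finite-volume solver for the gel
annulus around the vessel, in cylindrical-radial coordinates — the efflux is
radially symmetric in the cross-sectional plane, and the lumen is held at a
fixed concentration because perfusion replenishes the tracer. The permeable
wall is a Robin boundary: the wall concentration is found by matching
$P_D(c_{lumen} - c_w)$ to the diffusive flux into the first gel cell, which
is standard, second-order accurate, and testable against the analytic
constant-transfer-coefficient half-space solution (the solver agrees to
within 2% in the early-time planar limit, and conserves mass to well below
1% by construction of the finite-volume update). Explicit time stepping is
used with the stable step checked up front; an unstable user step is
rejected with the bound in the message.

`simulate_device_gradient` covers the second transport question: how growth
factor gradients form between the two channels. It solves the diffusion
equation implicitly (theta scheme, sparse LU factored once) either on a 2D
cross-section with the channels as disks — the vascular channel a fixed
source, the duct channel a sink or inert per configuration — or as a 1D
reduction along the inter-channel axis. The steady state is solved directly
from the pinned Laplacian, and the series reports the time for monitored
locations (by default the midpoint, 250 um from the source) to reach half
their steady value. The 1D reduction reproduces the linear steady profile
exactly and the half-space erfc rise time to within 0.2%. A finite-element
treatment of the full 3D device with dead-ended duct lumen is out of scope;
this module is a physics-equivalent cross-sectional stand-in, with the
default dextran diffusivity in collagen set to an order-of-magnitude
literature value of $4\times10^{-7}$ cm$^2$/s and exposed as a parameter
because solute and gel batch both move it.

## Morphometry

* **Junctional (cortical) actin.** Line profiles are drawn through the short
  axis of a cell, through the nucleus; position and intensity are normalized
  to their maxima, and the score is the fraction of trapezoidal area in the
  outer 10% at each end, $(A_{0-10\%} + A_{90-100\%})/A_{Total}$, with
  inclusive boundaries at $x = 0.10$ and $x = 0.90$ (sample points are
  interpolated onto the boundaries so the sub-areas are exact for
  piecewise-linear data). A uniform profile scores exactly 0.2; the score is
  invariant to positive scaling and reversal. Profile intensities are not
  background-subtracted before normalization by default, matching the raw
  line-profile workflow; subtract beforehand if your acquisition needs it.
* **Golgi polarity.** The angle between the nucleus-to-GM130 vector and the
  apical direction, via the arccosine of the normalized dot product —
  unsigned, in [0, 180], rotation-invariant. 0 is apical (lumen-facing),
  180 basal.
* **Ki67 fraction.** DAPI is Otsu-thresholded, components above `min_area`
  become nuclei (border-touching nuclei are excluded by default since their
  means are unreliable), and positivity is decided on the nuclear mean Ki67
  intensity. The default positivity threshold is data-driven — halfway from
  the channel median to its 99.9th percentile — which separates negative
  from positive nuclear populations without assuming absolute units; a pixel
  overlap criterion (`criterion = "pixel_overlap"`) is available because the
  original thresholding rule is a judgment call.
* **Vessel diameter.** Mask width perpendicular to the principal axis at
  three evenly spaced stations, averaged, mirroring manual width
  measurements at distinct locations.
* **VE-cadherin integrated density.** Background subtraction (grayscale
  opening as the rolling-ball analogue, or a constant), Otsu binarization,
  and the sum of background-subtracted intensity inside the mask, with the
  mask area reported alongside.
* **Sprout counts.** Annotation points are tallied per vessel and split by
  side of the axis; an optional single-linkage merge radius absorbs
  duplicate clicks. Points naming unknown vessels are returned as orphans,
  not dropped silently.

## Secretome normalization

Duplicate-spot membranes are quantified by disk means on a registered grid
(registration = mean centroid displacement of the reference spots; an
upside-down scan is handled by a layout flag). Relative secretion against
the empty-vector control is

$$\frac{i_{test} - Bg_{test}}{i_{EV} - Bg_{EV}} \times
  \frac{Ref_{EV}}{Ref_{test}},$$

with the background defined as the mean of the negative-control spots and
the reference as the positive/loading-control spots, duplicates averaged.
Both definitions are configurable through the layout because membrane
vendors differ; an upstream total-protein value (e.g. a BCA measurement) can
equally serve as the reference input. The ratio construction makes the
result invariant to per-membrane exposure, which the tests exercise
explicitly; analytes whose control signal does not exceed background are
flagged `NA` rather than producing a fabricated fold.

## Hydrogel stiffness

Force-indentation curves from a spherical probe are fit to the Hertz
relation $F = \tfrac{4}{3}\,\tfrac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$ with
$\nu = 0.5$ for an incompressible gel and, by default, $R = 50$ um and a
10 um depth — the probe and depth regime of soft collagen characterization.
Only the loading branch is fit. Without a contact-point search the model is
linear in the prefactor and solved in closed form; `fit_contact_point =
TRUE` co-fits an offset by Levenberg-Marquardt for instrument exports whose
contact point is uncertain. Six noisy synthetic curves at a true modulus of
130 Pa summarize to 130 Pa mean, the soft-collagen regime the platform
polymerizes.

## What the synthetic generator does and does not emulate

The generator exists to close the loop between construction and estimation,
not to imitate micrographs. Cells are schematic indicator ellipses with
blob organelles; the vessel render projects the simulated radial
concentration field through the optical axis so that window intensity is
proportional to tracer mass (the assumption the estimator makes); noise is
additive Gaussian, stated per channel, because the processing chain is
intensity-ratio based and largely insensitive to the noise family. Real
data add texture, uneven illumination, point-spread blur, bleaching and
segmentation ambiguity that the generator deliberately omits — so green
tests demonstrate that the estimators are correct *given* their imaging
assumptions, not that those assumptions hold on any particular microscope.
Apical axes are recorded explicitly in the truth table rather than inferred
from a rendered lumen, since the polarity angle is defined relative to that
axis and the synthetic axis is known by construction. All generated images
use 0-based pixel coordinates, origin top-left, with physical lengths via
`pixel_size`; raw intensity units are arbitrary throughout because no
camera calibration is being modeled.

Every generator is bit-reproducible from its spec and seed, and each
returns a `ground_truth` side-car recording every generating parameter.

## Numerical choices and problem sizes

Radial efflux uses a 2 um grid to a 600 um outer radius (explicit stepping
at half the stable bound); the Robin benchmark uses a 1 um grid on a 2 mm
wall radius for 25 s so the planar limit applies to better than 2%. The
gradient solver uses 5 um cells in 1D and 20 um cells in 2D (at least 8
cells across a channel is enforced). Morphology validation images are
0.5 um/px, 800–1400 px across with 10–50 cells; permeability validation
movies are 31 frames of roughly 230 x 100 px. These sizes were chosen so
the full validation suite exercises every claim in a couple of minutes on a
laptop-class core while keeping discretization error well inside each
stated tolerance; all of them scale up through the spec objects if finer
renders are wanted.

## Known limitations

Transmural advection, shear coupling, growth-factor uptake kinetics, 3D
duct-lumen transport, viscoelastic or adhesive indentation corrections,
automatic sprout detection, volumetric morphometrics and cell tracking are
all out of scope. The permeability estimator assumes a straight vessel
segment and depth-integrated intensity; strongly curved vessels or thin
optical sectioning violate the $d/4$ convention and would need a different
geometric factor.
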