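---
title: "Methods: the elliptical dose model and volume-averaging quadrature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the elliptical dose model and volume-averaging quadrature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkvol)
```

## Scope and model

`gkvol` computes volume-averaging correction factors, `k_vol`, for
detectors placed at the centre of Gamma Knife Perfexion fields. The chain
is: (1) fit the three principal-axis relative dose profiles with sums of
error functions; (2) compose them into an analytical 3D dose distribution;
(3) integrate that distribution over a parametric model of the detector's
active volume; (4) form clin/msr ratios and the volume-averaging
contribution to the TRS-483 field output correction factor.

The model deliberately ignores everything about a detector except the
shape of its active volume: the response is taken as perfectly isotropic
and uniformly weighted, so fluence, spectral and density perturbations are
out of scope. `k_vol` as computed here is the purely geometric averaging
term.

### Profile fitting

Each profile is modelled as
$D(k) = \sum_{i=1}^{n} A_i\,\mathrm{erf}\!\left(\frac{k+a_i}{b_i}\right)
+ C_0$, with amplitudes $A_i$ (%), shifts $a_i$ (mm), widths $b_i > 0$
(mm) and one global offset. The standard term counts are $n = 4$ for x/y
at all field sizes, $n = 5$ for z at 16 and 8 mm, and $n = 2$ for z at
4 mm; the z profile needs the extra flexibility at larger fields because
it is asymmetric about the XY plane (the Co-60 sources are symmetric
about the device z-axis only), and that asymmetry fades as the field
shrinks.

x/y profiles are taken as exactly rotationally symmetric: only $k \ge 0$
data enter the fit and the model is evaluated at $|k|$, which makes
$D(k)=D(-k)$ hold to machine precision rather than approximately. The z
profile is fitted over its full range with a single global erf-sum; we
found no benefit in constraining the two sides separately.

Fitting uses Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
with box bounds keeping every $b_i$ positive. The erf-sum family is badly
non-identifiable — terms can be permuted, or traded against the offset —
so convergence from a poor start can stall in flat regions. Two measures
address this:

* **Structured initialisation.** For half-range (symmetric) data the
  dominant term starts as a falling edge at the 50% crossing with width
  set from the 80–20 penumbra distance ($b = p_{80\text{–}20} /
  (2\,\mathrm{erf}^{-1}(0.6))$) and offset at half the plateau; for
  full-range data two opposed edge terms carry the flat top. Surplus terms
  start as small perturbations near the edges.
* **Deterministic multi-start.** Eight restarts with seeded jitter on all
  parameters; the best residual wins. The jitter stream comes from a
  small private linear-congruential generator so that fitting never
  disturbs the caller's RNG state.

Fit quality is always judged on predictions ($R^2$, maximum and RMS
residual), never on recovered parameters. A zero-variance profile has no
defined $R^2$ and is reported as a failed fit with the degenerate constant
model attached; non-convergence after all restarts is likewise flagged
while still returning the best model found.

### 3D composition

A single algebraic reading of the elliptical composition is used
throughout: with $\Delta\vec r$ the offset from the field centre and
$\rho = |\Delta\vec r|$,
$$D(\vec r) = \sum_{k\in\{x,y,z\}} D_k(s_k\,\rho)\,
  \left(\frac{\Delta k}{\rho}\right)^2,$$
each axis profile evaluated at the *radial distance* and weighted by the
squared direction cosine. The published renderings of this formalism are
typographically ambiguous between evaluating $D_k$ at $\rho$ or at the
coordinate component; we adopt the $\rho$ reading because it (a) reduces
exactly to each 1D profile on its axis, (b) makes the dose depend only on
$\rho$ in the XY plane whenever the x and y profiles agree — circular XY
isodoses, as observed — and (c) keeps the weights summing to one, so a
uniform set of profiles composes to a uniform field. The z profile is
evaluated at $\mathrm{sign}(\Delta z)\cdot\rho$, so its asymmetry
propagates to the two hemispheres. At $\rho = 0$ the dose is defined as
exactly 1, removing the 0/0; evaluation is continuous there along any
ray. Each profile is divided by its own value at 0, so normalization is
exact regardless of small fit error at the centre.

### Detector geometries

Chambers are modelled as a cylindrical cavity, plus a hemispherical cap
of the cavity radius on top, minus a coaxial flat-ended cylindrical
electrode rising from the cavity base; the remaining detectors are disks
or a rectangular box. The long axis is mounted along z and the *centroid*
of the active volume — the signed-volume-weighted centre of cavity + cap −
electrode — is placed at the field centre; we read "geometric centre of
the active volume" as the centroid rather than the midpoint of the
extents, since the centroid is the natural centre of a composite solid.
Per-detector reference-point offsets can be emulated by editing the
library.

Manufacturer schematics for most chambers are not public, so the shipped
library reconstructs dimensions from published constraints: nominal active
volumes (within 10%, allowing for manufacturer rounding), the PinPoint's
5 mm active length with length-to-diameter ratio 2.5, the CC04's 3.6 mm
length with ratio 0.9, the PinPoint 3D's ratio 1.23, the microDiamond's
2.2 mm × 1 µm disk, and the scintillating fibres' exact 1 mm ⌀ × 1 / 3 mm
designations. Entries carry an `approximate` flag and the YAML is fully
user-overridable; results are reproducible from the config alone.
Boundary points count as inside (`contains()`), a measure-zero choice
fixed for determinism. The electrode tip is modelled flat; available
drawings do not resolve its shape, and for the thin electrodes involved
the volume at stake is well below the 10% dimension tolerance.

### Quadrature

`k_vol = 1 / \bar D` with $\bar D$ the volume-average of the normalized
dose, computed by composite Simpson quadrature with 100 steps per
direction (tunable, must be even). The coordinate system matters more
than the step count: Simpson over a Cartesian bounding box with an
inclusion mask degrades to first-order convergence at the curved
boundary, so bodies of revolution are integrated in cylindrical
coordinates $(z, \rho, \varphi)$, radially rescaled per z-slice so the
domain boundary is exact, and composite shapes are handled as a signed
sum of smooth-segment integrals (cavity + cap − electrode). Boxes use
Cartesian coordinates directly. Consequences:

* a uniform field integrates to its volume exactly (the Jacobian is
  polynomial), so `kvol` returns 1 at machine precision there;
* doubling the steps from 100 to 200 moves `k_vol` by well under 5e-4 on
  the steepest (4 mm) fixture field — the third decimal is stable, which
  is the reporting precision;
* an independent Monte Carlo volume-average (`kvol_mc`, uniform rejection
  sampling inside the active volume) agrees with the quadrature to
  better than 1e-3 in mean dose for every shipped detector and fixture
  field; the tests pin this with 10^6 points per combination.

Reporting uses rounding half away from zero at 3 decimals
(`round_report()`); every chained quantity (ratios, k) is computed at
full precision and rounded only at the end. The shipped published tables
are treated the same way, which reproduces the self-consistent printed
ratios and k values exactly; a few printed cells were evidently chained
from unrounded intermediates not published, and the package does not try
to force agreement there.

### Validation mode

`model_error()` implements the absorbed-dose comparison used to qualify
the dose model against a treatment planning system export: both dose sets
are summed over the points inside an isodose-bounded volume (membership
decided on the *reference* dose, mirroring how such volumes are selected
in practice) and compared as $R_v = (D_{ref} - D_{model})/D_{ref}\times
100\%$. The sum is unweighted; the exports this emulates sample
approximately uniformly within the extraction range, and no point-density
weighting information is available. $R_v$ is exactly 0 when the reference
was generated by the model, is invariant under common rescaling, and
grows monotonically with fixture perturbations of the penumbra — those
properties, not any numeric agreement with a specific TPS, are what the
tests establish.

## The synthetic generator

Real vendor Monte Carlo profiles and TPS exports are not
redistributable, so the package generates its own fixtures:

* `synth_profile()` builds a flat-top profile with error-function
  penumbrae. Edge centres are calibrated (a few fixed-point iterations)
  so that after normalization to a 100% maximum the 50% crossings sit
  exactly `fwhm` apart; asymmetry scales the positive/negative penumbra
  widths by $(1 \pm s)$; noise is seeded Gaussian.
* Default fixture scales per collimator: 50% isodose diameters at the
  nominal 16/8/4 mm on x/y with penumbrae of 3.5/2.5/1.6 mm, a narrower z
  profile (12/6/3 mm FWHM, penumbrae 2.6/1.8/1.2 mm) and z-asymmetry
  0.10/0.06/0.02. These are one-time choices for field realism —
  quantitatively they make the fixture fields somewhat *steeper* than the
  vendor's, particularly along z at 4 mm, so fixture `k_vol` values are
  systematically larger than the published ones. Passing tests therefore
  demonstrate correctness of the machinery (fit quality, quadrature
  accuracy, orderings, flagging logic), not agreement with measured
  Gamma Knife data; quantitative reproduction of the published tables is
  done through the shipped constants instead.
* `generate_reference_points()` rejection-samples points whose model dose
  lies in the extraction window (default 19–99%), snaps z to a 1 mm grid
  to mimic export resolution, and can apply a multiplicative bias to
  emulate model/TPS disagreement. The device-realistic point counts used
  in the examples are 1700/783/378 for 16/8/4 mm.

## Problem sizes and determinism

The test-suite defaults are sized for a single CPU: quadrature at the
production 100 steps per axis where the claim concerns accuracy, reduced
(10–60 steps) where only table plumbing is exercised; Monte Carlo oracles
at 10^6 points in the acceptance checks and 2×10^5 in the unit tests.
Every stochastic component (multi-start jitter, noise, point sampling)
is seeded explicitly, and re-running a configuration byte-reproduces its
CSV outputs.

## Known limitations

* Single shot, centred detector, long axis along z, 90° gamma angle; no
  multi-shot superposition or off-axis placement.
* Geometry-only averaging: no wall/stem/cable, no material or density
  response weighting.
* Chamber dimensions for four of the six chambers are reconstructions
  consistent with published constraints, not data-sheet values; users
  with manufacturer drawings should override the YAML library.
* The elliptical composition is exact on the principal axes and smooth
  elsewhere, but it is an interpolation ansatz: off-axis accuracy is
  bounded by how well the real field is described by its three principal
  profiles.
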