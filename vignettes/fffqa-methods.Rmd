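---
title: "Model and methods: source modelling and planar dose calculation for FF/FFF IMRT QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fffqa)
```

# The physical model

## Head model

The treatment head is modelled as a primary point source at the target
plus an **extra-focal source**: a sum of $N$ bivariate Gaussian intensity
distributions on a plane perpendicular to the beam axis,

$$ f(x, y) = \sum_{i=0}^{N-1} \frac{A_i}{2\pi\,\sigma_{x,i}\sigma_{y,i}}
   \exp\!\left(-\frac{x^2}{2\sigma_{x,i}^2}-\frac{y^2}{2\sigma_{y,i}^2}\right), $$

with amplitudes $A_i$ relative to the primary source (weight 1).  The
plane sits at the bottom of the flattening filter for flattened (FF)
beams and at the bottom of the primary collimator for
flattening-filter-free (FFF) beams, reflecting the dominant scatterer in
each mode.  Two components suffice in practice; the shipped parameter
sets (`beam_model_library()`) use $N=2$ for all four supported modes
(6/10 MV, FF/FFF).  The $x$ axis is the cross-plane (leaf-travel)
direction and $y$ the in-plane (jaw) direction; the *anisotropy*
$\sigma_x \neq \sigma_y$ implicitly carries the collimator-exchange
effect (the different influence of the upper and lower collimator on
output), so no explicit monitor-backscatter term is needed.

Useful summaries of a source are its **central intensity density**
$f(0,0)$, its **axis-averaged half-maximum radius** (the mean of the
distances along $x$ and $y$ at which $f$ falls to half its central
value, found by bracketed root finding to $10^{-8}$ cm), and its **total
relative intensity** $\sum_i A_i$.  Removing the flattening filter makes
the source smaller, denser at the center, and weaker overall; the
relative reduction $100\,(\Sigma A^{FF} - \Sigma A^{FFF})/\Sigma A^{FF}$
quantifies the head-scatter loss.

## In-air output factors

The in-air output factor $S_c$ of a rectangular field is computed by
back-projecting the collimator edges from the calculation point onto the
source plane and integrating $f$ over the visible rectangle.  An edge at
isocenter coordinate $e$ and collimator level $z_\ell$ sits physically at
$e\,z_\ell/\mathrm{SAD}$; the ray from the point through that edge meets
the source plane at an affine function of the point coordinate
(`backproject_edge()`).  The Gaussian integral over the rectangle is the
product of error-function differences (`gaussian_rect_integral()`), so
$S_c$ evaluation is closed-form and effectively instantaneous:

$$ S_c = \frac{1 + I(\text{field})}{1 + I(10\times10)} . $$

On the modelled machine (an Elekta-like head) the MLC is the upper
collimator and defines the $x$ edges; the single jaw pair below defines
the $y$ edges.

## Off-axis ratio (FFF only)

Unflattened beams have cone-shaped profiles.  The off-axis ratio is a
rotationally symmetric fourth-degree polynomial $R(r)=\sum_k a_k r^k$ in
the radial distance at the isocenter-depth plane, applied
multiplicatively to the **total** (primary + scatter) fluence, and used
in its normalized form $R(r)/R(0)$ so its absolute scale is irrelevant.
Beyond a validity radius (default 22 cm) $R$ is held constant: a quartic
extrapolates unphysically outside the radial range covered by
commissioning profiles — the shipped 10 MV FFF polynomial, for example,
crosses zero near 24 cm.  The clamp also keeps the dose forward model
exactly linear in the coefficients, which the OAR fitting stage exploits.

## MLC detail

Per-ray primary transmission (`transmission_map()`) distinguishes:

* **open aperture** — transmission 1;
* **rounded leaf end** — within 1 cm of a tip, $L(d)=\exp(-d^{\alpha}/\beta)$
  with the fitted $\alpha=0.70$, $\beta=0.24$ (both energies).  Of the
  typographically plausible readings of the published tip law, only this
  one decays to $\approx 1.6\%$ at 1 cm, consistent with the ~1% bulk
  transmission it must hand over to; the alternatives give 85% or 6.6%
  at 1 cm, which are physically implausible.  The choice is recorded in
  the model files so it remains swappable;
* **leaf body** — bulk factor 0.01 beyond the tip zone;
* **interleaf strips** — 0.03 cm strips between two *closed* neighbouring
  leaves carry the interleaf factor (0.01), replacing bulk;
* **tongue-and-groove strips** — where an exposed row abuts a shielded
  one, a strip of the projected tongue-and-groove width (0.026 cm)
  multiplies the open-side fluence by 0.01.  Whether this factor should
  multiply or replace the open fluence is not settled; multiplication
  reproduces the expected underdose notch of the projected width without
  modelling the leaf cross-section;
* **jaw shadow** — points outside the jaw opening are multiplied by the
  jaw transmission (default: the bulk factor).

Strips narrower than the 1 mm lattice are *area-averaged* into their
pixel rather than demanding a finer grid; the small approximation of
using the mean of the two adjacent row transmissions as the under-strip
baseline is confined to sub-pixel widths.  Scatter through closed leaves
is neglected (the product of a $\le 10\%$ scatter amplitude and a
$\le 1\%$ transmission is below every tolerance used here).

## Fluence and dose

The fluence of a segment at a point is the primary transmission plus the
extra-focal integral over the rectangles visible through the open leaf
rows (`visible_rects()`), all times the normalized OAR.  Because the
back-projection is affine in the point coordinate, the scatter term
separates into per-row outer products of $x$ and $y$ error-function
factors, which is what makes full-plane evaluation fast.  Beams are
MU-weighted sums of segment fluences.

Planar dose is the 2D linear convolution of the fluence with an
analytical dose deposition kernel, a sum of three circular Gaussians
$k(x,y)=\sum_i \frac{A_i}{2\pi\sigma_i^2}e^{-(x^2+y^2)/2\sigma_i^2}$
describing in-water energy transport at the QA depth.  The kernel is
sampled at pixel centers out to $4\sigma_{\max}$ and renormalized so its
discrete sum equals the analytic $\sum_i A_i$, removing discretization
bias at 1 mm spacing; convolution is FFT-based (zero-padded, sizes
rounded to 2-3-5-smooth numbers) and agrees with direct summation to
$10^{-10}$.  For single scan lines, `dose_profile_line()` exploits the
separability of each Gaussian component (a weighted collapse across the
perpendicular axis followed by a 1D convolution) to obtain the same
result without the full-plane transform — this is what makes iterative
profile fitting affordable.

Inverse-square and depth effects are not modelled: the scope is a single
QA plane at fixed SSD/depth, and those factors are absorbed into the
relative normalization.

## Detector volume averaging

Scanned profiles are smoothed by the finite chamber volume (VAE), which
broadens penumbra by 2–3 mm for typical chambers.  Computed profiles are
therefore convolved with a Gaussian detector response before any
comparison with "measured" profiles (`apply_detector_response()`).  The
default width $\sigma = 0.20$ cm is an assumption representative of a
CC13-class chamber — no published value is available — and is
configurable; consequently any profile-level comparison against scanned
data is only as absolute as that width.  $\sigma = 0$ disables the
correction.

## Gamma comparison

`gamma_index()` implements the 2D gamma test with a percent
dose-difference criterion (local or global), a distance-to-agreement
(DTA), and a low-dose threshold relative to the reference maximum.  The
search is an interpolated exhaustive scan: the evaluated plane is
bilinearly resampled on a 0.1 mm lattice within a disk of three DTA
radii, which keeps the gamma error below 0.01 at 1 mm grids and is
directly verifiable against a brute-force oracle (the test suite does
exactly that).  By the diode-array convention the *reference* is the
measurement and the *evaluated* plane the calculation; sparse arrays are
represented as planes with `NA` at non-detector positions.  Points below
the threshold are excluded from the evaluated count.

# Commissioning

Parameters are estimated in four stages, mirroring how a physicist would
commission the model, each by bounded Levenberg–Marquardt least squares
(`minpack.lm`) with seeded multistarts (5 for the source, 3 for the
kernel; convergence at relative cost change $10^{-12}$ or 300
iterations):

1. **Source from $S_c$** (`fit_source()`): amplitudes and per-axis sigmas
   minimize the percent $S_c$ error over square fields 3–35 cm and
   rectangular families with one side fixed at 10 cm; fields smaller than
   3×3 cm² are rejected (source occlusion invalidates the model there).
   Bounds: $A_i \in (0, 0.5]$, $\sigma \in [0.05, 20]$ cm; the default
   start pairs a broad (3 cm) and a narrow (0.8 cm) component.
2. **OAR from large fields** (`fit_oar()`): since dose is linear in the
   polynomial coefficients, the degree-4 OAR is recovered *linearly*: the
   five basis doses of $\text{fluence}\cdot r^k$ are computed once
   through the full VAE-convolved forward model and the coefficient
   vector is the null-space direction (smallest singular vector) of the
   stacked normalized-profile equations.  Only in-field samples at least
   1 cm inside the field edges enter.  This is deterministic, exact on
   noise-free data, and insensitive to the provisional kernel used at
   this stage (the test suite perturbs the provisional $\sigma_0$ by
   ±20% and requires recovery within 0.5%).
3. **Kernel from in-plane profiles** (`fit_kernel()`): the jaw-defined
   ($y$) edges are free of leaf-end effects, so 5–30 cm square in-plane
   profiles determine the three kernel components.  The ordering
   $\sigma_0<\sigma_1<\sigma_2$ is enforced by disjoint boxes
   ($[0.05,0.6]$, $[0.6,3]$, $[3,15]$ cm).  Because every profile is
   normalized to its central axis, only *relative* component weights are
   identifiable; the absolute kernel scale is a free direction that
   relative dosimetry never uses.
4. **Leaf end from cross-plane profiles** (`fit_leaf_end()`): with the
   kernel frozen, $\alpha, \beta \in (0, 5]$ are fitted to the
   leaf-tip-defined ($x$) edges.  The extra-focal scatter map of each
   field is cached across iterations; only the thin tip-transmission band
   is recomputed.

The stage routing is enforced (in-plane profiles only for the kernel,
cross-plane only for the leaf end) because fitting the kernel on
tip-defined edges would absorb leaf-end transmission into the kernel
width.

**Conditioning.**  $S_c$ ratios pin down the *visible* scatter tightly
but the raw amplitude sum only loosely: a Gaussian narrower than the
smallest field's visible rectangle (or much broader than the largest)
trades amplitude against width at nearly constant cost.  On noise-free
data the fit recovers the generating parameters essentially exactly; at
a realistic 0.1% measurement repeatability the fitted $\Sigma A_i$ can
deviate by 10–25% between noise realizations even though predicted
$S_c$ — including held-out validation fields — stays at the noise level.
Summary metrics of a *fitted* source should therefore be read with that
conditioning in mind; the shipped parameter sets are not affected.

# Synthetic data

The generators (`make_sc_dataset()`, `make_profiles()`,
`make_imrt_plan()`, `make_measurement()`) emulate a commissioning and QA
session without any measured input:

* $S_c$ menu: squares 3–35 cm plus the fixed-10 rectangular families for
  fitting and fixed-4 families as held-out validation (held out *by
  construction*: no validation field appears in the fit block).
  Multiplicative Gaussian noise (default 0.1% — instrument
  repeatability), renormalized to the noisy 10×10 reading as in a real
  session.
* Profiles: VAE-convolved, central-axis-normalized square-field scans at
  the standard QA geometry (10 cm depth, 90 cm SSD), 1 mm step, 0.5%
  default noise.
* Plans: step-and-shoot segments built from smooth random walks of
  per-row openings on a 0.5 cm leaf bank with conformal jaws, honoring
  the planning constraints (≤ 70 segments, ≥ 4 cm² open area per
  segment; a segment is redrawn up to 1000 times before the generator
  gives up with the offending seed reported).
* Measurements: the calculated plane sampled on a staggered 1 cm
  diode-array lattice (represented as a half-pitch grid with `NA` at
  empty sites) with multiplicative noise.

All generators are bit-reproducible given a seed.  What they do **not**
emulate: diode dose-rate dependence, source occlusion for sub-3×3 cm²
fields, depth variation, beam spectrum and hardening, kernel tilting,
and any measurement drift that is not white multiplicative noise.  A
passing synthetic QA loop therefore demonstrates the *internal
consistency* of the pipeline at realistic noise levels, not agreement
with a physical machine.

# Numerical choices and problem sizes

* Grids: 1 mm spacing throughout (the QA dose-grid convention); fluence
  grids for rectangular-field profiles extend 5 cm beyond each field
  edge, so the part of the broadest kernel tail ($\sigma_2 \approx
  8.4$ cm) reaching in from outside the grid is neglected consistently
  in generation and fitting.
* Geometry defaults (no published values exist): SAD 100 cm, MLC at
  33 cm, jaws at 43 cm, source plane at 12.5 cm (FF) / 6.0 cm (FFF) from
  the target, 0.5 cm leaves.  All are configuration fields, recorded in
  every file header.
* Commissioning field menus in the shipped tests: OAR from 30 and 40 cm
  squares; kernel from 5/10/20/30 cm in-plane; leaf end from
  cross-plane profiles.  The full staged pipeline on this menu runs in
  well under a minute on one core.
* Tie-breaks and degenerate inputs: abutted (closed) leaf tips leak
  through the rounded-end law, which is physical; a fully closed segment
  contributes only transmission; an empty visible region in $S_c$
  degrades to the primary-only ratio with a warning; zero-MU segments
  are skipped; `half_max_radius()` reports degenerate parameter sets
  that place the half-maximum beyond 50 cm.

# Known limitations

* Planar, fixed-depth, homogeneous water only; no 3D dose, no
  heterogeneity.
* The FF parameter sets ship with the same-nominal-energy FFF kernel as
  a stand-in (no FF kernel was published); FF planar dose is therefore
  nominal, while FF $S_c$ and source metrics are exact to the published
  parameters.
* Absolute calibration is a single optional scalar, not modelled physics.
* The collimator-exchange and $S_c$-spread *orderings* between FF and
  FFF reproduce published behaviour, but their magnitudes depend on the
  assumed head geometry.
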