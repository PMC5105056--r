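---
title: "Characterizing AFM tip shape and tracking tip wear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing AFM tip shape and tracking tip wear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipshape)
```

## The problem

In atomic force microscopy the recorded image is never the bare sample
topography: it is the grayscale morphological dilation of the surface by the
(reflected) tip shape. The apex radius of the tip therefore sets the image
resolution, and in force spectroscopy it sets the contact mechanics. Tips
wear during scanning, and on hard, high-roughness polycrystalline samples
(e.g. ultra-nanocrystalline diamond) wear can be exploited deliberately: it
broadens the apex gradually while keeping it rounded, so controlled wear is
a way of *shaping* tips of different radii with identical cantilevers.

`tipshape` implements the analysis chain for such experiments:

1. **Height-map handling** — GSF/TIFF/CSV input and output (all heights in
   nm internally), R_rms roughness, and raster kinematics (sliding distance
   and velocity of the tip over the sample).
2. **Preprocessing** — per-line polynomial flattening and Gaussian low-pass
   filtering, plus robust spike/discontinuity rejection.
3. **Morphology** — dilation (image formation), erosion (surface recovery),
   and blind tip reconstruction (BTR).
4. **Tip geometry** — end radius by circle + sphere fitting, open
   sphericity, disc-method volumes, and worn-volume overlays.
5. **Fast in-situ tracking** — parabolic fits of individual peaks in
   fast-axis line profiles, and maximum-likelihood decomposition of the
   resulting radius distribution into a normal (tip) plus lognormal
   (surface) convolution (the NLN model).
6. **Synthetic data** — parametric surfaces, tips, images and wear
   sequences, so the whole chain is testable without instrument data.

## Image formation and blind reconstruction

With the tip stored as an apex-normalized height bump $T(u) \le 0$,
$T(0) = 0$, the contact condition of a down-pointing tip gives the image

$$I(x) = \max_u \left[ S(x+u) + T(u) \right],$$

so a delta-spike sample images the tip reflected through its apex. The
adjoint erosion $\min_u [I(x-u) - T(u)]$ recovers an upper bound on the
surface, with equality wherever the apex touched.

Blind reconstruction finds the *least upper bound* tip consistent with an
image of an unknown surface. For every image pixel $x$ with (unknown)
contact offset $v$, every tip pixel $p$ obeys
$T(p) \le T(v) + I(x + v - p) - I(x)$, and the apex pixel additionally
forces $T(v) \ge I(x) - I(x+v)$. Our iteration starts from the bluntest
candidate (flat, 0) and repeatedly carves the estimate down using the first
family of constraints, restricted to contact offsets that are admissible
under the second. The admissibility filter matters: without it the
relaxation provably stalls at the flat tip on a single-spike image (the
constraints decouple and a flat tip with surface = image explains the data
pointwise). Numerically, contacts frequently sit *exactly* on the
admissibility boundary in noiseless morphology, so a 1e-7 nm grace keeps
float rounding from dropping the true contact; a user-facing
`threshold_nm` absorbs real pixel noise the same way. Iteration stops when
no tip pixel moves by more than 1e-3 nm.

Properties we verify (against an independent brute-force max-plus/min-plus
oracle): the Galois inequalities of closing and opening, exact recovery of
a tip imaged over a delta spike, the outer-bound guarantee at threshold 0,
and invariance under constant image offsets. Simulated images must have
their border (half a tip width, where dilation support is truncated)
cropped with `crop_border()` before reconstruction — a physical scan has no
such border.

## Tip geometry metrics

* **End radius** $R_t$: the height contour `depth` (default 15 nm) below
  the apex is extracted by sub-pixel interpolation, a circle is fitted to
  it (algebraic Kåsa least squares — deterministic and adequate at
  instrument sampling of ~2.4 nm/px), and the sphere through that circle
  and the apex has radius $R_t = (r_c^2 + d^2) / (2d)$. A spherical apex
  returns its own radius at any depth; a paraboloid of apex curvature
  radius $R$ returns $R + d/2$; a 45° cone returns $d$ — the metric is a
  sphere-equivalent, not a curvature estimate.
* **Open sphericity** $\Psi_o = (18\pi)^{1/3} V^{2/3} / A$, with $V$ by
  trapezoidal integration of horizontal cross-section areas (256 levels by
  default) and $A$ by triangulation of the height grid (two triangles per
  cell, included when the vertex-mean height is above the cutoff; a strict
  comparison keeps a plateau exactly at the cutoff from contributing).
  $\Psi_o = 1$ for an open hemisphere; for a paraboloid measured from the
  apex down to its apex radius of curvature the analytic value is
  $18^{1/3} \cdot 1.5 / (3\sqrt{3} - 1) = 0.9368$. The default measurement
  depth is the tip's own end radius. $\Psi_o$ is scale invariant.
* **Worn volume**: fast- and slow-axis profiles of the unworn and worn tip
  are overlaid by searching the vertical offset (worn apex at or below the
  unworn) that maximizes occupation subject to the worn width never
  exceeding the unworn width at any height. Because occupation is monotone
  in the offset, the optimum is the smallest feasible offset; a coarse
  0.1 nm scan is refined by bisection at the feasibility boundary. Volumes
  are disc-method integrals down to the depth where the widths first agree
  (within one pixel by default), averaged over the two axes.

## The NLN tracking model

Each fast-axis line profile is scanned for peaks with a topographic
prominence of at least 20 nm on *both* sides (the stricter of the two
possible readings of "height difference with neighbouring minima"). Each
peak is fitted with a parabola $y = ax^2 + bx + c$ over the contiguous
samples within 15 nm below its apex — the window is truncated at an
intervening local minimum so a neighbouring peak's flank never leaks in —
and contributes a radius $1/(2|a|)$. Non-concave or under-sampled fits are
rejected and counted in QC statistics rather than raised as errors. The
abscissa is centred on the apex sample for conditioning; the radius is
origin invariant.

A measured peak radius is (to good approximation for locally spherical
grain apices) the sum of the tip radius and the grain apex radius, so the
sample is modelled as $R = T + S$ with $T \sim N(\mu_t, \sigma_t)$ (tip)
and $S \sim \mathrm{LogN}(\mu_\ell, \sigma_\ell)$ (surface grain
curvature; lognormal is the standard grain-size model for crystalline
materials). The density is computed by numerical convolution on a uniform
grid with step $\min(\sigma_t, e^{\mu_\ell}\sigma_\ell)/10$ (capped at
$2^{16}$ points; a lognormal narrower than one grid step is treated as a
point mass at its mean, which reproduces the shifted-normal limit to
1e-3), then interpolated linearly at the observations.

Fitting choices, all deterministic so results are exactly reproducible:

* **Surface calibration** (`fit_nln_surface`) maximizes the summed
  log-likelihood over several calibration samples with
  $(\mu_\ell, \sigma_\ell)$ shared and per-set normal parameters free
  (the natural reading of a "global" surface fit), by quasi-Newton
  (`nlminb`) over the joint parameter vector from three deterministic
  starts that attribute 30/50/70% of the pooled median radius to the
  surface.
* **Tip fits with fixed surface** (`fit_nln_tip`) use Nelder-Mead from a
  moment-matched start plus the documented grid
  $\mu_t \in \{10, 20, 35, 50\}$ nm, with $\sigma_t$ log-transformed.
  Radii outside (1, 500) nm are excluded first as parabola-fit artifacts;
  at least 50 radii are required.
* **Confidence intervals** on $\mu_t$ are 95% profile-likelihood intervals
  (log-likelihood drop of 1.92), assuming the surface parameters are
  exact — surface uncertainty is deliberately not propagated.
* `track_wear` applies the fixed-surface fit per image section (six
  contiguous row blocks by default; the first five take
  `floor(rows/6)` rows, the last the remainder) and annotates each with
  the cumulative sliding distance at the section midpoint (trace +
  retrace). Failed sections are flagged, not fatal.

One deliberate quirk: sliding *distance* counts trace and retrace
(1024 lines × 2 × 2.5 µm ≈ 5.1 mm) while the *velocity* is the customary
one-way figure (0.2 Hz × 2.5 µm = 0.5 µm/s). The two conventions are
inconsistent with each other but match what instruments report, so both
are reproduced as printed and flagged in the documentation.

## What the synthetic generator does and does not emulate

`generate_surface` places Poisson-distributed spherical-cap grains (apex
radii lognormal, default $\mathrm{LogN}(\log 15, 0.5)$ in nm; apex heights
uniform over 20–110 nm; 350 grains/µm² at 2.44 nm/px), resolved by
pointwise maximum over a flat base. The defaults were chosen once to land
in the R_rms ≈ 24 nm regime of a hard polycrystalline surface with sharp
apices, and are deliberately not tuned per experiment. Spherical caps make
the additive tip + grain radius decomposition exact at the apex, which is
precisely the assumption the NLN model makes — so parameter-recovery tests
validate the estimator, not the model's adequacy on real facetted grains.
The generator also does not emulate feedback/PID artifacts, thermal drift,
scars, or surface wear; images carry optional white noise and per-line
offsets only. Wear is modelled geometrically (a spherical apex of linearly
growing radius blended into a fixed cone, so material is only removed),
not through any attrition physics.

One genuine limitation the synthetic testbed exposes is worth spelling
out: the tip/surface decomposition of image-derived peak radii is only
*gauge*-identified. A line profile that misses a bump's apex slices the
bump off-centre and reports a smaller radius, and the parabola fitted over
a fixed 15 nm window underestimates a circular arc (by ~19% when the
window is half the radius) — both effects act multiplicatively on the
*sum* of tip and grain radius, which the additive NLN model cannot
represent exactly. Real measurement campaigns fix this gauge by
calibrating the surface parameters on images taken with fresh tips of
known nominal radius; the end-to-end test fixtures do the synthetic
analogue, solving for the lognormal location that makes the fixed-surface
fit return a 25 nm reference tip's radius exactly, and then checking
genuine transfer to 15 and 40 nm tips. The fixture surfaces are dense,
tall and sharp-grained (~1000–1800 grains/µm², apex radii
LogN(log 8, 0.5), heights 30–120 nm) so that neighbouring grains occlude
off-apex slices — the same geometric reason the method performs well on
real ultra-nanocrystalline diamond.

Consequently, passing tests show that the estimators recover what the
model assumes, at instrument-like sampling and realistic roughness; they
do not certify behaviour on facetted, anisotropic or contaminated real
surfaces.

## Numerical choices and degenerate inputs

* Heights are nm everywhere; GSF stores metres and is converted on load.
  GSF data are 32-bit floats (~1e-7 relative quantization); 16-bit TIFF
  quantizes to range/65535 and records the range in a JSON sidecar.
* Loaders reject non-finite pixels; `fill = TRUE` substitutes the line
  median explicitly. Silent interpolation would corrupt roughness
  statistics.
* Flattening fits each line's baseline on its lowest 80% of pixels
  (`exclude_fraction = 0.2`) so tall peaks do not bias it; the paper-side
  software's exact settings are unknown, and order 1 with 20% exclusion is
  standard practice. Low-pass: Gaussian, σ = 1 px, reflective borders
  (DC-preserving up to boundary effects; a constant map is exact).
* Apex ties in `tip_model` break to the pixel nearest the grid centre.
* A constant image yields a flat, warning-flagged reconstruction;
  `end_radius` refuses tips shallower than the requested depth or contours
  that exit the grid.
* The NanoScope-style "sigma mult" rejections are reimplemented as
  documented robust rules (line median ± 7·MAD for spikes; fast-axis
  gradient beyond 3·MAD of the global gradient for discontinuities, the
  more deviant endpoint of the gradient being replaced). On a clean
  Gaussian map the gradient rule flags ~2·Φ(−3) ≈ 0.27% of pixels — that
  tail mass is the theoretically expected behaviour of the rule, and what
  the tests assert.

## Problem sizes used in the test suite

The suite simulates at reduced but instrument-like scales chosen as
representative conditions: 64–148 px fields for morphology oracles and
reconstruction (2–4 nm/px), 3 × 3000 radii for calibration recovery,
800–1500 radii per section for CI coverage and wear tracking, and ten
end-to-end images for the reconstruction-vs-tracking agreement check. The
1024 × 1024, 2.5 × 2.5 µm geometry of a real experiment appears directly
in the kinematics and sectioning arithmetic, which are resolution-exact.

## Known limitations

* BTR returns an outer bound; on surfaces without sufficiently sharp
  features it overestimates the tip (our synthetic surfaces are calibrated
  sharp, mirroring the choice of high-roughness samples in practice).
* The worn-volume overlay is 1-D (two apex profiles), not a full 3-D
  registration.
* NLN confidence intervals condition on the calibrated surface; surface
  misestimation shifts all tracked radii coherently.
* The peak-fit window truncates at the first local minimum, so unsmoothed
  high-frequency noise shortens windows; apply `lowpass()` first.
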