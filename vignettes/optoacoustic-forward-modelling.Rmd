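---
title: "Optoacoustic forward modelling and far-field depth-profile inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optoacoustic forward modelling and far-field depth-profile inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6, fig.height = 4)
library(oasim)
```

## The physical model

A short laser pulse absorbed in a medium deposits a volumetric energy
density $W(\mathbf r)$ which, under stress confinement (pulse much shorter
than the acoustic relaxation time), acts as an instantaneous pressure
source. The resulting transient at a field point $\mathbf r_D$ is given by
the optoacoustic Poisson integral: the pressure is the time derivative of a
spherical-shell integral of $W(\mathbf r')/|\mathbf r_D-\mathbf r'|$ over
the source volume, the shell radius growing as $ct$.

`oasim` specializes this to optically layered but acoustically homogeneous
media, the situation of melanin-doped hydrogel tissue phantoms and, more
loosely, of layered skin. Then $W$ factorizes into a lateral beam profile
and an axial Beer–Lambert profile,

$$W(\mathbf r) \;\propto\; f_I(\rho)\, g(z), \qquad
  g(z) = \mu_a(z)\,\exp\Big\{-\int_0^z \mu_a(z')\,dz'\Big\},$$

with $\mu_a(z)$ piecewise constant over the layer stack and a top-hat beam
$f_I(\rho)=1$ for $\rho\le a$, $\exp\{-(\rho-a)^2/d^2\}$ beyond. Layer
intervals are half-open $[z_{\rm start}, z_{\rm end})$ so $\mu_a$ is
single-valued at boundaries; gaps (clear layers) are allowed, overlaps are
rejected.

All lengths are in cm, absorption in cm$^{-1}$. Signal axes are propagation
distance $ct$ (cm) and amplitudes are arbitrary units: the product of
fluence, Grüneisen parameter and inverse sound speed is folded into one
constant, conventionally $4\pi$ so it cancels the Poisson prefactor. The
speed of sound never enters the core; `ct_to_time()` converts axes when a
value (default $1.5\times10^5$ cm/s, soft tissue) is supplied.

## The fast solver

In cylindrical coordinates centred on the detector the azimuthal integral
of the beam profile can be tabulated once per ring radius,

$$F_D(\rho_i) = \rho_i \sum_j f_D(\rho_i, \phi_j)\,\Delta\phi,$$

which for an on-axis detector collapses to the closed form
$F_D(\rho_i)=2\pi\rho_i f_I(\rho_i)$. The remaining $(\rho, z)$ sum treats
the delta constraint of the Poisson integral as an indicator: each
quadrature cell deposits $F_D(\rho_i)\,g(z_k)\,\Delta\rho\,\Delta z/r$ into
the propagation-distance bin containing $r=\sqrt{\rho_i^2+z'^2}$, where
$z'$ is the axial source–detector distance. A central finite difference
over $ct$ then yields the pressure. The cost is
$O(N_\rho N_\phi + N_\rho N_z)$, and only $O(N_\rho N_z)$ on axis.

Numerical choices:

* **Quadrature nodes** sit at cell midpoints,
  $\rho_i = (i+\tfrac12)\Delta\rho$, $z_k=(k+\tfrac12)\Delta z$. The index
  offset is genuinely open in the discretization; midpoints avoid the
  degenerate $\rho=0$ ring and halve the boundary bias of the rectangle
  rule.
* **Bin width** defaults to $\max(\Delta\rho, \Delta z)$ in $ct$ units.
  Bins finer than the spatial quadrature cannot add information; they only
  add shot-like binning noise that the derivative amplifies.
* **Bins are half-open**; a distance exactly on an edge goes to the higher
  bin. The bin lattice is anchored at $ct=0$, so two solvers sharing a bin
  width sample the same axis.
* **Pre-derivative smoothing**: the delta-to-indicator discretization
  leaves staircase artifacts, so a short 3-bin moving average is applied to
  the binned record before differentiation. Its support stays below the
  foil-averaging window, so it cannot alter any feature the detector model
  could resolve; `smooth_bins = 1` disables it.
* **Causality** holds up to the smoothing support: the record is
  identically zero more than a few bins (derivative stencil, pre-smoothing
  and half a foil window) before the earliest arrival $|z_D| + z_{\rm first}$.

The brute-force Cartesian solver (`oa_solve_cart()`) voxelizes the source
volume and bins $W\Delta V/r$ voxel by voxel — $O(N_xN_yN_z)$, no
symmetry exploited. It exists to validate the fast solver: the two share
only the binning/derivative back end, and agree on the two-layer test
scenarios to better than 5% relative $L_\infty$ after a least-squares
amplitude match (the default oracle grid, $300\times300\times75$, is
deliberately desk-scale; near-field detection points a few hundred
micrometres from the surface need finer voxels relative to their distance,
e.g. $900\times900\times300$).

## Detector model

The finite thickness $\Delta w$ of the transducer foil smears the
pressure over the transit time $\Delta w/c$; `foil_average()` implements
this as a centred moving mean over $\Delta w$ in $ct$, rounded to an odd
bin count (50 μm → 0.005 cm → 5 bins at the default grid). At record
edges the window shrinks symmetrically instead of zero-padding, which
avoids spurious edge transients in short records. Moving averages never
increase the maximum amplitude. The same utility backs
`smooth_measured()` for digitized voltage traces (20 ns at 2 GS/s → 40
samples), and `amplitude_calibration()` provides the least-squares scalar
that maps arbitrary-units simulations onto a measured trace.

`to_retarded_depth()` shifts the axis to the retarded signal depth
$c\tau = ct + z_D$, which is zero at the absorber surface — the natural
axis for reading layer boundaries off a signal.

## Near field, far field, and the diffraction parameter

The regime of a detection point is classified by
$D = 2|z_D|/(\mu a_0^2)$ with $\mu$ the thickness-weighted mean absorption
over the absorbing layers only and $a_0 = 1.25\,a$. Averaging over the
absorbing layers (rather than the full computational depth) is the only
reading consistent with the full set of printed regime values of the
two-layer scenario; with it, one effective product $\mu a_0^2 \approx
0.527$ cm reproduces all four classified distances within rounding.

```{r diffraction}
st <- oa_stack(data.frame(z_start = c(0, 0.05), z_end = c(0.05, 0.1),
                          mu_a = c(10, 20)), L_z = 0.15)
diffraction_parameter(st, oa_beam(0.15, 0.15 / 4), c(-0.04, -0.2, -4, -5))
```

Near-field signals ($D<1$) carry an extended compression phase that traces
$g(z)$ along the axis; far-field signals ($D>1$) are derivative-like — a
step up in $\mu_a$ appears as a compression peak, a step down (or the
absorber end) as a rarefaction dip. `extract_features()` locates these
extrema with a prominence threshold defaulting to 5% of the peak
amplitude: above the binning noise, below the smallest feature of interest
in the bundled scenarios.

One caveat for shape comparisons: the simulated signal has passed the foil
window, so the profile it can trace is $g$ blurred by that same window.
Tests of the "NF traces $g$" property therefore correlate the signal with
the foil-blurred profile; against the raw discontinuous $g$ the smeared
jumps alone dominate the residual.

## Far-field inversion

In the limit $D\gg1$ the transient approaches the temporal derivative of
the initial acoustic stress profile $p_0(z)\propto g(z)$, so integrating
the signal over $c\tau$ recovers an estimate $p_{0,\rm FF}$. The
implementation integrates forward from the first sample (the far-field
leading compression makes the integral positive over the absorber; no sign
flip), clips the reconstruction to $c\tau\in[0, L_z]$ where the exact
profile is defined, normalizes both profiles to unit sample sum, and
scores with ${\rm MSE}=\sum_i[p_0(z_i)-p_{0,\rm FF}(z_i)]^2/N_z$ after
linear interpolation onto the exact grid.

`mse_sweep()` repeats this over detector distances. For the PIII phantom
the MSE decreases monotonically with $|z_D|$: the reconstruction error is
dominated by the smearing of the sharp S/M boundary over the shell
aperture, whose width scales as (lateral beam extent)$^2/(2\,|z_D|)$ plus
a floor set by the foil window and bin width. Because the squared error of
a smeared discontinuity grows linearly with the smear width, the
improvement between moderate and deep far field is a factor of a few in
this model — the gain from $z_D=-0.3$ to $-2.0$ cm measures ≈3.5 — and
with the foil removed the deep-far-field MSE drops further, showing the
temporal averaging is what limits the $|z_D|\to\infty$ residual.

## Study conditions and problem sizes

The bundled presets (`oa_preset()`) are the package's fixture source; all
their parameters are the printed study conditions: the two-layer scenarios
(10/20 cm$^{-1}$ over 0.05 cm each, beam $a=0.15$, $d=a/4$, detections at
$z_D=-0.04$ and $-4$ cm; `fig3b` reversed), the off-axis series
($x_D\in\{0, 0.1, 0.2\}$, $z_D\in\{-0.2,-1,-5\}$) and the phantom presets
PI–PIII with their detector-relative layer coordinates (shifted by
$|z_D|=0.3$ cm into surface form), beam radii 0.054/0.056/0.08 cm and
edge ratios $R=d/a$ of 1.5/1.2/1.2. $R=1.5$ makes the PI edge wider than
its flat top; unusual, but taken at face value from the printed setup.
The default cylindrical grid is the printed
$(L_\rho, L_z)=(0.3, 0.15)$ cm, $(N_\rho, N_\phi, N_z)=(6000, 360, 150)$;
phantom presets keep those spacings while extending the radial and axial
domains over their wider beams and deeper stacks. The `fig4` preset
deliberately keeps the printed radial domain $L_\rho=0.3$, which clips the
outermost edge of the laterally shifted beam for $x_D=0.2$ — that is the
domain on which the off-axis series was defined, and the far-field
off-axis smearing is sensitive to it.

One full-grid solve takes well under a second, so tests and the
acceptance script run the study grids directly; only the Cartesian oracle
is scaled to the reduced grids quoted above, its role being error
bounding rather than production.

## What the generator does and does not emulate

The presets emulate the simulation side of the study: ideal point
detector, normal plane-wave incidence, non-scattering layers, homogeneous
acoustic properties, no acoustic attenuation. They do not emulate oblique
incidence and refraction, the finite 1 mm active detector area,
transducer/pre-amplifier electrical response, or measurement noise —
passing tests therefore validate the numerics and the model's internal
consistency, not agreement with any particular measured voltage trace
(none are bundled). `amplitude_calibration()` and `smooth_measured()`
exist precisely for users who bring their own traces.

## Known limitations

* Homogeneous speed of sound only; no attenuation or dispersion
  correction, no time-reversal inversion.
* The far-field inversion is a single-detector approximation, not
  tomography; its resolution is bounded by the foil window and the shell
  aperture, as quantified by `mse_sweep()`.
* Feature extraction is a prominence filter on local extrema; heavily
  oscillatory records from too-fine bin widths should be smoothed (or the
  bin width left at its default) before trusting the feature list.
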