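# oasim — optoacoustic pressure transients in layered absorbing media

`oasim` simulates the optoacoustic (photoacoustic) pressure transients
generated when a short laser pulse is absorbed in an optically layered,
acoustically homogeneous medium — the situation of melanin-doped hydrogel
tissue phantoms used as skin/melanoma models — and approximately inverts
far-field transients back to the initial acoustic stress depth profile.
It is aimed at people building or analysing backward-mode optoacoustic
depth-profiling experiments who need a fast, validated forward model for
plane-layered absorbers.

## The model

Under stress confinement the pressure at a detection point
$\mathbf r_D$ is the optoacoustic Poisson integral

$$p_D(t) \;\propto\; \partial_t \int_V
  \frac{W(\mathbf r')}{|\mathbf r_D - \mathbf r'|}\,
  \delta(|\mathbf r_D - \mathbf r'| - ct)\, d\mathbf r',$$

with the deposited energy density factorizing for non-scattering layered
media into a top-hat beam profile and a Beer–Lambert depth profile,
$W \propto f_I(\rho)\,g(z)$,
$g(z)=\mu_a(z)\exp\{-\int_0^z\mu_a(z')dz'\}$.

The package provides:

* **`oa_solve()`** — the fast solver: cylindrical coordinates centred on
  the detector, precomputed azimuthal weights
  $F_D(\rho_i)=\rho_i\sum_j f_D(\rho_i,\phi_j)\Delta\phi$
  (closed form $2\pi\rho_i f_I(\rho_i)$ on axis), delta-as-indicator
  binning of shell contributions by propagation distance, central
  temporal derivative; cost $O(N_\rho N_\phi + N_\rho N_z)$.
* **`oa_solve_cart()`** — an independent brute-force Cartesian voxel
  solver used for cross-validation.
* **`oa_foil()` / `foil_average()`** — the finite transducer-foil model
  (temporal averaging over the foil transit), plus utilities for measured
  traces (`smooth_measured()`, `amplitude_calibration()`).
* **`diffraction_parameter()`** — near-/far-field classification via
  $D = 2|z_D|/(\mu a_0^2)$, $\mu=\langle\mu_a\rangle$ over the absorbing
  layers, $a_0 = 1.25a$.
* **`reconstruct_p0_ff()` / `mse_sweep()`** — far-field reconstruction of
  $p_0(z)$ by temporal integration of the transient, with
  mean-squared-error benchmarking against the exact profile as a function
  of detector distance.
* **`oa_preset()`** — the bundled study scenarios (two-layer `fig3a`/
  `fig3b`/`fig4`, tissue phantoms `PI`, `PII`, `PIII`), and a small CLI
  (`inst/cli/oa`, or `oa_cli()` from R).

All lengths are cm, absorption cm⁻¹, signal axes propagation distance
$ct$ (cm), amplitudes arbitrary units; the speed of sound never enters
the core.

## Worked example

Two absorbing layers (10 cm⁻¹ over 0–0.05 cm, 20 cm⁻¹ over 0.05–0.1 cm)
under a top-hat beam, observed on axis from the irradiated side:

```r
library(oasim)

stack <- oa_stack(data.frame(z_start = c(0, 0.05), z_end = c(0.05, 0.1),
                             mu_a = c(10, 20)), L_z = 0.15)
beam <- oa_beam(a = 0.15, d = 0.15 / 4)

diffraction_parameter(stack, beam, c(-0.04, -4))
#>     z_D          D regime
#> 1 -0.04  0.1517037     NF
#> 2 -4.00 15.1703704     FF

sig <- to_retarded_depth(oa_solve(stack, beam, oa_detection(-4)))
sig
#> Optoacoustic pressure transient: 181 samples, ct in [3.99, 4.17] cm (bin 0.001 cm)
#>   detector at x_D = 0 cm, z_D = -4 cm; max |p| = 43.72 a.u.
#>   retarded depth axis ctau = ct + z_D in [-0.0095, 0.1705] cm

extract_features(sig)
#>               kind   ctau  amplitude
#> 1 compression_peak 0.0025  43.715375
#> 3  rarefaction_dip 0.0105  -2.492759
#> 2 compression_peak 0.0515  23.197940
#> 4  rarefaction_dip 0.0595  -5.499324
#> 5  rarefaction_dip 0.1015 -20.978632
```

The detector at $z_D=-0.04$ cm sits in the acoustic near field
($D\approx0.15$), at $-4$ cm in the far field ($D\approx15$). The
far-field transient is derivative-like: compression peaks at retarded
depths $c\tau\approx0$ and $0.05$ cm mark the surface and the upward
absorption step between the layers, the rarefaction dip at
$c\tau\approx0.10$ cm marks the absorber end (all within half a foil
window of the boundaries); the shallow dips in between are diffraction-
driven rarefaction phases. `plot(sig)` draws the transient against
$c\tau$.

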