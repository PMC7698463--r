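---
title: "Methods: voxelized Monte Carlo fluorescence photon migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelized Monte Carlo fluorescence photon migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxfluor)
```

This vignette documents the model, the numerical choices, and the design
decisions behind `voxfluor`, in the spirit of a methods section: what is
simulated, under which assumptions, and what the tests do and do not show.

## The transport model

The medium is a 3D grid of integer tissue labels (outside/air, skin, fat,
duct, cancer) at isotropic 0.033 cm voxels, matching the 0.33 mm slice
pitch of cryosection anatomy; the full anatomical grid is
(500, 250, 220) voxels, while tests and examples use reduced grids.
Every label maps to band-specific optical properties (μa, μs, g, n); the
shipped table covers the six wavelengths 488/520 nm (VIS), 780/820 nm
(NIR) and 970/1100 nm (SWIR) with no spectral interpolation, because the
model only ever runs at those six discrete points.

Photon transport follows the standard weighted-photon scheme for
multi-layered and voxelized media:

* **Hop.** A dimensionless pathlength budget s̄ = −ln ξ is drawn once per
  free flight and consumed voxel-by-voxel as μt·d, so free-path statistics
  remain correct across heterogeneous voxels. Ambient voxels (μt = 0) are
  traversed without consuming the budget.
* **Drop.** At the interaction site the photon deposits W·μa/μt into the
  voxel's absorption tally.
* **Spin.** The deflection cosine is sampled from the Henyey–Greenstein
  phase function; the azimuth is uniform; the direction update uses the
  usual local-frame rotation with the |μz| ≈ 1 special case and an
  explicit renormalization.
* **Boundaries.** Fresnel reflectance (unpolarized average) is evaluated
  only at voxel faces where n changes; matched-index faces are
  transparent, which is exact since R = 0 there. After the deterministic
  specular deduction at the first air–tissue entry (MCML convention,
  weight₀ = 1 − R_spec), boundary crossings are decided stochastically:
  reflect with probability R, otherwise refract by Snell's law. Total
  internal reflection gives R = 1. A photon transmitted from tissue into
  ambient air escapes; re-entry across concave surface pockets is not
  modeled, which is a very small effect for convex breast-like contours.
* **Termination.** Photons below the weight threshold (default 10⁻⁴ of
  the photon's initial weight) play Russian roulette with survival factor
  m = 10 (MCML defaults; both configurable). An event cap (default 10⁶)
  guards against pathological loops; capped photons are retired into the
  roulette ledger with a warning counter.

### The weight ledger

Each run reports `launched = absorbed + escaped + roulette_killed` with
`roulette_killed` defined as the *net* weight retired by the roulette
game: deaths minus the survival top-ups that multiply a surviving
photon's weight by m. Gross deaths and gains are reported separately.
With this convention the identity holds to floating-point accumulation
accuracy (≲ 10⁻¹¹ relative in practice) on every run; with gross
bookkeeping it could only hold in expectation, because roulette conserves
weight statistically, not per photon.

### Fluence scoring

Fluence uses the collision estimator
Φ[v] = absorbed[v]·P₁/(μa[v]·V_voxel), with P₁ = A_beam·E₀/N the source
power carried per unit weight (beam aperture area × irradiance / photons).
For a pencil beam, A_beam is taken as 1 cm² by convention, so fluence is
the response per 1 W of injected power. The estimator is undefined for
μa = 0 tissue; since no shipped tissue has zero absorption at any of the
six wavelengths, such voxels raise an explicit error rather than being
served by a track-length fallback — anyone substituting a zero-absorption
tissue table needs to know the estimator no longer applies, and a silent
fallback would change the variance structure of every result.

### Random numbers

The engine draws 53-bit uniforms from a 64-bit Mersenne twister seeded
per run; launch-position and emission-ensemble sampling use R's own seeded
generator. Runs are bitwise reproducible single-threaded for a fixed seed.
The generator identity is an implementation detail, not a contract.

## Fluorescence coupling

The probe is characterized by quantum yield QY and probe absorption
εC (molar absorptivity × concentration, cm⁻¹): fluorescein in the VIS
(QY 0.95, εC 12 cm⁻¹), indocyanine green in the NIR (QY 0.09,
εC 20 cm⁻¹), PbS quantum dots in the SWIR (QY 0.40, εC 0.63 cm⁻¹).

Coupling is perturbation-free: εC is *not* added to the cancer's μa
during excitation transport, and emitted photons are not reabsorbed by
the probe (single-generation model). The emission source term is

> emitted power density = QY · εC · Φ_ex  (W/cm³), confined to the cancer.

A million-photon-class ensemble is launched isotropically at positions
uniform over the cancer voxel union. Two modes:

* **with the excitation gradient** — per-photon weights proportional to
  the launch voxel's excitation fluence, renormalized so the launched
  total equals QY·εC·Σ_v Φ_ex[v]·V_voxel *exactly*. The renormalization
  (rather than the unbiased V_cancer/N scaling alone) removes the
  O(1/√N) fluctuation of the total source power, so the accounting
  identity holds to machine precision and run-to-run variance comes only
  from transport.
* **without the gradient** — all weights equal,
  QY·εC·Φ_ex(center)·V_cancer/N, reproducing the uniform-excitation
  approximation of layered models. The two modes coincide exactly when
  the excitation field is uniform over the cancer, which is the
  regression anchor for the mode logic.

Emission weights are physical (watts), so the surface map needs no
further normalization: bin irradiance = binned escaped weight / bin area.

## Detection

Escape events with a negative z direction component (back toward the
illuminated side) are binned by (x, y) voxel column at 0.033 cm
resolution; side and bottom escapes and the launch specular reflection
stay in the escape ledger but are not binned, since a reflectance-mode
detector does not see them. The detectability statistic is the peak bin
compared against a 10 nW/cm² sensor floor (strictly "more than"); an
aperture-averaged mean is available behind `stat = "mean"` for users who
prefer an integrating detector. Peak-vs-aperture is a genuinely open
choice — the detector geometry behind the sensor-floor figure is not
specified — so both are provided and the choice is recorded in the map
metadata.

Band comparisons in `sweep_detectability()` reuse one phantom and one
seed per row (common random numbers) so that band and size effects are
not confounded by geometry or sampling noise.

## The synthetic breast phantom

The generator stands in for segmented cryosection anatomy so that every
downstream stage is testable without external data. It emulates the
*structural* features that drive the physics:

* an ellipsoidal outer contour whose apex (the nipple) touches the z = 0
  plane — the anchor for the depth convention;
* a skin shell exactly 2 voxels thick, derived per (x, z) slice by 2D
  erosion of the tissue mask, mirroring the slice-wise border rule used
  for cryosection stacks (a consequence worth knowing: along the
  stacking axis the shell is not guaranteed to be 2 voxels thick);
* a duct tree grown from just below the apex by a depth-biased random
  binary branching process (8 trunks, 4 generations, segment lengths
  0.3–0.8 cm, trunk radius 0.07 cm tapering by 15% per generation),
  rasterized as capsules that only ever replace fat. With the default
  parameters the duct fraction of tissue lands in the 1–15% band asserted
  by the generator's contract tests.

The default test-scale grid is (140, 100, 110) voxels (4.6 × 3.3 ×
3.6 cm). A 1 cm cancer at 2 cm depth — and a 1 mm cancer at 3 cm depth —
must fit strictly inside the contour together with the skin shell, which
a thinner slab (e.g. 2 cm along the slice axis) cannot hold; the chosen
size is the smallest round grid that accommodates every experiment in
the acceptance suite with margin.

What the phantom does *not* emulate: anatomically validated duct
statistics, lobular structure, chest-wall muscle, or the irregular
surface texture of real cryosections. Passing trend tests on the phantom
therefore shows that the *engine and coupling* behave correctly in a
breast-like heterogeneous medium — it does not certify absolute
intensities for real anatomy, which depend on the supplied volume.

## Numerical choices

* Voxel membership is voxel-center-in-sphere with half-open voxel
  extents [i·h, (i+1)·h); an analytic-volume check keeps the discretized
  sphere within 1% of (π/6)d³ at d = 1 cm.
* On face crossings the crossed coordinate is snapped onto the face and
  the voxel index stepped explicitly, so floating-point drift cannot
  desynchronize position and voxel index.
* Cancer depth is the distance from the z = 0 anchor to the *upper
  surface* of the sphere; the anchor of a segmented stack is the
  shallowest tissue voxel of the middle slice.
* Grayscale conversion uses ITU-R 601 luma; segmentation thresholds are
  fat > 180, duct 80–120, with interior pixels outside both windows
  assigned to fat (fat is the bulk matrix and only three tissue classes
  exist); background is pixel value 0.
* Roulette thresholds are relative to each photon's initial weight, so
  excitation (weight 1) and emission (watt-valued weights spanning
  decades) stages terminate with identical statistics.

## Problem sizes

Unit tests run at 10³–10⁵ photons on slab geometries; the acceptance
suite uses 10⁵ excitation + 10⁵ emission photons per run on the default
phantom with fixed seeds, where every trend assertion (SWIR > NIR > VIS,
monotone depth and diameter responses) resolves far outside shot noise.
The statistical assertions use 3-standard-error bands around closed-form
expectations, and the voxel engine is cross-checked against an
independent, vectorized single-medium Monte Carlo for semi-infinite
diffuse reflectance (isotropic scattering, matched boundary — a geometry
where only depth and direction cosine matter, so the oracle shares no
code with the voxel traversal).

## Known limitations

* No time-resolved transport, polarization, or refractive-index
  gradients; no re-entry of escaped photons across concave surfaces.
* Single-generation fluorescence: no probe self-absorption at the
  emission wavelength, no photobleaching, no multi-fluorophore mixtures.
* The collision fluence estimator is noisy in voxels visited rarely
  (deep tissue at VIS wavelengths); absence of signal at a fixed photon
  count is a statement at that sampling depth, not an analytic zero.
* Bitwise determinism is guaranteed single-threaded only.
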