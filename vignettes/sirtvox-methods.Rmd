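---
title: "Voxel dosimetry for yttrium-90 SIRT: models, engines and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel dosimetry for yttrium-90 SIRT: models, engines and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After yttrium-90 microsphere selective internal radiation therapy
(SIRT), the absorbed dose to tumors, non-tumoral liver (NL) and lung is
estimated from post-therapy quantitative imaging: a SPECT/CT activity
map on a ~4.8 mm voxel grid, a CT-derived density map, and organ masks.
Several voxel-based dosimetry methods (VBDM) are in clinical use, and
they disagree most where it matters for safety — in the lung and at the
liver–lung interface, where tissue density drops from about 1.04 to
0.26 g/cc and the beta range stretches from 11 mm to 44 mm.

`sirtvox` implements four dose engines on a common voxel-grid data
model, plus the two analyses that quantify their differences: a slab
liver–lung interface simulation with controllable spatial resolution
and lung shunt fraction (LS), and a synthetic-cohort VOI analysis with
interface-exclusion sensitivity regression.

## Physical model

All engines share one set of constants (`y90_constants()`): mean beta
energy `E_avg` = 0.937 MeV per disintegration, half-life 64.1 h,
endpoint 2.28 MeV, maximum soft-tissue range 11 mm at the reference
density 1.04 g/cc, lung reference density 0.26 g/cc. Microspheres are
permanent implants, so cumulated decays per voxel are
`N = A * T_half / ln 2` with no biological clearance. Activity maps are
self-calibrated: reconstructed counts are scaled so that their total
equals the administered activity, which makes the absolute counts scale
irrelevant.

### The four engines

* **LD (local deposition)** — `D = N * E_avg / (rho * dV)`. Exact under
  charged-particle equilibrium; no transport.
* **SK (soft-tissue kernel)** — `D = N (*) K`, FFT convolution of the
  disintegration map with the reference soft-tissue voxel kernel. In a
  medium of density `rho` it is low by exactly `rho / 1.04`; deep in
  lung that is the −75% plateau.
* **SKD (density-corrected kernel)** — `D = (N (*) K) * 1.04 / rho`.
  Restores the equilibrium dose at any density, but not the range
  stretching across interfaces.
* **RT (radiological transport reference)** — the package's
  deterministic reference engine. For each source–target voxel pair the
  geometric segment is ray-traced through the density grid
  (Amanatides–Woo traversal) to obtain the radiological path length
  `l_eff = ∫ (rho / 1.04) dl`; the pair contribution is the reference
  voxel kernel sampled (trilinear) at the offset scaled by
  `s = l_eff / l_geo`, times `s^3` (the volume Jacobian of the radial
  scaling) and `1.04 / rho_target`. In any uniform medium the pair sum
  reduces exactly to the density-scaled kernel, so interior dose equals
  LD at every density; across the interface it reproduces the beta
  range stretching into lung. It does not model backscatter, lateral
  scatter redistribution, or bremsstrahlung.

The trilinear-kernel form of the RT pair term (rather than evaluating
the radial point kernel at the pair distance) is a deliberate choice:
the voxel-averaged kernel is bounded, so the discrete pair sum
conserves energy to <0.5% in uniform media at 4.8 mm voxels, where
midpoint sampling of the 1/r² point kernel errs by several percent.

### Energy bookkeeping

`global_energy(D, rho) = Σ D * rho * dV` is the conservation
diagnostic. LD satisfies `global_energy = Σ N * E_avg` algebraically.
SK/SKD/RT match within 0.5% for activity fully inside the grid in
uniform media. Two corners are physically irreducible and are asserted
as such in the tests: SK *cannot* conserve energy on lung-containing
grids (dose landing in lung is booked at 0.26/1.04 of its energy —
precisely the SK deficiency the analyses quantify; on the default
phantom its deficit equals 0.75 × the lung energy share), and the RT
pair discretisation biases energy by ~2–3% for sources straddling the
density interface, while remaining ≤0.5% in uniform media.

## The radial dose-point kernel

The soft-tissue kernel is built from a radial dose-point kernel
Phi(r) (MeV/g per decay) for ⁹⁰Y in an infinite 1.04 g/cc medium. The
bundled table (`inst/extdata/y90_dpk_synthetic.tsv`) is *synthetic*: it
is generated by `y90_dpk()`, a fixed-seed condensed-history random
walk built from three classical published ingredients — the
allowed-shape beta spectrum with a nonrelativistic Fermi correction,
the Katz–Penfold range–energy relation
`R = 0.412 E^(1.265 − 0.0954 ln E)` g/cm² (which independently
reproduces the 11 mm maximum soft-tissue range), and Gaussian multiple
Coulomb scattering with the Highland angle. One scale factor (0.5) on
the Highland angle is calibrated so the kernel reproduces the published
X90 of ⁹⁰Y in water (90% of emitted energy within 5.43 mm); the
uncalibrated walk gives 4.5 mm and a straight path 5.9 mm, because the
raw Highland variance — a single-slab Moliere-core parameterisation —
over-relaxes the direction when accumulated along a track. The kernel
is truncated at 11 mm and renormalised so its total energy is exactly
0.937 MeV per decay. Not modelled: energy-loss straggling, delta rays,
bremsstrahlung.

### Voxelisation

`build_voxel_kernel()` averages Phi over source and target voxels for
each offset of a 7×7×7 grid at 4.8 mm (the smallest odd grid containing
the support). The voxel-pair average is computed by an exact reduction
over the source–target *difference* variable: a radial midpoint rule
(0.01 mm) times a 3000-point Fibonacci-sphere average of the separable
triangular difference density. The r² factor cancels the 1/r²
singularity, so the rule is accurate to ~0.1% (a naive fixed
sub-division midpoint rule was measured 1–2% biased against dense Monte
Carlo and was discarded). Octant symmetry is enforced by construction,
and the kernel is renormalised to exactly `E_avg`.

The test-suite oracle for the voxelisation is an *importance-sampled*
Monte Carlo integral: plain uniform point pairs are unusable here
because ~4% of the self-voxel value comes from pairs closer than
0.05 mm (probability ~5e-9 per draw), making the naive estimator
heavy-tailed and biased low at any practical sample size.

## The interface simulation

`run_interface_study()` reproduces the slab experiment: liver
(1.04 g/cc) fills z ≤ 0 and lung (0.26 g/cc) z > 0 on a 61³ core of
4.8 mm voxels, extended by 12 voxels (57.6 mm) of the same pattern on
every face so the core is at equilibrium — beyond the beta range plus
the blur extent this is equivalent to the ~2 m padding a Monte Carlo
study would use, and it is noise-free and deterministic. Uniform
activity is placed in one compartment at a time, blurred with an
isotropic Gaussian point-spread function (FWHM 0/10/20 mm — the
package's imaging-resolution model; σ = FWHM/2.3548, truncated at 4σ
and renormalised), each engine is run per unit compartment activity,
and compartments are superposed as `(1−LS)·liver + LS·lung` for LS =
1/10/20%. Central 7×7-column z-profiles are compared with the truth —
the RT engine on the *unblurred* activity at the same LS — as percent
differences, and reduced to ±10% agreement intervals.

Numerical choices: interval endpoints are reported at 1 mm resolution
by linear interpolation of |percent difference| between voxel centres
(the printed endpoints are finer than the 4.8 mm pitch, which implies
sub-voxel interpolation); an outermost compliant run touching the
profile boundary is extended to ±∞ since the slab is at equilibrium
there. The RT engine is evaluated only on the central 7×7 column (the
profile region), which is what makes the study run in seconds. Each
compartment's dose is normalised per unit *total* compartment activity,
so the LS weights act as activity fractions.

Known behaviour of the surrogate: the liver-side boundaries and the
lung-side boundaries at LS 10–20% agree with condensed-history Monte
Carlo results within one voxel, and the deep-lung SK plateau sits at
the analytic −75%. The worst-case lung-side boundary at low LS (1%) is
the surrogate's weakest cell: there the truth is at a 1%-of-equilibrium
floor, the percent-difference profile exceeds 100% over a broad plateau
and crosses 10% only on a shallow tail, so the crossing position is
extremely sensitive to small profile-level differences (and, in a Monte
Carlo reference, to its statistical noise). A noise-free deterministic
truth crosses several millimetres deeper than a noisy one.

## The synthetic cohort

`generate_phantom()` builds a deterministic phantom: a liver ellipsoid
capped by a horizontal liver–lung interface plane, a lung ellipsoid cap
above it at 0.26 g/cc, soft-tissue background, 1–3 spherical tumors
inside the liver with uptake ratios 2–6, a lung shunt fraction of the
administered activity uniform over the lung, and an imaging chain of
20 mm FWHM Gaussian blur with counts proportional to activity
(optional Poisson noise; off by default so every stage is exactly
reproducible). Activity sums exactly to the administered activity at
every stage.

`cohort_spec()` mirrors a 17-case post-therapy series: administered
activity uniform on 1.13–5.21 GBq, LS on 1–20%, 31 tumors across the
cohort, liver semi-axes 42–55 mm (x, y) × 40–50 mm (z) on a 40×40×44
grid. The distribution shapes (uniform) and the geometry ranges are the
package's choices; the activity, LS, tumor-count and resolution values
are the study conditions. One master seed fixes every draw
bit-identically.

What the generator does *not* emulate: realistic anatomy, attenuation
and scatter in the imaging chain, reconstruction artifacts,
respiratory motion, and anatomical lung volumes — the lung cap is a few
hundred cc, far smaller than a real lung, so absolute lung doses are
higher than clinical values and only relative and structural
comparisons (engine-vs-engine, original-vs-remainder) are meaningful.
Passing cohort tests therefore demonstrate the *pipeline's* behaviour
under the stated statistical structure, not patient-level dose
accuracy.

`run_cohort_study()` computes all four engines per phantom (RT on the
liver ∪ lung voxels), VOI mean doses and DVHs, remainder VOIs excluding
1/2/3 cm around the interface (Euclidean distance from voxel centres to
the set of liver–lung face centres, 6-connectivity — a reproducible
stand-in for contour-based margin tools), and the cohort regression of
original on remainder mean doses per VOI and margin.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| voxel size | 4.8 | mm | SPECT reconstruction voxel |
| kernel half-width | 3 | voxels | smallest odd grid containing 11 mm |
| PSF FWHM | 20 | mm | post-therapy bremsstrahlung SPECT resolution |
| slab core / margin | 61³ / 12 | voxels | printed grid; margin > 44 mm lung reach + blur |
| LS set | 0.01, 0.10, 0.20 | — | studied shunt fractions |
| agreement threshold | 10 | % | reported accuracy criterion |
| DVH bin width | 0.5 | Gy | resolves 10–300 Gy VOI distributions |
| exclusion margins | 10, 20, 30 | mm | studied interface margins |
| material ranges | 0.05 / 0.70 / 1.50 | g/cc | bracket 0.26 and 1.04 reference densities |
| density LUT | −1000→0.001, 0→1.0, 3000→2.9 | HU→g/cc | generic two-segment table; scanner tables are measured |

The material cut-points and the default LUT are package choices (the
clinical tables are scanner-specific); both are configurable through
`material_thresholds()`, `density_lut()` or a YAML/JSON config read by
`read_materials_config()`.

## Degenerate inputs and edge rules

Anisotropic grids are accepted by the data model but refused by the
kernel-based engines. Convolutions zero-pad by at least the kernel
half-width (no wrap-around) and clamp the ~1e-16 negative FFT residue
to zero. `counts_to_activity` refuses all-zero counts; `dose_ld`
refuses zero density at active voxels; `dose_rt` caps its search
radius using the smallest grid density clamped at 0.2 g/cc (a
near-vacuum voxel would otherwise blow the radius up) and warns when
the cap engages. Half-open material ranges make the density→material
map total on [0, ∞).

## Problem sizes

The shipped analyses run on one CPU in a few minutes total: the
interface study uses the 61³ core with a 12-voxel margin (85³ grid)
with RT restricted to the profile column; the cohort uses seventeen
40×40×44 phantoms with RT on the liver and lung VOIs; the uniform-
medium equilibrium checks use 41³ grids with interior targets. The
radial kernel ships pre-generated (4×10⁵ electron histories);
regenerating it takes ~15 s.

## Known limitations

* RT is a deterministic surrogate for coupled electron–photon Monte
  Carlo: no backscatter, no lateral scatter redistribution, no photon
  (bremsstrahlung) dose component.
* The radial kernel's distal shape rests on a one-parameter calibration
  to the published X90; its far tail (beyond ~7 mm water-equivalent) is
  the least constrained region and dominates the worst-case low-LS
  lung-side agreement boundary.
* The phantom cohort is geometric, not anatomical; lung doses are not
  on a clinical absolute scale.
* Masks and volumes must be co-registered on one grid; no registration
  is provided.
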