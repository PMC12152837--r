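---
title: "Models and methods for charged lipopeptide micelle analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for charged lipopeptide micelle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellar)
```

This vignette documents the science implemented by `micellar`: the
scattering and spectroscopic models, the estimation procedures built on
them, the synthetic-data generators that stand in for raw measurements, and
the numerical and design choices a user should know about before trusting a
fit.

## The system and the measurement problem

Lipidated peptides such as semaglutide (31 residues, an octadecanedioyl
chain on Lys20) are amphiphiles: above a critical aggregation concentration
they self-assemble in water into micelles whose hydrophobic chains form a
core and whose peptide moieties form a corona. Because the peptide carries
ionizable groups, the micelles are charged, and concentrated solutions show
interparticle interference in small-angle scattering. The analysis tasks
this package covers are:

* extracting micelle geometry and effective charge from SAXS curves,
* estimating the association number p (molecules per micelle)
  model-independently from absolute-scale forward scattering,
* quantifying the (small) alpha-helix content from CD,
* profiling micelle structure from coordinate snapshots
  (electron-density profiles, solvent-accessible surface area),
* locating the CMC from probe-fluorescence titrations, and
* the supporting TEER permeability arithmetic.

## Scattering models

All wavenumbers are in nm^-1, lengths in nm, electron densities in e/Å^3
and absolute intensities in cm^-1; conversions happen only at interfaces.

**Form factors.** The homogeneous sphere uses the kernel
f(x) = 3(sin x − x cos x)/x³; the core–shell sphere amplitude is

F(q) = (4π/3)[(ρ_core − ρ_shell) R_i³ f(qR_i) + (ρ_shell − ρ_solv) R_o³ f(qR_o)],

evaluated in Ångström units so F is in electrons, and normalized to
P(0) = 1 for fitting (the absolute level is carried by the `scale`
parameter). Dissolved oligomers are modelled as Gaussian chains with the
Debye function D(x) = 2(e^−x + x − 1)/x², x = (qR_g)²; irregular
fractal-like aggregates by I(q) = A q^(−α). Both kernels switch to series
expansions at small argument (x < 0.1 for the sphere kernel, x < 0.01 for
the Debye function) to avoid catastrophic cancellation.

**Hard-sphere structure factor.** The Percus–Yevick S(q) is evaluated from
the closed-form direct correlation function; the three trigonometric
brackets are series-expanded below A = 2qR < 0.25, where the closed forms
lose up to half their significant digits to cancellation. The q → 0 limit
is the PY compressibility (1 − φ)⁴/(1 + 2φ)².

**Charged-sphere (Hayter–Penfold) structure factor.** Charged micelles
repel through a screened Coulomb (Yukawa) potential; with hard core
diameter σ = 2R_HS the DLVO contact coupling is

β u(σ) = z_eff² λ_B / (σ (1 + κσ/2)²),

with λ_B the Bjerrum length (0.714 nm in water at 298 K, dielectric
constant 78.5). When no ionic strength is supplied the screening κ is
computed from the counterions the particles themselves release
(κ² = 4π λ_B z_eff n_particle), the appropriate assumption for salt-free
water. The MSA closure (g = 0 inside the core, c = −βu outside) is solved
numerically: the core part of c(r) is iterated through the
Ornstein–Zernike relation in Fourier space (discrete sine transforms on a
grid whose core boundary falls midway between nodes, keeping the
trapezoidal transform second-order accurate across the discontinuity of c
at contact), with Anderson acceleration (depth 4) and, for strongly coupled
states, continuation in the coupling from the hard-sphere solution. At the
default grid (4096 points, dx = σ/192.5) the z_eff = 0 limit agrees with
the analytic PY solution to a few times 10⁻⁵.

In the dilute charged regime the raw MSA yields an unphysical negative
contact value g(σ⁺); following the standard low-density prescription the
effective hard-core diameter is then grown (η' = s³η, with the *physical*
potential retained) until g(contact) = 0. The rescaling root is solved to
1e−11 in s — far tighter than any physical need — because the fitted model
must be smooth at the ~1e−8 parameter steps used by finite-difference
Jacobians; a looser root makes S(q) numerically noisy and wrecks
gradient-based fitting. Parameter regions with no physical root, or with a
contact coupling beyond a configurable cap, raise informative errors; the
fitter treats such trial points as misfits.

**Combination.** The default combination is the product
I = scale·P(q)·S(q) + background, the standard reading for monodisperse
spheres; a decoupling mode I = scale·P·[1 + β(S − 1)] is provided, with
β = |⟨F⟩|²/⟨|F|²⟩ = 1 in the monodisperse case implemented here, so the two
modes coincide — the switch exists so polydisperse extensions have a
defined seam. Structure factors combine only with compact-particle form
factors; requesting one with a chain or power-law form is an error.

## Fitting

`fit_saxs()` minimizes Σ[(I_obs − I_model)/σ]² with bounded
Levenberg–Marquardt. Curves without uncertainties are fitted unweighted
with a warning; negative background-subtracted intensities are retained and
weighted normally (clipping them would bias the least squares). Because the
(φ, z_eff, R_HS) surface is multi-modal, the fitter restarts from a seeded
Latin hypercube over the parameter bounds (default 8 starts, default seed
20250512) and returns the best converged start; results are bit-identical
across runs for a fixed seed. The outer radius is parametrized as
R_i + shell thickness so the ordering constraint is a simple positivity
bound, and `tie_hs_radius = TRUE` constrains R_HS to the micelle outer
radius — physically sensible (the fitted interaction radii match the outer
form-factor radii) and it removes a poorly determined degeneracy direction.

Two properties of these fits deserve honesty. First, with 2% relative
uncertainties, deep core–shell form-factor minima at high q act as
near-hard constraints, and misaligning them creates genuine local minima a
few percent away in the radii; multi-start and sane bounds are the remedy,
and the effective charge — set by the interference-peak shape — is robust
to these traps (recovered within ~3% in all probed cases, against a 10%
acceptance band). Second, during fitting the structure-factor solver runs
on a coarsened grid (2048 points) whose ~2×10⁻⁴ relative model error is
negligible against the noise; reported predictions use the full-accuracy
grid.

`forward_intensity()` implements the Guinier route (weighted fit of ln I
against q² on the window q·R_g ≤ 1.3, iterated twice from an initial
lowest-quartile window) and a plateau route (uncertainty-weighted mean of
the lowest-q decade) for flat dilute curves. `breakpoint_fit()` fits a
continuous two-segment line in log10(concentration) by profiling the knot
on a 201-point grid plus golden-section refinement, tests the break against
a single line with an F-test (two extra parameters, alpha = 0.05 — the
conventional level; the underlying measurement protocol does not prescribe
one), and converts the knot's RSS-profile curvature into an uncertainty.

## Association number from absolute intensity

On absolute scale, I(0) = c M [r0 v_p Δρ]²/N_A with r0 the classical
electron radius (0.28179×10⁻¹² cm) and Δρ the electron-density contrast in
e/cm³ (1 Å⁻³ = 10²⁴ cm⁻³ exactly). `micelle_molar_mass()` inverts this; the
concentration used is the total lipopeptide mass concentration (the
convention of the worked analyses this reproduces), with any CMC correction
left to the caller since the free-monomer fraction is system-specific. The
Tanford volume v = 27.4 + 26.9 n Å³ and the electron count of the chain
give the core electron density; for an n = 17 chain the formula gives
484.7 Å³ (values near 487 Å³ circulate in the literature for this case and
give 0.291 rather than 0.293 e/Å³ with 142 electrons — both are carried in
the tests). A documented reference test also records that evaluating the
mass relation with the commonly quoted inputs (I(0) = 0.0025 cm⁻¹,
c = 0.001 g cm⁻³, v_p = 1.17 cm³ g⁻¹, Δρ = −0.042 e/Å³) yields
≈ 7.85×10³ g mol⁻¹, whereas the published worked example for those inputs
quotes 9111 g mol⁻¹ — a value consistent with Δρ ≈ 0.039 e/Å³; the
implementation follows the formula.

`ratio_association_estimate()` scales a reference association number by
the concentration-normalized low-q intensity ratio between two curves, and
flags the estimate when the concentrated curve shows an interference peak,
which depresses low-q intensity and biases the ratio downward.

## CD helicity

CD in mdeg is normalized to whole-molecule molar ellipticity
[θ] = θ/(10 c l) and then divided by the residue count — the two-step
convention that reproduces the worked chain of numbers (−29310 → −945.5 per
residue for N = 31). The 100%-helix reference is the chain-length-corrected
−37400 × (1 − 2.5/N) deg cm² dmol⁻¹, and f_a is the ratio of the observed
to the theoretical per-residue value at 222 nm (values above 1 are reported
clipped, with the raw ratio retained). The [θ]222/[θ]208 ratio
distinguishes isolated helices (< 1) from coiled-coil association (≥ 1);
the boundary is assigned to the coiled-coil class. Smoothing is
Savitzky–Golay (default window 9, order 2) — a fixed, polynomial-preserving
choice standing in for unspecified vendor smoothing — and 222/208 nm values
are read by linear interpolation on the wavelength grid.

## Coordinate post-processing

Electron counts default to neutral atoms, with united-atom CH/CH2/CH3
pseudo-particles carrying summed counts; radii are Bondi-type van der Waals
values. Radial profiles assign each atom's electrons wholly to the shell
containing its centre (default width 0.05 nm, electron-weighted centre), so
electron conservation is exact by construction; converting shell volumes to
Å³ yields e/Å³ directly comparable to scattering contrasts. SASA uses
Shrake–Rupley sampling on a deterministic Fibonacci lattice (default 960
points, probe 0.14 nm): deterministic output for fixed inputs, exactly
translation-invariant, but — like any finite point sampling — only stable
to O(1/n_points) under rotation, which is why the tests check rotation
stability at 0.5% rather than machine precision. Periodic-boundary images
are not unwrapped; inputs are assumed to be whole molecules.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, each a
deterministic function of its parameters and seed:

* **SAXS curves** — model intensity with multiplicative Gaussian noise plus
  an absolute floor, σ(q) = rel·I(q) + floor, mimicking
  photon-statistics-dominated synchrotron data. Presets bundle the three
  regimes of the aqueous system: `dilute_0.1wt` (Gaussian chains,
  I(0) = 0.0025 cm⁻¹ at 0.001 g cm⁻³, R_g = 1.6 nm), `aged_1wt`
  (core–shell R_i = 1.5, R_o = 2.45 nm × charged spheres z_eff = 10.8,
  R_HS = 2.45 nm, φ = c·v_p = 0.0117 — the dry peptide volume fraction at
  1 wt%, which places the interference peak at 0.49 nm⁻¹, inside the
  observed 0.4–0.5 band), and `fractal_fresh` (α = 2.6 power law).
* **CD spectra** — fixed helix (208/222 minima, 190 maximum) and coil
  (198 minimum) band shapes combined so that the helicity pipeline inverts
  the generating f exactly at zero noise; the coil basis is constructed
  with a node at 222 nm to make that inversion exact rather than
  approximate.
* **Coordinates** — p bead-chains with 17 CH2 tail beads (an octadecyl
  chain without its terminal methyl) at volume-uniform radii inside the
  core and head beads in the shell, or dispersed random placements (the
  trimer-like starting state); minimum inter-chain distances are enforced
  by seeded rejection. The compact default construction yields a core
  plateau of ≈ 0.29 e/Å³, the methylene value. A frozen loose-vs-compact
  pair is calibrated so its true SASA ratio is 1.36, the aggregation
  propensity regime of interest.
* **Titrations** — two-segment piecewise-linear response in log
  concentration with the knot at the CMC (default 0.06 wt%).

Passing recovery tests on these data shows the estimators are correct and
unbiased *under the stated noise model*. Real beamline curves additionally
carry instrument smearing, background-subtraction residuals, incoherent
backgrounds, polydispersity and (here) a coexisting fibril population —
none of which the generators emulate, and none of which these tests probe.
Fit results on real data should be read with those caveats.

## Problem sizes and defaults

Synthetic curves default to 120–150 log-spaced q points on 0.05–5 nm⁻¹,
matching typical rebinned beamline output; recovery tests run at 1–2%
noise with single or few-start fits from 5–10% perturbed initial values,
and the structure-factor oracle comparisons use 25–40 point q grids —
sizes chosen so each check isolates one property at comfortable numerical
margins.

## Known limitations

* No polydispersity, instrument smearing, or multi-population fits (the
  fibril fraction visible in cryo-TEM is deliberately not modelled).
* The MSA has no solution at sufficiently strong coupling; such parameter
  corners raise errors rather than extrapolating.
* The CMC estimator assumes a single sharp breakpoint; gradual aggregation
  onset will blur both the location and its F-test.
* CD analysis quantifies only the 222/208 nm quantities; it is not a
  secondary-structure deconvolution.
* The TEER module is bookkeeping (differences, areas, percentages), not a
  transport model.
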