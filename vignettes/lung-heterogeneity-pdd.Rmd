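---
title: "Methods: depth dose in lung-heterogeneous slab phantoms"
author: "lungpdd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth dose in lung-heterogeneous slab phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `lungpdd`, the choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real measurements.

## The problem

When a megavoltage photon field is narrow and traverses a low-density
medium such as inflated lung, the lateral range of Compton secondary
electrons can exceed the field's half-width. Electrons set in motion on the
central axis then carry energy out of the field without being replaced from
the sides: charged-particle equilibrium is lost and the central-axis dose
inside the low-density region collapses. Analytic heterogeneity-correction
algorithms built on photon attenuation and scatter scaling — the Batho
power law, its dmax-shifted TMR modification, and the equivalent
tissue–air-ratio (ETAR) method — do not transport electrons and therefore
*increase* the predicted dose in lung, in the wrong direction. The package
reproduces this comparison end to end at desk scale: a Monte Carlo engine
provides the reference dose, the analytic algorithms provide the
TPS-style corrected curves, and a synthetic TLD chain stands in for the
measurement campaign.

## Materials and physics data

Four media are packaged: liquid water, PMMA (acrylic, 1.19 g/cm³), lung
tissue (ICRU-44 adult composition), and LiF (the TLD chip medium,
2.635 g/cm³). For each, `inst/extdata/` carries energy-indexed tables
(100 log-spaced points, 0.01–20 MeV) of

* mass collision stopping power, generated from the Berger–Seltzer
  (Møller + Bethe) formulation with Sternheimer density-effect fit
  coefficients (each coefficient set satisfies δ(x₀) ≈ 0; the generator is
  `data-raw/make_material_tables.R`); shell corrections are omitted, which
  matters only below ~0.05 MeV;
* total mass attenuation coefficients assembled from the analytic
  interaction models used by the transport engine (below), so table and
  engine are mutually consistent.

Two distinct densities matter for lung. The *stopping-power table* is
evaluated at the tabulated tissue density 1.05 g/cm³ — this is what
"lung tissue" means in standard dosimetry data, and it fixes the
density-effect correction. The *transport density* of the phantom's lung
slab defaults to 0.26 g/cm³ (inflated lung; also a reasonable cork density)
and is configurable via `make_reference_phantom(lung_density = )`. Cork is
represented by lung-tissue stopping powers throughout, as is conventional
when no cork data exist.

Table lookups interpolate log–log between grid points and refuse to
extrapolate. Relative electron densities (the Batho exponent basis and the
radiological-depth integrand) are computed from the embedded compositions
as ρ·⟨Z/A⟩ relative to unit-density water.

## Mean secondary-electron energy and dose-to-medium conversion

The energy at which stopping-power ratios are taken is
`E0 = ½·hν·σ_tr(hν)/σ(hν)`, with `hν` the fluence-weighted mean energy of
the photon spectrum, `σ` the closed-form Klein–Nishina total cross section
per electron (a series expansion replaces the closed form below
α = 5·10⁻³, where it cancels catastrophically) and `σ_tr` the
energy-transfer cross section obtained by numerical integration of the
Klein–Nishina angular distribution weighted by the electron's energy
share. The formula is evaluated at the single mean energy, not
spectrum-averaged — the literal reading of the defining relation; the
water/PMMA and water/lung ratios vary by less than 1.5% over
E0 ∈ [0.5, 5] MeV, so this choice is not delicate.

Bragg–Gray cavity theory gives `D_w/D_g = (S̄/ρ)_w/(S̄/ρ)_g`. A note on
conventions: the *conversion factor* that multiplies a measured
dose-to-water to give dose-to-medium is `(S̄/ρ)_g/(S̄/ρ)_w` — about 0.97
for PMMA and 0.99 for lung tissue at E0 ≈ 1.2 MeV — and it is this factor
that dosimetry papers usually print as the "water–medium stopping-power
ratio". `stopping_power_ratio(a, b, E0)` is literally `(S̄/ρ)_a/(S̄/ρ)_b`;
`dose_to_medium()` divides by `stopping_power_ratio(water, medium, E0)`,
which is the same arithmetic.

## The Monte Carlo engine

`simulate_depth_dose()` performs analog photon transport in a layered slab
geometry that is laterally infinite: Compton scattering off free electrons
(standard two-branch rejection sampling of the Klein–Nishina distribution,
electron direction from kinematics), pair production above 1.022 MeV
(Bethe–Heitler high-energy form with Z(Z+1) folding in triplet production;
annihilation photons re-emitted isotropically at 0.511 MeV from the end of
the positron track), and photoelectric absorption (Z^4.5/E³ scaling,
relevant only below ~0.1 MeV). Photon and electron cutoffs default to
1 keV and 70 keV (kinetic energy); the photon cutoff is configurable down
to 0.1 keV, with no visible effect on 0.5 cm tallies at 15 MV.

Secondary electrons use a *kernel* model rather than condensed-history
transport: each electron travels along a straight track whose direction is
the kinematic direction perturbed once by a transverse Gaussian
(`lateral_frac`, default 0.30 — this makes the lateral spread of deposited
energy grow as σ(s) = 0.30·s along the track, the mechanism behind lateral
disequilibrium), and deposits energy uniformly per unit *mass* path over an
effective range `forward_fraction × R_CSDA` (default 0.80, accounting for
path detours; Katz–Penfold range below 2.5 MeV, linear extension above).
Substeps are clipped at slab boundaries so that dose per unit mass stays
continuous across density interfaces. Track lengths scale with the local
relative electron density, which quadruples electron ranges in 0.26 g/cm³
lung and produces the field-size-dependent lung dose depression.

Square fields are converted to equal-area circular fields, `R = L/√π`, for
the cylindrical geometry. Dose is reported for 60 depth bins of 0.5 cm;
uncertainties come from 20-batch statistics, and a fixed seed reproduces a
profile bit for bit (a dedicated xoshiro256++ generator, independent of R's
RNG state).

**Scoring estimators.** Two estimators are provided:

* `scoring = "axis"` (default): because the slab geometry is laterally
  invariant, the central-axis dose of a uniform disk field equals the
  energy a *pencil* beam deposits within the field radius (a reciprocity
  identity familiar from kernel-superposition dose engines). The engine
  transports a central pencil and collects deposits within the
  depth-projected field radius, applying the inverse-square fluence factor.
  Nearly every history contributes, so the 10×10 cm² field reaches a
  relative standard error below 0.5% at the maximum-dose bin with ~2·10⁶
  histories on one CPU core.
* `scoring = "chip"`: the analog estimator — a divergent point source
  sampled over the field disk, scored in a fixed cylinder whose
  cross-section equals the 3.0×3.0 mm² TLD chip face (radius 0.16926 cm).
  This estimator is selected automatically whenever a detector chip is
  inserted, because the insert breaks the lateral invariance the
  reciprocity estimator relies on.

**Detector perturbation.** `perturbation_profile()` implements the
paired-run workflow: for each depth the profile is simulated with and
without a 0.09 cm LiF chip at that depth, with the same seed for both runs
so that histories decorrelate only where they touch the chip, and
`F_cor = PDD_TLD/PDD` at that bin. `apply_perturbation()` divides measured
doses by `F_cor` — the factor converts a detector-present value to a
detector-free one.

**Spectrum.** The 15 MV spectrum is a parametric thin-target-style shape,
weights ∝ (E/θ)^0.6·exp(−E/θ) on 0.25 MeV bins with a 15 MeV endpoint. The
scale θ = 2.6 MeV was calibrated once so that the homogeneous-water depth
of maximum dose lands near 3.0 cm (the physical dmax of a clinical 15 MV
beam); the resulting mean energy is 4.03 MeV and E0 = 1.225 MeV. The 6, 10
and 18 MV variants scale θ proportionally and are provided for
completeness.

## Heterogeneity corrections

`homogeneous_beam_data()` derives TMR from simulated homogeneous-water PDD
via `TMR(d) = PDD(d)·((SSD+d)/(SSD+dmax))²`, renormalized to 1 at dmax, and
sets TAR = TMR (peak scatter factor treated as 1; only relative factors
enter the corrections, and megavoltage backscatter is small). Tables extend
beyond the simulated 30 cm by an exponential tail fitted to the last bins,
so the dmax-shifted lookups of the modified Batho stay in range. Beam data
should bracket the field sizes of interest: the ETAR density-scaled radius
r·ρ̃ falls *below* the physical radius inside lung and *above* it in
acrylic, so the driver adds 0.4 cm and 1.25×max(L) bracketing fields.

The three algorithms, pinned to specific published variants:

* **Generalized Batho** (Sontag–Cunningham power-law form):
  `CF = Π_m TAR(z_m, r)^(ρ_m − ρ_above,m) / TAR(d, r)`, the product running
  over the layers at and above the point, `z_m` the distance from the point
  to the top of layer m, ρ the relative electron densities with the region
  above the phantom at ρ = 0. The division by `TAR(d, r)` is the same
  product on a homogeneous unit-density phantom, making CF exactly 1 there.
  TAR lookups are clamped at dmax: classical TAR tables begin at dmax, and
  buildup-region values would otherwise blow up the power law at layer
  tops. A consequence worth knowing: with unity-normalized TAR the Batho CF
  dips slightly below 1 in the first few centimetres of lung before rising
  well above 1 deeper in.
* **Modified Batho**: the same product with `TMR(z + dmax, r)` in place of
  `TAR(z, r)`, restoring buildup behavior near interfaces.
* **Equivalent TAR**, 1-D slab simplification:
  `CF = TAR(d′, r·ρ̃)/TAR(d, r)` with `d′` the radiological depth and `ρ̃`
  the thickness-weighted mean relative electron density from the surface to
  d. The full 3-D scatter-weighted density integral is out of scope; in
  slab geometry the thickness-weighted mean is the natural reduction.

In the buildup region (`d < dmax`) the Batho variants are undefined and CF
is held at its dmax value. `corrected_pdd()` multiplies the homogeneous PDD
by CF per depth and renormalizes.

## Comparison analysis

`normalize_pdd()` scales a profile to 100 at the maximum-dose bin; on noisy
Monte Carlo curves the bin is the argmax of a 3-bin moving average (raw
values define the 100% level), which picks the planted maximum reliably for
bin noise up to ~1%. Measured and simulated curves are normalized by the
same policy so their ratio is meaningful. `ratio_curve()` divides two
curves on a common grid with quadrature uncertainties; `interface_metrics()`
reports, over a 1.0 cm window (two bins — the natural reading of "close to
the interface"), the lung overdose below the soft→lung interface, the
soft-tissue underdose below the lung→soft interface, and the maximum
|ratio − 1| over all lung bins.

## Synthetic TLD studies

`generate_tld_study()` emulates the measurement campaign: 60 dosimeters of
which 8 are stability controls; per-dosimeter sensitivities lognormal
around 1 (sd 0.05); per-dosimeter zero-dose signals (150 ± 30 reader
units); per-session reader drift (lognormal, sd 0.02); multiplicative read
noise (CV 1%); a characterization session with triple zero and triple
common-exposure readouts; a calibration session (the FCm reference) with
groups of eight at 25, 50 and 100 cGy; controls exposed to 100 cGy every
session; and two dosimeters per measured depth. A raw reading for dose D is
`TL0_i + S_i·drift_m·(D−B)/A·(1+ε)` with the generating calibration
A = 9·10⁻⁴ cGy per reader unit, B = 1.4243 cGy. The generating truth is
returned separately and never enters the readings table.

The processing chain inverts all of this with no access to the truth. With
every spread at zero the recovery is exact to float precision; at the
default noise model the recovered doses sit within 2% of truth at ≥95% of
depths pooled over 100 seeds, with zero mean bias and a total propagated
uncertainty below 5%. What this shows is that the *chain* is unbiased and
correctly propagates the modeled noise sources; it does not validate
effects absent from the generator — fading, supralinearity, glow-curve
shape, energy-dependent intrinsic response, or dose-rate effects — which
real TLD work must handle separately.

## Numerical choices and problem sizes

* Log–log interpolation for material tables; linear for beam-data tables;
  points on a slab interface belong to the deeper slab.
* The acceptance analysis uses 2·10⁶ histories for heterogeneous-phantom
  runs and 10⁶ per homogeneous beam-data field, which puts the dmax-bin
  relative standard error near 0.2–0.3% and runs the full script in well
  under a minute; unit tests use 10⁵–10⁶ histories per case. These sizes
  were chosen as the smallest at which the statistical uncertainty of each
  reported quantity is small compared to the effect it measures.
* The 1×1 cm² maximum lung discrepancy is a max-statistic over ~26 noisy
  bins; its seed-to-seed spread at these sizes is ±2 percentage points,
  and statistical comparisons against it are made within three standard
  errors of the bin estimate.

## Known limitations

* The electron kernel captures range scaling and lateral spread but not
  backscatter, bremsstrahlung secondaries, or detailed angular evolution;
  condensed-history fidelity is explicitly out of scope. Interface dose
  structure finer than the 0.5 cm bins is not resolved.
* Compton scattering treats electrons as free (no binding/Doppler), pair
  production uses the unscreened high-energy form (zero below ~3.6 MeV,
  where its share of the total is negligible at 15 MV), and Rayleigh
  scattering is omitted.
* The spectrum is a parametric stand-in tuned to dmax, not a published
  linac spectrum tabulation; off-axis softening and electron contamination
  are not modeled (surface dose is therefore underestimated).
* ETAR is the 1-D slab reduction; no 3-D scatter integration.
* The paired-run perturbation workflow inherits the kernel's locality: it
  reproduces unit factors for matched media and stable factors for LiF, but
  absolute chip perturbations in severe disequilibrium carry model error
  beyond the quoted statistics.
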