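---
title: "Modelling ultrasonic attenuation in cancellous bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultrasonic attenuation in cancellous bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneatten)
```

## The model

Cancellous (trabecular) bone is a porous composite: a network of solid
trabecular struts immersed in fluid-like marrow. Clinical bone
ultrasound works in the 0.2–1.5 MHz range, where attenuation is driven
by two mechanisms: viscous absorption in the marrow and scattering from
the trabeculae, whose acoustic impedance (about 7.9 × 10⁶ kg s⁻¹ m⁻²)
greatly exceeds that of marrow (about 1.3 × 10⁶ kg s⁻¹ m⁻²).
`boneatten` implements a deliberately minimal two-phase model of this
situation:

* the marrow is a fluid with density ρ, sound speed c, and an empirical
  absorption power law α₁ = a₀ fⁿ (dB/cm, f in MHz);
* the trabeculae are identical, infinitely long, isotropic elastic
  cylinders of radius a (density ρ₁, longitudinal speed c₁, Poisson
  ratio ν), oriented perpendicular to the incident wave, occupying the
  bone volume fraction ∅ (porosity 1 − ∅);
* single scattering only: each cylinder scatters as if alone in an
  infinite marrow bath.

The total attenuation coefficient is then

$$\alpha(f) \;=\; (1-\emptyset)\,\alpha_1(f) \;+\;
\tfrac12\, \frac{\emptyset}{\pi a^2}\, \gamma^{\mathrm{sca}}(f),$$

where γ^sca is the scattering cross-section per unit length of one
cylinder and ∅/(πa²) the number of cylinders per unit cross-sectional
area. The factor ½ converts the intensity extinction rate n_s γ into an
amplitude attenuation coefficient. Absorption inside the trabeculae is
neglected (small solid fraction, large impedance mismatch); the general
formula with a non-zero inclusion absorption cross-section is available
as `general_attenuation()`.

## The scattering solution

γ^sca comes from the classical partial-wave solution for a plane wave
scattered by a solid elastic cylinder in a fluid. Writing x = ka for
the size parameter in the fluid and x₁ = k₁a, x₂ = k₂a for the
compressional and shear size parameters inside the solid,

$$\gamma^{\mathrm{sca}} = \frac{4a}{ka}\sum_{m=0}^{\infty}
\epsilon_m \sin^2 \eta_m, \qquad \epsilon_0 = 1,\; \epsilon_{m>0} = 2,$$

with phase shifts η_m determined by the boundary conditions at the
cylinder surface: continuity of radial displacement and normal stress,
and zero shear traction. In the familiar angle notation,

$$\tan\eta_m = \tan\delta_m(x)\,
\frac{\tan\Phi_m + \tan\alpha_m(x)}{\tan\Phi_m + \tan\beta_m(x)},
\qquad \tan\Phi_m = \frac{\rho}{\rho_1}\tan\xi_m(x_1,\nu),$$

where δ_m, α_m, β_m are combinations of Bessel and Neumann functions of
x, and ξ_m encodes the elastic response of the solid cylinder. The
shear speed is derived from ν by the isotropic relation
c₂ = c₁ √((1 − 2ν)/(2(1 − ν))) — the only consistent closed form when ν
rather than c₂ is given.

Three numerical choices matter:

* **Tangent-free evaluation.** The angles are never materialized as
  tangents. Each is carried as a numerator/denominator pair, so zeros
  of J_m or N_m (where a tangent is infinite) cause no loss of
  precision and no spurious branch jumps; `phase_shift()` reports the
  principal angle, and the cross-section uses sin²η_m which is
  branch-free. A continuity test (step 10⁻³ in ka) guards against
  branch errors.
* **The boundary angle ξ_m.** Published transcriptions of ξ_m vary and
  are easy to get wrong. The package derives ξ_m directly from the
  boundary-value problem: the shear potential is eliminated through the
  zero-shear-traction condition and ξ_m is the resulting ratio
  ρ₁ω²a·u_r/σ_rr of the condensed solid response. A variant
  transcription containing two typographical errors (an extra "+ m − 1"
  term and a doubled tan α_m(x₁)) is retained behind
  `xi_form = "printed"` purely so the discrepancy is demonstrable in
  the test suite; it is wrong for every m and is not used anywhere.
* **Truncation.** The series starts at m_max = max(10, ⌈ka⌉ + 12) and
  extends until the latest term ε_m sin²η_m falls below 10⁻¹² of the
  running sum (hard cap m = 200, raising a convergence error). A test
  verifies that 15 further orders change γ^sca by less than 10⁻¹⁰
  relative for ka ≤ 5.

Correctness of the whole chain is pinned by independent references
frozen into the tests: a 50-significant-digit solution of the full
three-condition boundary system (computed once, independently of the
package's condensation route) on 20 seeded parameter draws and on the
default-material ka grid; the rigid-cylinder limits η_m →
arctan(−J′_m/N′_m) and γ^sca/(a(ka)³) → (3/4)π²; and the elastic
long-wavelength closed form

$$\frac{\gamma^{\mathrm{sca}}}{a\,(ka)^3} \;\to\; \frac{\pi^2}{4}
\left[\Big(1-\frac{\kappa_e}{\kappa}\Big)^2 +
2\Big(\frac{\rho_1-\rho}{\rho_1+\rho}\Big)^2\right],$$

with κ = 1/(ρc²) the fluid compressibility and κ_e = 1/(λ + μ) the
plane-strain compressional compliance of the solid (monopole +
dipole contributions; the rigid limit κ_e → 0, ρ₁ → ∞ recovers
(3/4)π²). The far-field angular pattern (`angular_intensity()`)
is checked against the cross-section by quadrature:
γ^sca = (2a/(π ka)) ∫ I(θ) dθ.

## Units

The absorption prefactor a₀ is interpreted as dB/cm at 1 MHz, the
convention of the clinical bone-ultrasound literature, and the
scattering term — natively Np/m — is converted with 1 Np = 8.6859 dB.
This pairing, together with reading the "trabecular size" of 100 µm as
the cylinder *radius*, reproduces the reference behaviour of the model
(absorption/scattering crossover near 0.6 MHz at porosity 80%); a
Np-based reading of a₀, or a diameter reading of the size, does not
(the diameter reading moves the crossover to ≈ 1.4 MHz). Both choices
are therefore fixed as defaults, the radius is an explicit argument
everywhere, and `units = "np_cm"` exposes Neper output.

## Default study conditions

`default_bone_model()` fixes the reference conditions used by the
worked examples and the acceptance script: trabecular tissue 2000 kg/m³,
3929 m/s, ν = 0.24; marrow 900 kg/m³, 1400 m/s, α₁ = 3.15 f^1.15 dB/cm;
radius 100 µm; porosity 80%. Physiological context for the sweeps:
trabecular thicknesses of roughly 80–440 µm and porosities of
0.7–0.95 span healthy to osteoporotic cancellous bone, which is why
`porosity_sweep()` defaults to that interval and the size sweeps use
40–150 µm radii.

## What the model predicts

```{r headline}
model <- default_bone_model()
spec <- total_attenuation(seq(0.3, 0.65, length.out = 50), model)

powerlaw_exponent(spec$f_mhz, spec$alpha_scattering)
crossover_frequency(model)
bua(spec)
```

Three headline behaviours emerge, all computed (never asserted) by the
test suite:

* **Near-cubic scattering.** Over 0.3–0.65 MHz the scattering component
  fits a power law with exponent ≈ 2.86 — close to the cubic Rayleigh
  behaviour, reduced slightly because ka reaches ≈ 0.29 at the top of
  the band where the full series grows more slowly than (ka)³.
* **Crossover near 0.6 MHz.** Absorption dominates below ≈ 0.62 MHz,
  scattering above (radius 100 µm, porosity 80%).
* **Quasi-linear total attenuation.** The strongly non-linear
  scattering is partially compensated by the quasi-linear absorption
  term, so the total fits a straight line over the clinical band with
  r² ≈ 0.988, slope ≈ 6.7 dB/cm/MHz. This is the theoretical basis for
  measuring bone status by a single BUA slope. The r² is insensitive to
  grid density (0.985–0.989 for 5–200 points); the model's curve is
  quasi-linear, not perfectly linear.

At fixed frequency the total attenuation is *exactly* affine in
porosity — both terms are linear in the volume fractions — and
decreasing, and the BUA slope decreases with porosity; both trends
match published measurements on cancellous bone. Attenuation increases
with trabecular radius (scattering grows like a² per unit solid
fraction in the Rayleigh regime).

## Fitting choices

* **BUA band** frozen at 0.3–0.65 MHz (overridable), OLS with
  intercept; the slope is reported in dB/cm/MHz.
* **Power-law fits** are OLS in log–log space on a 50-point uniform
  grid by default; the exponent moves by < 0.005 between 25 and 200
  points, so grid density is immaterial.
* **Crossover search** scans 100 points for sign changes and refines
  each bracket by bisection to 10⁻⁴ MHz; absence of a sign change is
  reported explicitly as `"no_crossover"` (e.g. porosity 1, no
  scatterers), multiple crossings return the lowest and are flagged.

## Problem sizes

The reference figure tables (`regenerate_figures()`) use 60 ka points
for the cross-section curve, 29 frequencies per spectrum, 1° angular
resolution for the polar patterns, and 11 porosities × 3 radii for the
porosity sweeps; the test suite and acceptance script use 50-point
frequency grids. These sizes render every figure smooth at publication
scale while keeping a full run of the suite in seconds; all outputs are
deterministic, so no seed plumbing exists anywhere in the package.

## Limitations

The model is a mechanistic caricature, useful for trends rather than
absolute calibration against any individual bone:

* trabeculae are uniform parallel cylinders of a single radius; real
  networks mix rods and plates with a distribution of sizes and
  orientations;
* single scattering only — no multiple scattering, no phase velocity or
  dispersion prediction;
* marrow viscosity enters only through the empirical power law, not as
  an explicit poroelastic mechanism;
* the absorption/scattering split at a given frequency depends on the
  dB/cm unit reconstruction described above.

Consequently the package's passing tests demonstrate internal
correctness of the scattering solution and the composite formula, and
reproduction of the predicted *trends*; they do not validate the model
against experimental attenuation magnitudes.
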