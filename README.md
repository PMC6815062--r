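# boneatten

Theoretical prediction of ultrasonic attenuation in cancellous
(trabecular) bone, for researchers in bone quantitative ultrasound (QUS)
who want a mechanistic, fully reproducible baseline for how attenuation
depends on frequency, trabecular size and porosity.

Cancellous bone is modelled as a two-phase composite: fluid marrow with
empirical power-law absorption, containing identical solid elastic
cylinders (the trabeculae) that scatter the incident wave. The total
attenuation coefficient is

```
alpha(f) = (1 - phi) * alpha_1(f)  +  0.5 * (phi / (pi a^2)) * gamma_sca(f)
```

with `phi` the bone volume fraction (porosity `1 - phi`), `a` the
cylinder radius, `alpha_1 = a0 f^n` the marrow absorption (dB/cm, `f` in
MHz), and `gamma_sca` the scattering cross-section per unit length of
one cylinder from the classical partial-wave series

```
gamma_sca = (4a / ka) * sum_m eps_m sin^2(eta_m)
```

whose phase shifts `eta_m` solve the fluid–elastic-cylinder boundary
conditions (Bessel/Neumann functions of `ka` outside; compressional and
shear waves inside). The package provides the full scattering solution
(phase shifts, cross-sections, polar patterns, Rayleigh limit),
attenuation spectra, and the QUS summary statistics: broadband
ultrasound attenuation (BUA) slope, power-law exponent of the scattering
component, absorption/scattering crossover frequency, porosity and size
sweeps. See the vignette (`vignettes/cancellous-bone-attenuation.Rmd`)
for the model's assumptions, unit conventions and limitations.

## Worked example

```r
library(boneatten)

model <- default_bone_model()   # radius 100 um, porosity 80 %,
                                # marrow 900 kg/m^3 / 1400 m/s / 3.15 f^1.15 dB/cm,
                                # trabeculae 2000 kg/m^3 / 3929 m/s / nu 0.24
spec <- total_attenuation(seq(0.3, 0.65, length.out = 50), model)

powerlaw_exponent(spec$f_mhz, spec$alpha_scattering)
#> <powerlaw_fit>
#>   prefactor: 5.7016 dB/cm at 1 MHz, exponent: 2.8628
#>   r^2 (log-log): 0.99994

crossover_frequency(model)
#> # A tibble: 1 × 3
#>   crossover_mhz status n_crossings
#>           <dbl> <chr>        <int>
#> 1         0.623 ok               1

bua(spec)
#> <linear_fit>
#>   slope: 6.7357 dB/cm/MHz, intercept: -1.3635 dB/cm
#>   r^2: 0.98824 on 50 points in [0.3, 0.65] MHz
```

Reading these numbers: the scattering component grows almost with the
cube of frequency (exponent 2.86, the long-wavelength Rayleigh regime
for cylinders), absorption dominates below 0.62 MHz and scattering
above, and the *total* attenuation is nevertheless quasi-linear in
frequency over the clinical 0.3–0.65 MHz band (r² 0.988) — the
compensation between the two mechanisms that justifies the clinical BUA
slope, here 6.7 dB/cm/MHz. Attenuation falls exactly linearly with
porosity:

```r
porosity_sweep(model, c(0.7, 0.8, 0.9), f = 0.5)
#>   porosity alpha_total alpha_absorption alpha_scattering
#> 1      0.7        2.18            0.994            1.18
#> 2      0.8        1.92            1.14             0.788
#> 3      0.9        1.67            1.28             0.394
```

`autoplot()` renders spectra and sweeps; `plot_polar_pattern()` draws
the angular scattering diagrams.

## Command line

A thin executable wrapper lives at `inst/cli/boneatten.R`
(installed under `system.file("cli", "boneatten.R", package = "boneatten")`):

```sh
Rscript inst/cli/boneatten.R predict --fmin 0.1 --fmax 1.5 --npoints 29 --out spectrum.csv
Rscript inst/cli/boneatten.R pattern --ka 0.25 --out pattern.csv
Rscript inst/cli/boneatten.R figures --out figures/
```

Subcommands: `predict`, `pattern`, `crosssection`, `bua`, `crossover`,
`sweep-porosity`, `sweep-size`, `figures`. All outputs are
self-describing CSV tables (parameters embedded as `#` header lines),
byte-identical across runs; JSON configs are validated with unknown keys
rejected. Exit codes: 0 success, 2 validation error, 3 non-convergence.

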