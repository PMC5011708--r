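# qenscell

Four-component quasi-elastic neutron scattering (QENS) analysis of live
cells: model, fit and compare the dynamics of bulk water, hydration water,
the proteome and an immobile fraction in whole-cell spectra.

## The problem

QENS resolves diffusive molecular motions as a broadening of the elastic
line in the dynamic structure factor *S(Q, ω)*. In a cell pellet measured in
D₂O, the incoherent signal is dominated by four proton populations with very
different rates, and their spectrum is modelled as

    S(Q,ω) = p_el·R(ω) + [ p_bulk·S₁ + p_hyd·S₂ + p_prot·S₃ ] ⊗ R + B(Q)

with `p_el + p_bulk + p_hyd + p_prot = 1`. Each water population (S₁, S₂) is
translational jump diffusion — HWHM `Γ(Q) = ħ·D_T·Q² / (1 + D_T·Q²·τ)` —
convolved analytically with isotropic rotational diffusion (spherical-Bessel
weights `(2l+1)·j_l²(Qa)`, widths `ħ·l(l+1)·D_R`); the proteome S₃ is a broad
Q-independent Lorentzian of HWHM `Γ_prot`; `R` is the instrument resolution
(analytic Voigt profiles for a Gaussian `R`). The package is written for
analyses like the comparison of a piezophilic and a pressure-sensitive
*Thermococcus* species at 0.1 and 40 MPa, where the headline observable is a
~35% slowdown of the hydration-water diffusion coefficient under pressure.

It provides, tidyverse-style (tibbles in and out, `tidy()`/`glance()`
methods, `autoplot()` figures):

- the forward spectral model (`composite_model()`, `voigt_profile()`,
  `jump_diffusion_hwhm()`, `rotational_weights()`, ...);
- a synthetic-spectrum generator emulating a 10 Å cold-neutron
  time-of-flight configuration (19 detector groups, 0.20–1.10 Å⁻¹, 10 μeV
  Gaussian resolution) with Poisson counting noise, plus the four published
  whole-cell parameter sets as generating truths (`preset_in5()`,
  `scenario_params()`, `generate_spectra()`);
- per-Q model-free Lorentzian fits, dispersion curves (HWHM vs Q²) and
  jump-diffusion fitting (`fit_model_free()`, `extract_dispersion()`,
  `fit_jump_diffusion()`);
- a global multi-Q weighted least-squares fit with multi-start and
  curvature-based standard errors (`fit_global()`), derived quantities and
  cross-condition comparisons (`derived_quantities()`, `compare_fits()`);
- columnar text I/O and an end-to-end pipeline with a thin CLI
  (`read_spectrum_set()`, `run_pipeline()`, `inst/scripts/qenscell`).

## Worked example

Simulate one condition at realistic counting statistics and refit it:

```r
library(qenscell)

set <- generate_spectra(scenario_params("Tb_0.1MPa"),
                        noise = "poisson", counts_per_spectrum = 1e5,
                        seed = 1)
fit <- fit_global(set, seed = 1)
tidy(fit)
```

```
# A tibble: 11 × 6
   term           estimate std.error unit         fixed at_bound
   <chr>             <dbl>     <dbl> <chr>        <lgl> <lgl>
 1 p_elastic        0.0111   0.00219 ""           FALSE FALSE
 2 p_hyd            0.0987   0.00227 ""           FALSE FALSE
 3 p_proteome       0.225    0.00161 ""           FALSE FALSE
 4 d_t_bulk         1.98     0.00981 "1e-5 cm2/s" FALSE FALSE
 5 tau_bulk         1.07     0.0907  "ps"         FALSE FALSE
 6 d_r_bulk         0.106    0.00503 "1/ps"       FALSE FALSE
 7 d_t_hyd          5.36     0.315   "1e-7 cm2/s" FALSE FALSE
 8 tau_hyd          0        0       "ps"         TRUE  FALSE
 9 d_r_hyd          0.0740   0.0188  "1/ps"       FALSE FALSE
10 gamma_proteome   0.420    0.00478 "meV"        FALSE FALSE
11 p_bulk           0.666    0.00170 ""           FALSE FALSE
```

The generating truth was the `Tb_0.1MPa` scenario — bulk water with
`D_T = 1.98e-5 cm²/s` and `τ = 1.05 ps`, hydration water at
`D_T = 5.17e-7 cm²/s`, `Γ_prot = 0.431 meV`, fractions
(0.0099, 0.6634, 0.0990, 0.2277) — and every estimate above sits within a
couple of its standard errors of it. `glance(fit)` reports
`chi2_reduced = 1.03` on 5719 points, i.e. the weights are consistent with
the counting noise, and `derived_quantities(fit)` turns the rotational
coefficients into correlation times `1/(2·D_R)` (here 4.7 ps for bulk
water). Comparing two fitted pressures,

```r
compare_fits(fit_ambient, fit_high, "0.1 MPa", "40 MPa")
```

tabulates per-parameter changes; for the published parameter sets the
hydration-water diffusion coefficient of the piezophile drops
`5.17 → 3.34 ×1e-7 cm²/s`, a 35% decrease at integer rounding, while
`d_t_bulk` does not change at all.

The same workflow runs from the shell:

```sh
inst/scripts/qenscell simulate --scenario Tb_0.1MPa --noise poisson --seed 1 --out tb01.tsv
inst/scripts/qenscell fit --input tb01.tsv --outdir out_tb01
inst/scripts/qenscell dispersion --input tb01.tsv --n-lorentzians 3 --component 2 --out disp_bulk.csv
```

writing `params.csv`, `params_stderr.csv`, `dispersion_*.csv`,
`derived.json` and a seeded, reproducible `run.log`.

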