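# foldshift

Quantitative analysis of two-state fold-switching protein equilibria from
slow-exchange NMR peak volumes.

Some proteins interconvert between two stably folded conformations — for
example a PAS domain whose central β-strand can slip its register by three
residues, inverting the strand while keeping the domain folded. When the
interconversion is slow on the NMR chemical-shift timescale, each conformer
contributes its own resolvable peaks to an HSQC spectrum, and the relative
peak volumes report the conformer populations directly. `foldshift` turns
those conformer-assigned peak volumes into thermodynamics and ligand-binding
parameters:

* **Population quantification** — percent populations and the equilibrium
  constant `Keq = [WT]/[SLIP]` per condition, with per-residue peak pairing
  and jackknife uncertainties.
* **Van't Hoff analysis** — ordinary least squares of `ln Keq` on `1/T` over
  a selected linear region: the slope is `−ΔH/R`, the intercept `ΔS/R`, and
  `ΔG(T) = ΔH − TΔS` (ΔH in kcal mol⁻¹, ΔS in cal mol⁻¹ K⁻¹).
* **Four-state conformational selection** — a ligand that binds the WT
  conformer (dissociation constant `kd_wt`) and the SLIP conformer
  negligibly couples the binding and conformational equilibria in a
  thermodynamic cycle. Solving both mass balances by 1-D root-finding on
  the free-ligand concentration predicts the ligand-driven population
  shift; the cycle closes as `Keq_bound = Keq_apo · kd_slip / kd_wt`.
* **Titration analysis** — from unperturbed peaks (no chemical-shift change
  on binding), volume ratios against the zero-ligand reference scale the
  conformer pools (`C_WT,T = C_WT,0 · V_WT/V_WT,0`, likewise for SLIP), and
  the bound-WT concentration follows from the unchanged apo equilibrium:
  `C_WT,B = C_WT,T − Keq_apo · C_SLIP`. Fitting the single-site isotherm
  `C_WT,B = Bmax · CL/(Kd + CL)` yields `Kd` and `Bmax`; a
  maximum-likelihood alternative (`fit_titration_ml()`) fits the four-state
  forward model to every peak volume at once. For a bound state too weak to
  observe, `lower_bound_kd()` bounds its affinity: if at most a fraction
  `f` of the pool is bound at the highest ligand concentration `CL_max`,
  then `Kd ≥ CL_max (1 − f)/f`.
* **Synthetic data** — a seeded generator produces peak-volume tables from
  known ΔH/ΔS, binding parameters, per-peak response factors and
  multiplicative noise, so every stage is testable by parameter recovery.

## Worked example

Simulate a temperature series (ΔH = 6.8 kcal mol⁻¹, ΔS = 23.9 cal mol⁻¹ K⁻¹,
278–303 K, 3 % volume noise), quantify it, and fit:

```r
library(foldshift)

cfg <- synthetic_config(noise_cv = 0.03, seed = 42,
                        temperature_grid = seq(278, 303, by = 5))
pops <- percent_populations(generate_equilibrium_series(cfg))
vant_hoff_fit(pops, region = select_linear_region(pops))
#> Van't Hoff fit (SLIP -> WT conversion, Keq = [WT]/[SLIP])
#>   dH:    6.820 +/- 0.212 kcal mol^-1
#>   dS:   24.001 +/- 0.729 cal mol^-1 K^-1
#>   dG(298 K): -0.332 kcal mol^-1
#>   r^2 = 0.99617 over 6 temperatures (278-303 K)
```

The fitted enthalpy and entropy recover the generator's values within their
standard errors: the conversion towards WT is endothermic but favoured at
298 K by entropy (negative ΔG). `tidy()` and `glance()` return the same
results as tibbles.

A ligand titration of the same protein (50:50 apo equilibrium, 200 µM
protein, WT-selective ligand with Kd = 684 µM, 0–1000 µM ligand):

```r
series <- generate_titration(synthetic_config(noise_cv = 0.03, seed = 42))
titration_fit(series)        # classical volume-accounting + isotherm fit
#> Single-site isotherm fit: C_WT,B = Bmax * CL / (Kd + CL)
#>   Kd   =  475.309 +/- 131.168 µM
#>   Bmax =   80.098 +/- 13.203 µM
#>   7 points, residual sd 2.7 µM
fit_titration_ml(series)     # maximum-likelihood four-state fit
#> Maximum-likelihood four-state titration fit (profiled log volumes)
#>   Kd (WT conformer) = 732.5 +/- 29.9 µM
#>   fixed inputs: Keq_apo = 1, p_total = 200 µM
#>   70 volumes, residual log-sd 0.0334
```

Both estimators target the same conformer-intrinsic Kd (truth 684 µM);
the ML fit pools information across all titration points and is markedly
less sensitive to noise in the zero-ligand reference (see the methods
vignette). A bound state invisible in the spectra is bounded rather than
fitted:

```r
lower_bound_kd(cl_max = 1000, max_bound_fraction = 0.10)
#> [1] 9000    # µM, i.e. 9 mM
```

Each result type has an `autoplot()` method (populations vs condition,
van't Hoff line, binding isotherm) and `plot_shift_curve()` draws the
predicted ligand-driven population shift from `predict_shift_curve()`.
`run_pipeline()` drives the same analyses from a YAML configuration and
writes delimited reports; `inst/scripts/foldshift` wraps it as a shell
command with subcommands `simulate`, `quantify`, `vanthoff`, `titration`
and `shift-curve`.

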