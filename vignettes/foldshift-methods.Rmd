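---
title: "Quantifying fold-switching equilibria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fold-switching equilibria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldshift)
```

## The measurement model

`foldshift` analyses proteins that interconvert between two stably folded
conformations, labelled WT (the original fold) and SLIP (the alternative,
register-slipped fold), in slow exchange on the NMR chemical-shift
timescale. Slow exchange means each conformer gives its own resolvable
peaks, and for well-dispersed, unoverlapped peaks the volume of a
conformer's peak is proportional to that conformer's concentration times a
per-peak response factor. Everything in the package rests on that single
proportionality; peak picking, lineshape fitting and assignment are
upstream and out of scope.

Conventions used throughout:

* the equilibrium constant is always the SLIP→WT direction,
  `Keq = [WT]/[SLIP]`, so a 50:50 mixture has `Keq = 1` and WT-favoured
  conditions have `Keq > 1`;
* concentrations are µM, temperatures K, enthalpies kcal mol⁻¹, entropies
  cal mol⁻¹ K⁻¹ (the conventional reporting units; the factor of 1000
  bridging kcal and cal is applied internally and tested);
* the gas constant is fixed at `R_KCAL = 1.98720425e-3` kcal mol⁻¹ K⁻¹.

### Population quantification

`percent_populations()` converts a condition's conformer-labelled volumes
into percent populations. When a WT and a SLIP peak share a residue tag
(the `peak_id` minus a `wt`/`slip` affix), the pair's percentage
`100·V_WT/(V_WT+V_SLIP)` is computed per pair and averaged, and the spread
across pairs is reported as `sd_percent`; response factors shared within a
pair cancel exactly. Without pairing information, volumes are summed per
conformer and the uncertainty comes from a leave-one-peak-out jackknife.
Pairing was chosen as the default because amide experiments naturally
yield one peak per conformer per residue; summing is the fallback because
published population ratios are frequently reported from summed volumes.
Conformationally locked samples (population 0 or 100 %) have no finite
`Keq`; `keq_from_percent()` refuses them rather than returning an
infinity, since tables conventionally report such entries as censored
("<1", ">99") rather than as numbers.

### Van't Hoff analysis

`vant_hoff_fit()` is ordinary least squares of `ln Keq` on `1/T`:
slope `= −ΔH/R`, intercept `= ΔS/R`, with standard errors from the linear
fit. The fit is unweighted by default — matching the usual practice of
fitting the linear region directly — with optional inverse-variance
weights propagated from `sd_percent` by the delta method. `ΔG(T) = ΔH −
T·ΔS` with `T = 298 K` as the headline temperature (a `temperature`
argument accepts 298.15 for those who prefer the thermochemical
convention).

Apparent equilibria of fold-switching proteins are often van't
Hoff-linear only over part of the accessible range; at higher temperatures
aggregation during interconversion can pin the apparent `Keq` at a
plateau. `select_linear_region()` therefore either applies a fixed
temperature cutoff (default 303 K) or, in `auto` mode, scans contiguous
low-temperature windows of at least `min_points` temperatures and keeps
the one maximising r²; near-ties (within 1e-9) resolve towards the larger
window so perfectly linear data return the full range. Plateau points are
excluded from fitting but retained in reports.

### The four-state cycle and its solver

With a ligand that binds WT (dissociation constant `kd_wt`) and SLIP
(`kd_slip`, possibly non-binding), the four protein states are linked by

* `[WT_u] = Keq_apo · [SLIP_u]`
* `[WT_b] = [WT_u] · L / kd_wt`, `[SLIP_b] = [SLIP_u] · L / kd_slip`
* protein and ligand mass balances,

where `L` is the free-ligand concentration. Cycle closure gives
`Keq_bound = Keq_apo · kd_slip / kd_wt`: a WT-selective ligand
(`kd_wt < kd_slip`) makes the bound equilibrium more WT-favoured, which is
the thermodynamic engine of the population shift.

`solve_four_state()` reduces the system to one dimension: for fixed `L`
every species is linear in `[SLIP_u]`, so the protein balance gives
`[SLIP_u]` in closed form and the ligand balance becomes a strictly
increasing scalar function of `L` with a guaranteed sign change on
`[0, L_total]`. A bracketed root search (`stats::uniroot` plus one Newton
polish) is unconditionally convergent and deterministic; the solved state
is verified against both mass balances at a relative tolerance of 1e-10
and the call fails loudly rather than returning an unconverged state. A
non-binding conformer is represented by `kd_slip = Inf` — exact in IEEE
arithmetic (`L/Inf` is exactly 0), so no special-casing or large-number
overflow enters the solver.

### Titration analysis

The classical protocol (`titration_fit()`) follows the volume-accounting
inversion. Peaks that show no chemical-shift perturbation on binding
report their conformer's total concentration (bound plus unbound), so
volume ratios against the zero-ligand reference scale the known
zero-ligand pools:

`C_WT,T = C_WT,0 · (V_WT / V_WT,0)`, `C_SLIP = C_SLIP,0 · (V_SLIP / V_SLIP,0)`.

Assuming the SLIP conformer stays in its apo equilibrium with the
*unbound* WT conformer, `C_WT,B = C_WT,T − Keq_apo · C_SLIP`. The
`Keq_apo` factor generalises the 50:50 special case (where it is 1 and
the expression collapses to a plain difference) to variants whose apo
ratio is away from 50:50. Only unperturbed-flagged peaks enter the
ratios: how partially broadened peaks should be weighted is not
determinable from volumes alone, so they are excluded rather than
guessed at. Negative `C_WT,B` values arising from noise are clipped to
zero and flagged, keeping the ligand grid intact for fitting.

Two facts shape the isotherm step. First, written against *free* ligand,
the four-state model's bound-WT concentration is exactly a single-site
isotherm — but with apparent constants fixed by linkage:
`Kd_app = kd_wt (1 + Keq_apo)/Keq_apo` and `Bmax_app = p_total` (at
saturation the entire protein converts to bound WT). Second, written
against *total* ligand it is not a hyperbola at all once ligand depletion
matters. `titration_fit()` therefore extracts `CL_free = L_total −
C_WT,B` (exact when the other conformer is non-binding), fits
`C_WT,B = Bmax·CL/(Kd+CL)` by bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`; starting values `Kd₀ = median CL`,
`Bmax₀ = 1.2·max C_WT,B`; bounds `Kd ∈ (0, 10⁶]`,
`Bmax ∈ (0, p_total]` — bound ligand cannot exceed the protein total),
and by default converts the apparent parameters back through the linkage
factor `Keq_apo/(1+Keq_apo)`: the reported `kd` is then the
conformer-intrinsic dissociation constant and `bmax` the apo WT pool.
This makes the noiseless pipeline an exact inverse of the generator;
`intrinsic = FALSE` reports the apparent parameters instead, and the
unconverted fit is always retained. Because the apparent `Bmax` truth
lies on its physical bound, its noisy estimates are right-censored
there; the reported `bmax` consequently never exceeds the conformer
pool implied by `p_total`.

The classical protocol has a structural weakness: the single zero-ligand
point calibrates the entire series, so noise in the reference volumes
rescales every derived concentration coherently and propagates strongly
into `Kd`. `fit_titration_ml()` is the package's recommended estimator
when the generative assumptions hold: under multiplicative lognormal
noise, `log V_ij = log ρ_j + log C_i(kd) + ε`, the per-peak response
factors `ρ_j` profile out analytically, and minimising the profiled sum
of squares over `log kd` is maximum likelihood. Every titration point
then contributes to every peak's calibration. The trade-off is that
`p_total` and `Keq_apo` enter as fixed inputs rather than being absorbed
into a fitted `Bmax`. `methyl_titration_fit()` is a named entry point for
methyl-detected series (used when amide peaks broaden); the machinery is
identical because the model is observable-independent.

For a bound state too weakly populated or too broadened to observe,
`lower_bound_kd(CL_max, f)` inverts the isotherm at an assumed maximal
undetected occupancy `f`: `Kd ≥ CL_max (1 − f)/f`. With `CL_max = 1000`
µM and `f = 0.10` this gives 9000 µM (9 mM). The default `f = 0.10`
reflects a conservative detection limit for a slow-exchange species in a
crowded spectrum; the bound is linear in `CL_max` and decreases
monotonically in `f`.

## The synthetic-data generator

`synthetic_config()` + `generate_equilibrium_series()` /
`generate_titration()` define the study conditions under which the
pipeline is validated:

* temperature series: `Keq(T) = exp(ΔS/R − ΔH/(RT))` with defaults
  ΔH = 6.8 kcal mol⁻¹, ΔS = 23.9 cal mol⁻¹ K⁻¹ on 278–303 K in 5 K steps;
  an optional plateau (`plateau_above = 303`) pins `Keq` above the cutoff
  to emulate the aggregation-limited regime;
* titrations: species solved exactly by `solve_four_state()` for the
  default model `Keq_apo = 1`, `kd_wt = 684` µM, SLIP non-binding,
  `p_total = 200` µM on the grid 0, 25, 50, 100, 200, 500, 1000 µM;
* observables: five residue pairs by default (ten peaks, matching a
  typical set of well-dispersed amide pairs), volume = conformer
  population (or conformer total, for titrations) × response factor ×
  noise;
* noise: multiplicative lognormal with mean 1 and coefficient of
  variation `noise_cv` — volumes are positive and their errors scale with
  size, which additive Gaussian noise (available via
  `noise_model = "additive"`, truncated at zero) does not capture;
* determinism: an explicit `seed` gives byte-identical tables and leaves
  the session RNG stream untouched.

Response factors are shared within a residue pair by default (one factor
per residue): the WT and SLIP peak of the same residue experience similar
transfer efficiency, and independent per-peak factors would bias raw
population ratios even at zero noise, confounding recovery tests of the
quantifier. A double-length `response_factors` vector assigns independent
per-peak factors to probe exactly that bias; the titration inversion is
immune to it because response factors cancel in the Eq.-style volume
ratios. A `bound_attenuation < 1` deliberately violates the premise that
unperturbed peaks report conformer totals (emulating bound-state
broadening), which makes the inversion underestimate bound WT — useful
for sensitivity analysis, never the default.

What the generator does not emulate: peak overlap, baseline and
integration-region errors, chemical-shift drift with temperature or
ligand, partial broadening short of the all-or-none `bound_attenuation`,
co-solvent effects, and aggregation kinetics behind the plateau (only its
steady-state signature). Passing recovery tests therefore demonstrates
correctness of the inversion and fitting machinery under the stated
observation model, not robustness to every pathology of real spectra.

## Numerical choices and degenerate inputs

* Solver tolerance: mass-balance residuals < 1e-10 × totals, verified
  post hoc; no randomness anywhere in the solvers or fits.
* `percent_populations()` refuses all-zero conditions and single-conformer
  conditions by name; ambiguous residue tags (duplicated within a
  conformer) fall back to unpaired summing.
* `fit_isotherm()` requires ≥ 3 points including `CL = 0` and a non-zero
  signal; non-convergence reports the starting values.
* `fit_titration_ml()` requires strictly positive volumes (log space) and
  errors if the optimum lands on the `kd` search bound.
* Region selection needs ≥ 3 temperatures below the cutoff; the van't
  Hoff fit refuses non-positive `Keq` listing the offending conditions.
* Tie-break in `auto` region selection: larger window wins within 1e-9
  in r².

## Validation scale

The test suite validates by parameter recovery at sizes chosen to give
stable medians while keeping the default run fast: 1000-replicate
population-recovery and ΔH-recovery checks, 500-replicate titration
recovery at 5 % volume noise, 1000 random models against an independent
bisection oracle for the solver, and grid-based monotonicity properties.
`scripts/acceptance.R` re-runs the headline quantities (including the
500-replicate recovery) from scratch under a user-supplied seed.

## Known limitations

* The classical two-step titration protocol is sensitive to noise in the
  zero-ligand reference; prefer `fit_titration_ml()` when `p_total` and
  `Keq_apo` are reliably known, and treat the Eq.-style `Kd` standard
  error as optimistic otherwise.
* `Bmax` is weakly determined when the grid reaches well under apparent
  saturation (as in the default conditions, ~0.7 · Kd_app); its estimate
  leans on the physical bound discussed above.
* The lower-bound `Kd` inherits the arbitrariness of the assumed maximal
  undetected occupancy `f`; report `f` alongside the bound.
* Only 1:1 binding to each conformer is modelled — no cooperativity, no
  second site, no co-solvent corrections (keep DMSO ≤ 2 % in practice and
  treat it as a constant background).
* Interconversion kinetics are out of scope; all analyses assume full
  equilibration at every condition.
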