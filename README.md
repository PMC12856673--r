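# relaxex

Proton-exchange models for low-field NMR relaxation in aqueous sugar
solutions.

Time-domain NMR T1 (saturation recovery) and T2 (CPMG) measurements on
carbohydrate solutions show biexponential relaxation, which is commonly
attributed to "bound" vs "free" water. `relaxex` implements the
alternative, exchange-based account for people analyzing such data
(benchtop-NMR users in food science, pharma formulation, hydration
research): protons hop between water and solute hydroxyl sites by a
bimolecular mechanism, and carbon-bound solute protons relax on their
own, so multiexponential decays arise with no bound-water compartment.

## The model in brief

Two exchangeable proton pools — water (`A`, concentration A_tot) and
solute hydroxyls (`B`, B_tot) — exchange with a single second-order rate
constant k_ex, giving pseudo-first-order coefficients
`kA = k_ex * B_tot`, `kB = k_ex * A_tot`. Coupled to longitudinal
relaxation this yields a biexponential recovery with eigenrates

    lambda_{1,2} = [(rA + rB) -/+ sqrt((rA - rB)^2 + 4 kA kB)] / 2,
    rA = kA + R1_A,  rB = kB + R1_B,

and closed-form amplitudes; the transverse channel follows by
substituting R1_j -> R2_j - i omega_j. In the fast-exchange limit
`lambda1 ~ xA R1_A + xB R1_B` (population-weighted mean) and the fast
component's amplitude vanishes, so the *observed* second component comes
from the nonexchangeable protons: a biexponential fit recovers
`a_fast ~ xp_non`, the nonexchangeable proton fraction — a quantity
fixed by stoichiometry, not by water binding. A sucrose molecule has 14
carbon-bound and 8 hydroxyl protons, so for sucrose in high-purity D2O
the exchangeable fraction is 8/22 = 0.36 ~ 0.4 at every concentration.

The package provides:

* `proton_inventory()`, `freeze_dry_exchange()`, `wt_to_concentrations()`
  — stoichiometric proton bookkeeping for H2O / D2O / freeze-dried
  preparations;
* `exchange_pair()`, `longitudinal_solution()`, `transverse_solution()`,
  `fast_exchange_approx()`, `observed_signal()`, `ode_reference()` — the
  closed-form exchange model, its asymptotics and a tight-tolerance ODE
  oracle;
* `fit_recovery()`, `fit_cpmg()`, `select_model()`, `replicate_stats()`,
  `confidence_band()` — mono/biexponential fitting with F-test + runs-test
  model selection and bootstrap uncertainty;
* `simulate_decay()`, `simulate_series()` — a seeded synthetic TD-NMR
  generator for the three solvent scenarios;
* `run_inventory()`, `run_sweep()`, `run_fit()`, `run_compare()` and the
  `inst/cli/relaxex` Rscript — config-driven pipelines.

## Worked example

Predict the proton inventory of a 50 wt% sucrose solution, simulate a
saturation-recovery measurement including the nonexchangeable pool, and
fit it:

```r
library(relaxex)

inv <- proton_inventory(mixture_spec(0.5, "H2O"))
inv
#> Proton inventory (H2O, 50.0 wt%, basis mol_per_kg)
#>   A_tot = 55.51  B_tot = 11.69  C_nonexch = 20.45
#>   x_A = 0.8261  x_B = 0.1739  xp_exch = 0.7667  xp_non = 0.2333

pair <- exchange_pair_from_inventory(
  proton_inventory(mixture_spec(0.5, "H2O",
                                density = sucrose_solution_density(0.5))),
  R1_A = 0.5, R1_B = 1.2, k_ex = 0.05)
round(longitudinal_eigenrates(pair), 4)
#>   lambda1   lambda2
#>    0.6217 4132.5684

cur <- simulate_decay(pair, "saturation_recovery",
                      noise = noise_model(0.005, seed = 42),
                      nonexch_rate = 1 / 0.25,
                      nonexch_fraction = inv$xp_non)
fit_recovery(cur, fit_config(model_order = "bi", ci_method = "none"))
#> saturation_recovery biexponential fit: a_slow = 0.8033 (T = 1.544 s),
#>   a_fast = 0.1967 (T = 0.2146 s), y0 = 0.0027
#>   R2 = 0.999825, RMSE = 0.00526, converged = TRUE
```

Reading the output: 23.3% of the sample's protons are nonexchangeable
(`xp_non`); exchange is fast (`lambda2` ≈ 4100 1/s, so the exchangeable
pool relaxes as one component at `1/lambda1` ≈ 1.6 s), and the fitted
fast fraction `a_fast` ≈ 0.20 tracks `xp_non` — the coefficient reflects
proton stoichiometry, with the residual gap set by the noise level (see
the vignette for the attainable precision at 0.5–1% noise).

The command-line interface wraps the same pipelines:

```sh
Rscript inst/cli/relaxex inventory --config config.yaml --out inventory.csv
Rscript inst/cli/relaxex sweep     --config config.yaml --out sweep.csv
```

## Documentation

The methods vignette (`vignettes/exchange-relaxation.Rmd`) covers the
model and its assumptions, the fitting and model-selection protocol, what
the synthetic-data generator does and does not emulate, the attainable
fit precision (Cramér–Rao analysis), and numerical edge cases.
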