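---
title: "Proton exchange and biexponential NMR relaxation in sugar solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proton exchange and biexponential NMR relaxation in sugar solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxex)
```

## The problem

Low-field time-domain NMR relaxation measurements on hydrated
biomolecules and carbohydrate solutions routinely show two (or more)
relaxation components in both the longitudinal (T1) and transverse (T2)
channels. A long tradition reads the slow and fast components as "free"
and "bound" water. `relaxex` implements the alternative reading: in a
homogeneous solution, *bimolecular chemical exchange* of protons between
water and solute hydroxyl sites, plus the independent relaxation of
carbon-bound (nonexchangeable) solute protons, produces multiexponential
relaxation with no bound-water compartment at all.

## The model

Two pools of exchangeable protons are tracked: pool A (water protons,
total concentration $A^{tot}$ in mol/m$^3$) and pool B (solute hydroxyl
protons, $B^{tot}$). Because the molecules are electrically neutral,
proton transfer is a paired, second-order process with a single rate
constant $k_{ex}$ (units s$^{-1}$ per mol/m$^3$), giving
pseudo-first-order coefficients

$$k_A = k_{ex} B^{tot}, \qquad k_B = k_{ex} A^{tot}.$$

These are constants during an experiment but depend explicitly on
composition — the essential difference from the usual two-site
exchange treatment with free first-order rates. The longitudinal
magnetizations obey

$$\dot M_{z,A} = R_{1,A}(M^{\infty}_{z,A} - M_{z,A}) - k_A M_{z,A} + k_B M_{z,B},$$

and symmetrically for B. With $r_A = k_A + R_{1,A}$, $r_B = k_B + R_{1,B}$
the decay eigenrates are

$$\lambda_{1,2} = \tfrac12\left[(r_A + r_B) \mp \sqrt{(r_A - r_B)^2 + 4 k_A k_B}\right],$$

ordered slow-first. `longitudinal_solution()` returns the eigenrates and
the per-pool amplitudes; for saturation initial conditions (both pools
nulled) with equilibrium magnetizations proportional to pool sizes the
A-pool amplitudes reduce to the closed forms
$\Lambda_1 = -M^{\infty}_{z,A}(R_{1,A}-\lambda_2)/(\lambda_2-\lambda_1)$ and
$\Lambda_2 = -M^{\infty}_{z,A}(\lambda_1-R_{1,A})/(\lambda_2-\lambda_1)$,
which satisfy $\Lambda_1 + \Lambda_2 = M^{\infty}_{z,A}$ identically. We
verified algebraically (and test) that these closed forms *require* the
saturation + proportional-equilibrium assumptions: for any other initial
condition the general 2x2 eigendecomposition is used, and it reduces to
the closed forms in the saturation case. One algebraic subtlety: in
the normalized total-recovery expression the weight of mode $i$ is
$\Lambda_i (k_B + r_A - \lambda_i)/k_B$; only the $k_B$ form makes the
saturation signal vanish at $t = 0$ and drives the slow-component weight
to 1 in the fast-exchange limit, so that is what the package computes.

The transverse channel is obtained by the substitutions
$M^\infty_z \to 0$ and $R_{1,j} \to R_{2,j} - i\omega_j$, giving complex
eigenrates $\vartheta_{1,2}$ and amplitudes with
$\Theta_1 + \Theta_2 = M^{0}_{xy,A}$. On resonance (the default,
matching how CPMG data are fitted) everything is real.

Every closed form is validated against `ode_reference()`, a
`deSolve::lsoda` integration of the coupled equations at relative
tolerance $10^{-10}$; the test suite requires agreement to a relative
$10^{-8}$ over randomized parameter sets spanning slow, intermediate and
fast exchange.

### Fast-exchange asymptotics

When $R_{1,A}, R_{1,B} \ll k_A, k_B$,

$$\lambda_1 \simeq x_A R_{1,A} + x_B R_{1,B}, \qquad
  \lambda_2 \simeq k_{ex}(A^{tot}+B^{tot}) + x_B R_{1,A} + x_A R_{1,B},$$

with $x_A = A^{tot}/(A^{tot}+B^{tot})$, and the fast component's
amplitude vanishes ($a_{slow} \to 1$). The exchangeable pool then relaxes
with a single population-weighted rate — which is why, in protiated
water, a third proton class is needed to explain the observed second
component.

### The nonexchangeable pool

A sucrose molecule carries 14 carbon-bound protons that cannot exchange
but do relax. `observed_signal()` composes the total signal as
$(1-f_{non})\,s_{exch}(t) + f_{non}\,s_{non}(t)$ where $f_{non}$ is the
nonexchangeable proton fraction and $s_{non}$ a single exponential. In
the fast-exchange regime a biexponential fit of this composite recovers
$a_{fast} \approx f_{non}$ and $a_{slow} \approx 1 - f_{non}$ — the
package's central testable claim: *the fitted coefficients track proton
stoichiometry, not water binding.*

## Proton bookkeeping

`proton_inventory()` turns a preparation (sucrose wt%, solvent isotope,
site protiations) into pool concentrations and fractions by plain mole
accounting: sucrose C12H22O11 (342.30 g/mol, 14 CH + 8 OH), H2O
(18.015 g/mol) or D2O (20.027 g/mol) with 2 exchangeable sites each.
Labile hydrogen is assumed to scramble uniformly over all exchangeable
sites (solvent + hydroxyls), consistent with fast cyclic exchange; no
equilibrium isotope fractionation factor is applied. Two consequences
worth noting:

* In high-purity D2O with as-purchased sucrose, all protons come from
  the solute, so $x_p^{exch} = 8/22 \approx 0.36$ and
  $x_p^{non} = 14/22 \approx 0.64$ at *every* concentration. Rounded to
  one decimal this predicts a concentration-independent slow coefficient
  of 0.4 — the number `scripts/acceptance.R` recomputes.
* In H2O, $x_p^{non}$ grows monotonically with sucrose content, matching
  the growth of the fitted fast fraction.

```{r}
inventory_table(lapply(c(0.2, 0.5) , function(w)
  proton_inventory(mixture_spec(w, "H2O"))))
```

`freeze_dry_exchange()` models the partially deuterated preparation:
sucrose equilibrated in D2O carries away the equilibrium site occupancy
(total labile H over total exchangeable sites) through freeze-drying; for
20 wt% sucrose in ideal D2O that occupancy is 0.055. Back-exchange with
ambient moisture is neglected. Residual solvent protiation defaults to
0.003 (99.7 atom % D heavy water) and is configurable — predictions for
the freeze-dried scenario are sensitive to it, and the true value for any
given bottle is not derivable from first principles.

Molar concentrations (needed to form $k_A$, $k_B$) require a density;
fractions never do. When no measured density is supplied,
`sucrose_solution_density()` provides a quadratic fit to standard 25 °C
tables, $\rho = 997.0 + 3.7819 P + 0.017443 P^2$ kg/m$^3$ ($P$ in wt%),
accurate to about 1 kg/m$^3$ below 70 wt%.

## Fitting decay curves

`fit_recovery()` and `fit_cpmg()` implement the standard protocol:
nonlinear least squares of
$M_z(t)/M_z^\infty = 1 + y_0 - a_{1s} e^{-t/T_{1s}} - a_{1f} e^{-t/T_{1f}}$
and
$M_{xy}(t)/M_{xy}^0 = y_0 + a_{2s} e^{-t/T_{2s}} + a_{2f} e^{-t/T_{2f}}$,
with bounds $T \in [10^{-4}, 10^2]$ s, $a \in [0, 1.5]$,
$y_0 \in [-0.1, 0.1]$ — wide enough for every regime of interest here.
Choices that were genuinely open:

* **Normalization is fitted, not estimated.** The scale ($M_z^\infty$ or
  $M_{xy}^0$) is a free parameter — the recovery plateau, or the echo
  train extrapolated to $t = 0$. A tail-mean plateau estimate on the
  4 ms–30 s log grid is biased low by over a percent (the slow component
  has not fully plateaued) and that bias propagates into every
  coefficient.
* **Initialization** profiles the monoexponential time constant over a
  25-point log grid, solving the amplitudes exactly at each candidate
  (they enter linearly), then polishes with Levenberg–Marquardt
  (`minpack.lm`). The biexponential fit starts both from a geometric
  split of the mono time constant (x3, /3) and from the mono solution
  with a dormant second component; the better optimum is kept. The second
  start guarantees the nested-model inequality RSS(bi) <= RSS(mono).
* **Model selection** (`select_model()`) formalizes the usual
  residual-plot argument: the biexponential is accepted only when an
  F-test on the nested fits rejects at $\alpha = 0.05$ *and* a
  Wald–Wolfowitz runs test detects structure in the mono residuals.
* **Uncertainty**: parametric bootstrap (200 seeded resamples) by
  default, linearized-covariance draws as a cheaper alternative; 80%
  intervals and pointwise fitted-curve bands
  (`confidence_band()`). Replicates are aggregated as mean ± sd
  (`replicate_stats()`) without pooling per-fit covariances.
* **Ordering**: $T_{slow} \ge T_{fast}$ is enforced by relabeling after
  the fit, so results are invariant to optimizer parameter order.

### What precision to expect

At 1% Gaussian noise on the 32-point 4 ms–30 s grid, with truth
$(a_{1s}, a_{1f}, T_{1s}, T_{1f}) = (0.7, 0.3, 2.0\,\mathrm{s},
0.3\,\mathrm{s})$, the Cramér–Rao bound puts the *floor* on the median
relative error of any unbiased fit at roughly 2.7%, 6.2%, 3.0% and 7.7%
per parameter; the package's fitter lands within a factor ~1.3 of that
floor (and the test suite asserts a factor 1.7). Noiseless round-trips
are exact to at least six significant digits. Single-digit-percent
coefficient uncertainty at benchtop noise levels is therefore a property
of the experiment design, not the software; averaging replicates or
extending the grid is the remedy.

## The synthetic-data generator

`simulate_series()` emulates the three preparations behind the
experiments: sucrose in H2O, in D2O, and freeze-dried from 20/80
sucrose–D2O then redissolved in D2O (`"FD-D2O"`). For each concentration
it builds the proton inventory, forms the exchange pair from the pool
concentrations, composes the three-component observed signal, and adds
seeded i.i.d. Gaussian noise (sigma as a fraction of the maximum signal;
a Rician floor is deliberately out of scope at these SNRs). Defaults
follow the acquisition protocols: 32 log-spaced recovery delays from
4 ms to 30 s; CPMG echoes at $2\tau k$ with $\tau = 1$ ms, 3000 echoes;
three replicates.

Two generator inputs are not derivable from published information and
were fixed once as documented design choices:

* **Pool relaxation rates vs concentration**
  (`default_rate_model()`): smooth monotone-decreasing relaxation-time
  profiles (water pool T1 from 3.2 s down, hydroxyl and carbon-bound
  pools faster, T2 < T1 throughout), bracketing the ranges typical of
  low-field measurements on sucrose solutions. Any real analysis should
  replace them with measured values; they are stand-ins that control
  only the qualitative simulation studies.
* **Exchange rate constant** $k_{ex} = 0.05$ s$^{-1}$ per mol/m$^3$.
  Hydroxyl–water proton exchange near neutral pH has millisecond-or-
  faster site lifetimes, i.e. pseudo-first-order rates of order
  $10^2$–$10^3$ s$^{-1}$ in protiated water; 0.05 reproduces that and
  keeps all three scenarios in the fast-exchange regime, where the
  fitted coefficients mirror the proton fractions. At substantially slower
  exchange the model itself predicts a visible third decay mode from the
  exchangeable pool (proton dilution shrinks $k_A$, $k_B$) — the reason
  strongly deuterated preparations strain the fast-exchange
  approximation.

What passing simulation tests do **not** show about real data: the
generator has no pulse imperfections, no B1 inhomogeneity, no
temperature drift, no radiation damping, and CPMG refocusing is ideal
(no diffusion or exchange-modulated dephasing between echoes — the
free-evolution solution is applied directly to the echo envelope). Field
data failing where the simulations succeed points at those mechanisms.

## Numerical choices, edge cases

* Eigenrate ordering is slow-first; numerically degenerate eigenrates
  (possible only when $k_A k_B = 0$ and $r_A = r_B$) return a flagged
  single-exponential solution instead of dividing by
  $\lambda_2 - \lambda_1$.
* $k_{ex} = 0$ is handled by the same general eigendecomposition (the
  printed B-pool closed form has $k_B$ in a denominator and is not used
  directly).
* The scale constant $\mu$ relating population difference to
  magnetization is retained as a documented field (default 1); it
  cancels in every normalized output.
* All internal rates are s$^{-1}$ and times s; summary tables report
  time constants in ms to match the usual presentation.
* Zero total protons (ideal D2O, fully deuterated solute) raises
  "no proton signal" rather than returning NaN fractions.

## Problem sizes

The shipped tests run randomized oracle comparisons (21 parameter sets
per channel), a 100-seed recovery study on the 32-point grid, a 200-curve
coverage study for the confidence bands, and three-scenario trend
simulations at three concentrations with triplicates — about 15 s of
compute in total, chosen to exercise every regime while keeping the suite
fast. `scripts/acceptance.R` recomputes the deuterated-scenario
coefficient prediction from stoichiometry alone (four concentrations) in
well under a second.

## Limitations

* Two exchanging pools plus one additive nonexchangeable component; no
  general N-site exchange, no T1rho, no relaxation-mechanism theory
  (the pool rates are inputs, not predictions).
* No pH or temperature dependence of $k_{ex}$ or the densities.
* The exchange model treats concentrations as constant (linearized
  second-order kinetics), valid for an NMR experiment but not for
  chemically evolving samples.
* Inverse-Laplace / relaxation-spectrum analysis is out of scope; model
  order is mono vs bi only.
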