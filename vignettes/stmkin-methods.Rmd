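---
title: "Thermokinetic model construction and control analysis with stmkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermokinetic model construction and control analysis with stmkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmkin)
```

## The modelling problem

Kinetic metabolic models need rate laws and rate constants that are largely
unknown, while network structure, fluxes, and (often) metabolite
concentrations are measurable. stmkin builds kinetic models *around* a given
reference state instead of simulating towards one. The key observation is
that for modular rate laws the scaled reaction elasticities — the log-log
derivatives of rates with respect to concentrations that determine all
linearised dynamics — decompose into

* a **thermodynamic part** fixed entirely by the thermodynamic force
  `theta = -Delta_r G / RT` of the reaction: for substrate and product
  molecularities `mS`, `mP` and flux ratio `zeta = v+/v- = exp(theta)` it is
  `(zeta mS - mP) / (zeta - 1)`, and
* a **kinetic part** determined by saturation values
  `beta = c / (c + k)`, the bound fractions of enzyme with respect to each
  reactant or regulator.

Forces are constrained network-wide (they must sum to zero around
stoichiometric cycles, as must log equilibrium constants), but the
saturation values are free numbers in `]0,1[`. Sampling the free values
while keeping the state fixed therefore yields ensembles of
thermodynamically consistent models, and every consistent model with these
rate laws arises from some choice of the basic variables.

## Model construction pipeline

1. **Network** (`stm_network`): stoichiometric matrix, external (clamped)
   metabolites, optional non-competitive activation/inhibition edges with
   molecularities (default 1). `reduce_network()` splits the internal
   stoichiometry into independent rows `N_ind` and a link matrix `L`
   (`N_int = L N_ind`), plus conservation relations `G` and flux modes `K`.
2. **State** (`stm_state`): concentrations (mM, log-referenced to a 1 mM
   standard), net fluxes (mM/s), log equilibrium constants. Forces follow as
   `theta = ln keq - N' ln c` over all species. Feasibility means
   `v * theta > 0` for active reactions; stationarity `N_int v = 0`
   (or `N_int v = lambda c` with growth dilution `lambda`). Helpers:
   `project_fluxes()` (closest stationary sign-constrained fluxes, QP),
   `mdf_concentrations()` (max-min driving force, LP), `keq_from_mu0()`.
3. **Kinetics** (`stm_saturation`, `reconstruct_kinetics`): saturation
   values are supplied, fixed (1/2 by default, the canonical "half
   saturated" choice), or sampled. Dissociation constants follow as
   `k = c (1 - beta)/beta`; turnover rates split so the Haldane relation
   `ln keq = ln(kcat+/kcat-) + sum n ln kM` holds exactly (symmetric split
   around the velocity constant `kV`, or forward `kcat+` as the basic
   variable); enzyme levels scale rates to the reference fluxes.
4. **Analysis** (`elasticities`, `control_analysis`, `synergy_coefficients`,
   `spectral_response`, `propagate_spectrum`): first- and second-order
   elasticities, Jacobian `A = N_ind E_c L - lambda I`, control and response
   matrices, synergies, linearised time courses, and noise spectra.

## Rate laws

Three reversible laws share the mass-action numerator
`kcat+ prod (c/kM)^mS - kcat- prod (c/kM)^mP`:

* `ma` — mass action: numerator only; the kinetic elasticity term vanishes.
* `sm` — simultaneous binding: denominator `prod (1 + c/kM)^(mS+mP)`;
  scaled elasticity `E_rev - (mS + mP) beta`.
* `cm` — common modular (convenience kinetics): denominator
  `psi+ + psi- - 1` with `psi± = prod (1 + c/kM)^(m±)`; scaled elasticity
  `E_rev - beta (mS psi+ + mP psi-) / (psi+ + psi- - 1)`.

Regulation enters all laws as a non-competitive prefactor
`(c/(c+kA))^mA (kI/(c+kI))^mI`, contributing `mA (1 - betaA)` and
`-mI betaI` to the scaled elasticities. This prefactor convention was chosen
so that the activator elasticity is `mA (1 - betaA)`; the same structure is
recovered by differentiating the implemented rate laws numerically, which
serves as the authoritative oracle in the test suite for every closed-form
elasticity in the package.

A note on the thermodynamics-only factorisation `v = e kcat eta_rev eta_sat`
with `eta_rev = 1 - exp(-theta)`: differentiating it gives the elasticity
contribution `-n_il / (exp(theta) - 1)` in flux orientation. (A tempting
variant with `exp(-theta)` in the denominator has the wrong sign; the
finite-difference oracle on `v = e kcat (1 - exp(-theta(c)))` settles the
convention, and `elasticity_factorized()` implements the verified form.)

## Numerical choices

* **Units**: concentrations mM, fluxes mM/s, forces in RT
  (RT = 2.479 kJ/mol at 298.15 K, configurable), volumes µm³.
* **Rank and null spaces**: SVD with relative tolerance `1e-10`;
  independent metabolite rows chosen greedily in input order so reductions
  are reproducible. Cycle vectors are rescaled to a maximal entry of 1, so
  Wegscheider violations are reported in ln-keq units of the dominant
  reaction.
* **Equilibrium guard**: elasticity formulas diverge at `theta = 0`.
  Reactions with `|theta| < 1e-6` RT raise a structured warning; reactions
  with `v = 0` are treated as at equilibrium and given mass-action
  exchange-flux elasticities with a configurable exchange rate (default 0).
  State construction also warns when an active reaction has `|theta| <= 1`
  RT, since small forces inflate elasticities and enzyme demand.
* **Saturation sampling**: uniform or beta distributions, clipped to
  `[0.001, 0.999]` to avoid full saturation. With uniform beta, `ln(c/kM)`
  follows a standard logistic distribution — a property test checks this.
* **Second-order elasticities** are central finite differences (step 1e-4 on
  the log scale, Richardson-extrapolated) of the closed-form first-order
  elasticities, which are themselves validated against the rate laws. This
  is far better conditioned than double-differencing the rates and keeps
  the symmetric tensor accurate to ~1e-10.
* **Linear algebra**: the Jacobian solve inside the control matrices is
  row/column equilibrated before inversion, because unscaled elasticities
  can span many orders of magnitude when concentrations do (e.g. after
  aggressive force scaling).
* **Steady states** of reconstructed nonlinear models use a damped Newton
  iteration on the independent concentrations (relative tolerance 1e-10,
  at most 200 iterations), so conserved moieties stay on their reference
  totals. Synergy coefficients are central second differences of the log
  steady-state target with relative enzyme steps of 1e-3 (step-halving is
  tested to 1%).
* **LP/QP**: flux projection, MDF, FBA and MoMA use small dense
  simplex/active-set solves with deterministic settings; FBA ties are
  broken by a secondary minimisation of the l1 flux norm.
* **Noise**: chemical Langevin sources act per one-way flux,
  `s = (v+ + v-)/(Omega N_A)`, a diagonal white spectral density (sources
  are taken independent across reactions; correlated sources for shared
  enzyme complexes are out of scope). Spectra use the two-sided convention;
  windowed variances integrate `S(omega) sinc^2(omega dt/2)/pi` on the
  frequency grid. For an Ornstein-Uhlenbeck benchmark the boxcar-window
  variance has the closed form `s (E dt - 1 + exp(-E dt)) / (E^3 dt^2)`,
  which the numeric integral reproduces to better than 1% on a 4000-point
  grid; its `dt -> 0` limit is the total variance `s/(2E)`.
* **Growth dilution**: `lambda > 0` adds `-lambda c` to the mass balance and
  `-lambda I` to the Jacobian; the same corrected matrix is used inside the
  control-coefficient formulas, which the nonlinear steady-state oracle
  confirms.

## Fixtures: what they emulate, and what they do not

`make_fixture()` generates self-consistent toy systems used throughout the
tests (all states pass the cycle-consistency and feasibility checks by
construction):

* `linear_chain(n)` — an unbranched pathway with clamped ends, equal forces
  (default 2 RT) and unit flux (1 mM/s). Default conditions are meant as
  generic "healthy pathway" values: forces comfortably above 1 RT, mM-scale
  concentrations, half saturation.
* `bypass` — conversion `S1 -> S3` either directly or via `S2`, plus supply
  and demand; two stationary flux modes. The reference splits flux equally
  between the routes and satisfies the cycle constraint
  `theta(S1->S2) + theta(S2->S3) = theta(S1->S3)`.
* `moiety_cycle` — an ATP/ADP pair coupled to two reactions; one
  conservation relation.
* `turbo` — a pathway that invests one ATP upstream and regains two
  downstream, with an ATPase draining the surplus. At strong forces
  (default 4 RT) the ATPase has *negative* control over its own flux — the
  paradoxical self-repression behaviour of turbo-design pathways; the
  effect disappears near equilibrium. This is a qualitative desk-scale
  stand-in for genome-scale observations of the same mechanism.
* `random(n_met, n_rxn, seed)` — a random connected network whose state is
  built from a downhill potential along a backbone path plus sign-consistent
  flux projection.

These fixtures capture topology, thermodynamic structure, and saturation
behaviour but none of the biological detail of real networks: no
compartments, no cofactor stoichiometry beyond the toy ATP loops, no
regulation layers unless added. Passing tests on them demonstrates the
mathematical machinery — consistency, theorems, oracle agreement — not
predictive accuracy for any particular organism.

Test and example problem sizes (chains of 2-5 reactions, the 5-reaction
bypass network, ensembles of 40-200 samples) were chosen so the entire
suite exercises every code path in well under a minute; the methods scale
as dense linear algebra in the number of internal metabolites.

## Statistical choices

Ensembles record every sample (stable or not) so acceptance rates can be
analysed; stability screening uses `max Re(eig) < -1e-9`. Ensemble
comparisons use a two-sided Mann-Whitney U test per target with
Benjamini-Hochberg FDR control across targets (default level 0.05) and
median differences as effect sizes; degenerate targets are flagged with
p = 1 rather than dropped. Fraction-of-models statistics carry exact
binomial confidence intervals.

## Known limitations

* Linearised predictions hold for small perturbations; large knockdowns are
  better treated by the FBA/MoMA routines or by re-solving the nonlinear
  steady state, both provided.
* Reactions exactly at equilibrium carry no scaled elasticity information;
  the exchange-flux convention makes them inert unless an exchange rate is
  supplied.
* `mdf_concentrations` reports a negative best-case minimum force with a
  warning (naming the bottleneck reactions) instead of erroring, since the
  diagnosis is usually the purpose of the call.
* Flux distributions with infeasible directions are rejected, not repaired.
* SBML support covers the species/reaction/modifier/kinetic-law subset the
  package writes; compartments and unit definitions are not interpreted.
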